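#' Decay rate of a mean-corrected log coverage profile
#'
#' Ordinary least squares of `q_i` on the gene-length-corrected position
#' `i/d`, with positions indexed 5' to 3' in transcript orientation (the
#' profile is reversed for minus-strand genes before fitting), so a positive
#' slope means coverage loss toward the 5' end — the signature of 3'-biased
#' RNA degradation — comparably across strands and gene lengths.
#'
#' @param q length-`d` mean-corrected log coverage vector in ascending genomic
#'   order (`d >= 10`).
#' @param strand `"+"` or `"-"`.
#' @return named vector `c(alpha, beta)`: intercept and decay rate.
#' @export
decay_rate <- function(q, strand = "+") {
  d <- length(q)
  stopifnot(d >= 10L)
  if (strand == "-") q <- rev(q)
  x <- seq_len(d) / d
  xb <- mean(x); qb <- mean(q)
  beta <- sum((x - xb) * (q - qb)) / sum((x - xb)^2)
  c(alpha = qb - beta * xb, beta = beta)
}

#' Per-sample decay rates for one gene
#'
#' Depth differences are adjusted first with the first step of the scale
#' normalisation (each sample's log coverage divided by its mean scale
#' factor), the per-position trimmed mean is subtracted, and [decay_rate()]
#' is fitted per sample. Off samples (all-zero) get `NA`.
#'
#' @param coverage a [coverage_matrix()] (or a plain matrix plus `strand`).
#' @param c log-shift pseudo-count used for the transformation.
#' @param trim trimmed-mean fraction per tail.
#' @param strand used when `coverage` is a plain matrix.
#' @return tibble with `sample_id`, `alpha`, `beta`, `off`.
#' @export
compute_decay_rates <- function(coverage, c = 1, trim = 0.1, strand = "+") {
  if (inherits(coverage, "coverage_matrix")) {
    R <- coverage$R
    strand <- coverage$layout$strand
    ids <- coverage$sample_ids
  } else {
    R <- as.matrix(coverage)
    ids <- colnames(R) %||% paste0("s", seq_len(ncol(R)))
  }
  off <- colSums(R) == 0
  y <- log(R + c)
  b <- row_trimmed_means(y, trim = trim)
  a <- compute_msf(y, b)
  a[off | a <= 0] <- NA_real_
  q <- sweep(y, 2L, a, "/")
  q <- q - row_trimmed_means(q[, !is.na(a), drop = FALSE], trim = trim)
  fits <- matrix(NA_real_, nrow = 2L, ncol = ncol(R))
  for (j in which(!is.na(a))) fits[, j] <- decay_rate(q[, j], strand = strand)
  tibble::tibble(sample_id = ids, alpha = fits[1L, ], beta = fits[2L, ],
                 off = off | is.na(a))
}

#' Flag degraded samples by clustering decay rates across genes
#'
#' Decay rates are standardised within each gene (robust centre/scale, for
#' comparability across genes), samples are clustered by complete-linkage
#' hierarchical clustering on Euclidean distance and cut into two groups; the
#' group with the higher mean decay is flagged as degraded if its mean exceeds
#' the other group's by `margin` times the pooled robust spread of per-sample
#' mean decay.
#'
#' @param decay genes x samples matrix of decay rates (`NA` tolerated).
#' @param margin separation required, in pooled-MAD units.
#' @return list with `degraded` (character ids or column indices), `clusters`,
#'   `sample_decay` (per-sample mean standardised decay).
#' @export
flag_degraded <- function(decay, margin = 2) {
  decay <- as.matrix(decay)
  stopifnot(nrow(decay) >= 2L, ncol(decay) >= 4L)
  ids <- colnames(decay) %||% as.character(seq_len(ncol(decay)))
  z <- t(apply(decay, 1L, function(r) {
    m <- median(r, na.rm = TRUE)
    s <- stats::mad(r, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (r - m) / s
  }))
  z[!is.finite(z)] <- 0
  dd <- dist(t(z))
  if (max(dd) < 1e-12) {
    return(list(degraded = character(), clusters = rep(1L, ncol(decay)),
                sample_decay = colMeans(z)))
  }
  cl <- cutree(hclust(dd, method = "complete"), k = 2L)
  sm <- colMeans(z)
  m1 <- mean(sm[cl == 1L]); m2 <- mean(sm[cl == 2L])
  hi <- if (m1 >= m2) 1L else 2L
  pooled <- stats::mad(c(sm[cl == 1L] - m1, sm[cl == 2L] - m2))
  if (pooled == 0) pooled <- 1e-8
  degraded <- if (abs(m1 - m2) > margin * pooled) ids[cl == hi] else character()
  list(degraded = degraded, clusters = cl, sample_decay = sm)
}

#' On/off status of a gene by coverage-profile angle
#'
#' Measures shape similarity as the angle between each sample's log coverage
#' vector and the cohort mean vector. A sample expressed at a low level but
#' sharing the cohort profile has a small angle and counts as "on"; all-zero
#' samples and samples at more than `theta_star` degrees are "off". A gene is
#' excluded when strictly more than 20% of samples are off (off-fraction
#' exactly 0.20 is retained); a gene whose mean vector is zero is excluded
#' outright.
#'
#' @param coverage a [coverage_matrix()] or `d x n` count matrix.
#' @param theta_star angle cutoff in degrees.
#' @param c log-shift pseudo-count.
#' @param off_fraction_max exclusion threshold (strict inequality).
#' @return list with `theta` (degrees per sample), `off` (logical),
#'   `off_fraction`, `excluded` (logical).
#' @export
onoff_fraction <- function(coverage, theta_star = 60, c = 1,
                           off_fraction_max = 0.20) {
  R <- if (inherits(coverage, "coverage_matrix")) coverage$R else as.matrix(coverage)
  stopifnot(ncol(R) >= 4L)
  v <- log(R + c) - log(c)  # zero counts map to exactly zero
  m <- rowMeans(v)
  nm <- sqrt(sum(m^2))
  if (nm == 0) {
    return(list(theta = rep(90, ncol(R)), off = rep(TRUE, ncol(R)),
                off_fraction = 1, excluded = TRUE))
  }
  nv <- sqrt(colSums(v^2))
  cosang <- as.numeric(crossprod(v, m)) / (pmax(nv, 1e-300) * nm)
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  off <- nv == 0 | theta > theta_star
  off_fraction <- mean(off)
  list(theta = theta, off = off, off_fraction = off_fraction,
       excluded = off_fraction > off_fraction_max)
}

#' Cohort quality-control report
#'
#' Runs the degradation and on/off filters over a list of per-gene coverage
#' matrices.
#'
#' @param coverages named list of [coverage_matrix()] objects (one per gene).
#' @param margin see [flag_degraded()].
#' @param theta_star,off_fraction_max see [onoff_fraction()].
#' @param c log-shift pseudo-count for both filters.
#' @return object of class `qc_report`: list with `decay` (genes x samples
#'   beta matrix), `degraded` (sample ids), `genes` (tibble with per-gene
#'   `off_fraction` and `excluded`), `thresholds`.
#' @export
qc_report <- function(coverages, margin = 2, theta_star = 60,
                      off_fraction_max = 0.20, c = 1) {
  stopifnot(length(coverages) >= 1L)
  gene_ids <- names(coverages) %||%
    vapply(coverages, function(x) x$layout$gene_id, character(1))
  decays <- lapply(coverages, compute_decay_rates, c = c)
  decay <- do.call(rbind, lapply(decays, function(d) d$beta))
  rownames(decay) <- gene_ids
  colnames(decay) <- decays[[1]]$sample_id
  degraded <- if (nrow(decay) >= 2L && ncol(decay) >= 4L) {
    flag_degraded(decay, margin = margin)$degraded
  } else character()
  onoff <- lapply(coverages, onoff_fraction, theta_star = theta_star, c = c,
                  off_fraction_max = off_fraction_max)
  genes <- tibble::tibble(
    gene_id = gene_ids,
    off_fraction = vapply(onoff, `[[`, numeric(1), "off_fraction"),
    excluded = vapply(onoff, `[[`, logical(1), "excluded")
  )
  structure(
    list(decay = decay, degraded = degraded, genes = genes,
         thresholds = list(margin = margin, theta_star = theta_star,
                           off_fraction_max = off_fraction_max, c = c)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d gene(s) x %d sample(s): %d degraded sample(s), %d excluded gene(s)\n",
              nrow(x$decay), ncol(x$decay), length(x$degraded),
              sum(x$genes$excluded)))
  invisible(x)
}

#' @describeIn qc_report per-gene tidy table.
#' @param x a `qc_report`.
#' @param ... unused.
#' @export
tidy.qc_report <- function(x, ...) x$genes

#' @describeIn qc_report one-row summary.
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$decay), n_samples = ncol(x$decay),
                 n_degraded = length(x$degraded),
                 n_excluded_genes = sum(x$genes$excluded))
}
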