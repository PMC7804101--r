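#' Orthonormal exon/intron region basis
#'
#' One unit direction per exon and per included intron: constant on the
#' region's column support and zero elsewhere. Supports are disjoint, so the
#' basis is orthonormal by construction. A split intron's two flanks share one
#' direction (they are one basis region).
#'
#' @param layout a `gene_layout` with intron inclusion applied.
#' @return `d x K` matrix with region ids as column names.
#' @export
build_region_basis <- function(layout) {
  cols <- layout_columns(layout)
  regions <- layout_regions(layout)
  d <- nrow(cols)
  B <- matrix(0, nrow = d, ncol = nrow(regions),
              dimnames = list(NULL, regions$region))
  for (k in seq_len(nrow(regions))) {
    sup <- cols$column[cols$region == regions$region[k]]
    B[sup, k] <- 1 / sqrt(length(sup))
  }
  B
}

#' Data-driven degrees of freedom by Kolmogorov-Smirnov search
#'
#' Squared outlyingness scores behave like a chi-squared variable under the
#' null, but with effective degrees of freedom that depend on the direction
#' bank and the robust standardisation. The df is chosen over `1..K_max` to
#' minimise the K-S distance between the empirical distribution of the scores
#' and the chi-squared CDF. Potential outliers (the top 5% of scores) are
#' excluded from the sup computation while the empirical ranks are kept
#' relative to the full sample size, so the exclusion does not itself distort
#' the fit at the true df.
#'
#' @param go2 vector of squared outlyingness scores (n >= 30 recommended).
#' @param K_max largest candidate df.
#' @param exclude_top fraction of largest scores excluded as potential outliers.
#' @param step df grid step. The default 1 searches the integer df `1..K_max`;
#'   the detection steps use a finer grid (chi-squared distributions are
#'   well-defined at fractional df), which calibrates the tail noticeably
#'   better when the effective df of the score distribution is not integral.
#' @return list with `df` (the selected degrees of freedom) and the
#'   per-candidate `ks` statistics.
#' @export
fit_df_by_ks <- function(go2, K_max, exclude_top = 0.05, step = 1) {
  go2 <- go2[is.finite(go2)]
  n <- length(go2)
  stopifnot(n >= 3L, K_max >= step)
  if (diff(range(go2)) < .Machine$double.eps) {
    warning("degenerate score distribution; df set to 1")
    return(list(df = 1, ks = NA_real_))
  }
  x <- sort(go2)
  keep <- seq_len(n - floor(exclude_top * n))
  dfs <- seq(step, K_max, by = step)
  ks <- vapply(dfs, function(df) {
    Fx <- pchisq(x[keep], df = df)
    max(abs(keep / n - Fx), abs((keep - 1) / n - Fx))
  }, numeric(1))
  list(df = dfs[which.min(ks)], ks = ks)
}

#' Detect global shape changes
#'
#' Projects the latent expression matrix onto the orthonormal exon/intron
#' basis, scores every sample by modified projection outlyingness in the
#' K-dimensional coordinate space (bank: basis axes, data-driven directions,
#' seeded random directions), calibrates significance against a chi-squared
#' distribution with data-driven degrees of freedom, and maps each call's most
#' outlying direction back to base-level space.
#'
#' @param X `d x n` latent expression matrix (see
#'   [fit_mean_scale_correction()]), or a `normalization_model`.
#' @param layout the `gene_layout` the rows of `X` follow.
#' @param alpha per-sample significance level.
#' @param rho normality-screen cutoff.
#' @param n_random random directions added to the bank.
#' @param seed seed for the random directions.
#' @return object of class `global_result`: list with `K`, `coords`
#'   (`K x n`), `GO`, `df`, `alpha`, `calls` (flagged sample indices), `MOD`
#'   (`d x n`, oriented), `basis`, `sample_ids`.
#' @export
detect_global <- function(X, layout, alpha = 1e-4, rho = 3, n_random = 100L,
                          seed = 1L) {
  if (inherits(X, "normalization_model")) X <- X$X
  X <- as.matrix(X)
  B <- build_region_basis(layout)
  K <- ncol(B)
  n <- ncol(X)
  sample_ids <- colnames(X) %||% paste0("s", seq_len(n))
  if (K == 0L) {
    return(structure(list(K = 0L, coords = NULL, GO = numeric(n),
                          df = NA_integer_, alpha = alpha, calls = integer(),
                          MOD = NULL, basis = B, sample_ids = sample_ids),
                     class = "global_result"))
  }
  coords <- crossprod(B, X) # K x n
  axes <- diag(K)
  bank <- direction_bank(directions = axes, Y = coords, n_random = n_random,
                         seed = seed, provenance = "basis")
  mpo <- modified_projection_outlyingness(coords, bank, rho = rho)
  GO <- mpo$scores
  df_fit <- fit_df_by_ks(GO[is.finite(GO)]^2, K_max = 3 * K, step = 0.25)
  cutoff <- qchisq(1 - alpha, df = df_fit$df)
  calls <- which(GO^2 > cutoff)
  MOD <- B %*% mpo$mod # back to d-space; unit norm since B orthonormal
  colnames(MOD) <- sample_ids
  structure(
    list(K = K, coords = coords, GO = GO, df = df_fit$df, ks = df_fit$ks,
         alpha = alpha, cutoff = cutoff, calls = calls, MOD = MOD, basis = B,
         no_admissible_direction = mpo$no_admissible_direction,
         sample_ids = sample_ids),
    class = "global_result"
  )
}

#' @export
print.global_result <- function(x, ...) {
  cat(sprintf("<global_result> K = %d basis region(s); df = %s; %d call(s) at alpha = %g\n",
              x$K, x$df, length(x$calls), x$alpha))
  invisible(x)
}

#' @describeIn detect_global per-sample tidy table (`sample_id`, score `GO`,
#'   `GO2`, `p_value`, `call`).
#' @param x a `global_result`.
#' @param ... unused.
#' @export
tidy.global_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids,
    step = "global",
    score = x$GO,
    score2 = x$GO^2,
    p_value = pchisq(x$GO^2, df = x$df %||% NA_integer_, lower.tail = FALSE),
    call = seq_along(x$GO) %in% x$calls
  )
}

#' @describeIn detect_global one-row summary.
#' @export
glance.global_result <- function(x, ...) {
  tibble::tibble(step = "global", K = x$K, df = x$df, alpha = x$alpha,
                 n = length(x$GO), n_calls = length(x$calls))
}

#' Write per-sample detection scores as TSV
#'
#' @param result a `global_result` or `local_result`.
#' @param path output path.
#' @export
write_result_tsv <- function(result, path) {
  utils::write.table(as.data.frame(tidy(result)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a call's most outlying direction as a BedGraph track
#'
#' @param result a `global_result` or `local_result`.
#' @param layout the matching `gene_layout`.
#' @param sample_id flagged sample whose MOD to export.
#' @param path output path.
#' @export
write_mod_bedgraph <- function(result, layout, sample_id, path) {
  j <- match(sample_id, result$sample_ids)
  if (is.na(j)) stop("unknown sample_id: ", sample_id)
  v <- result$MOD[, j]
  pos <- layout$column_map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"MOD %s\"", sample_id), con)
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  utils::write.table(
    data.frame(layout$chrom, pos[starts], pos[ends] + 1L,
               signif(runs$values, 8)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
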