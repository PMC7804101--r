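#' Residuals after removing the exon/intron low-rank representation
#'
#' `X_resid = X - B (B' X)` for an orthonormal basis `B`; the residuals are
#' orthogonal to every basis direction.
#'
#' @param X `d x n` latent expression matrix.
#' @param basis `d x K` orthonormal basis from [build_region_basis()].
#' @return `d x n` residual matrix.
#' @export
compute_residuals <- function(X, basis) {
  X <- as.matrix(X)
  X - basis %*% crossprod(basis, X)
}

#' Sparse window direction bank for local detection
#'
#' Unit-constant window directions tiling the layout columns at each
#' requested size (stride = half the window by default, read-length scale
#' sizes 50-200 bp), plus one direction per junction-derived cryptic region:
#' an interval bounded by novel splice-junction evidence (at least
#' `min_junction_reads` supporting reads in some sample) whose skipped bases
#' lie inside the layout.
#'
#' @param layout a `gene_layout` with intron inclusion applied.
#' @param junctions optional junction tibble
#'   (`donor`, `acceptor`, `sample_id`, `count`).
#' @param sizes window sizes in columns.
#' @param strides per-size strides (default `sizes / 2`).
#' @param min_junction_reads support needed for a cryptic-region direction.
#' @return a [direction_bank()] containing only structured window directions
#'   (callers add random/data-driven directions if wanted).
#' @export
build_window_bank <- function(layout, junctions = NULL,
                              sizes = c(50L, 100L, 200L), strides = NULL,
                              min_junction_reads = 2L) {
  d <- length(layout$column_map)
  strides <- strides %||% pmax(1L, as.integer(sizes / 2))
  dirs <- list()
  meta <- list()
  for (si in seq_along(sizes)) {
    size <- min(sizes[si], d)
    starts <- unique(c(seq(1L, d - size + 1L, by = strides[si]), d - size + 1L))
    for (s in starts) {
      v <- numeric(d)
      v[s:(s + size - 1L)] <- 1 / sqrt(size)
      dirs[[length(dirs) + 1L]] <- v
      meta[[length(meta) + 1L]] <- tibble::tibble(
        provenance = "window", start = s, end = s + size - 1L, size = size
      )
    }
    if (sizes[si] >= d) break # one full-length window is enough
  }
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    jx <- dplyr::summarise(
      dplyr::group_by(junctions, .data$donor, .data$acceptor),
      max_count = max(.data$count), .groups = "drop"
    )
    jx <- jx[jx$max_count >= min_junction_reads, , drop = FALSE]
    for (i in seq_len(nrow(jx))) {
      cols <- which(layout$column_map >= jx$donor[i] &
                      layout$column_map < jx$acceptor[i])
      if (length(cols) == 0L) next
      v <- numeric(d)
      v[cols] <- 1 / sqrt(length(cols))
      dirs[[length(dirs) + 1L]] <- v
      meta[[length(meta) + 1L]] <- tibble::tibble(
        provenance = "cryptic", start = min(cols), end = max(cols),
        size = length(cols)
      )
    }
  }
  D <- do.call(cbind, dirs)
  # windows sharing support after clipping can duplicate; keep the first
  dup <- duplicated(t(D))
  D <- D[, !dup, drop = FALSE]
  info <- dplyr::bind_rows(meta)[!dup, , drop = FALSE]
  structure(
    list(directions = D, provenance = info, rng_seed = NA_integer_),
    class = "direction_bank"
  )
}

#' Detect local shape changes in residuals
#'
#' Scores the retained (non-global-outlier) samples by modified projection
#' outlyingness restricted to the sparse window bank, calibrates the squared
#' scores by [fit_df_by_ks()], and reports calls with window metadata. The
#' normality screen applies per window projection exactly as in the global
#' step.
#'
#' @param X_resid `d x m` residual matrix (columns = retained samples; see
#'   [compute_residuals()]).
#' @param bank window [direction_bank()] from [build_window_bank()].
#' @param alpha per-sample significance level.
#' @param rho normality-screen cutoff.
#' @param df_max largest candidate df for the calibration (default
#'   `min(50, number of windows)`).
#' @param retained sample indices (in the original cohort) that the columns of
#'   `X_resid` correspond to; defaults to `1..m`.
#' @return object of class `local_result`: list with `I2` (retained indices),
#'   `LO`, `df`, `alpha`, `calls` (indices into the original cohort), `MOD`,
#'   `windows` (per-call window metadata), `sample_ids`.
#' @export
detect_local <- function(X_resid, bank, alpha = 1e-4, rho = 3, df_max = NULL,
                         retained = NULL) {
  X_resid <- as.matrix(X_resid)
  m <- ncol(X_resid)
  sample_ids <- colnames(X_resid) %||% paste0("s", seq_len(m))
  retained <- retained %||% seq_len(m)
  stopifnot(length(retained) == m)
  if (m == 0L) {
    return(structure(list(I2 = integer(), LO = numeric(), df = NA_integer_,
                          alpha = alpha, calls = integer(), MOD = NULL,
                          windows = NULL, sample_ids = character()),
                     class = "local_result"))
  }
  mpo <- modified_projection_outlyingness(X_resid, bank, rho = rho)
  LO <- mpo$scores
  df_max <- df_max %||% min(50L, ncol(bank$directions))
  df_fit <- fit_df_by_ks(LO[is.finite(LO)]^2, K_max = df_max, step = 0.25)
  cutoff <- qchisq(1 - alpha, df = df_fit$df)
  calls_local <- which(LO^2 > cutoff)
  MOD <- mpo$mod
  colnames(MOD) <- sample_ids
  windows <- if (length(calls_local)) {
    info <- bank$provenance[mpo$direction_index[calls_local], , drop = FALSE]
    dplyr::bind_cols(tibble::tibble(sample_id = sample_ids[calls_local]), info)
  } else NULL
  structure(
    list(I2 = retained, LO = LO, df = df_fit$df, ks = df_fit$ks, alpha = alpha,
         cutoff = cutoff, calls = retained[calls_local],
         calls_local = calls_local, MOD = MOD, windows = windows,
         no_admissible_direction = mpo$no_admissible_direction,
         sample_ids = sample_ids),
    class = "local_result"
  )
}

#' @export
print.local_result <- function(x, ...) {
  cat(sprintf("<local_result> %d retained sample(s); df = %s; %d call(s) at alpha = %g\n",
              length(x$I2), x$df, length(x$calls), x$alpha))
  invisible(x)
}

#' @describeIn detect_local per-sample tidy table.
#' @param x a `local_result`.
#' @param ... unused.
#' @export
tidy.local_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids,
    step = "local",
    score = x$LO,
    score2 = x$LO^2,
    p_value = pchisq(x$LO^2, df = x$df %||% NA_integer_, lower.tail = FALSE),
    call = seq_along(x$LO) %in% x$calls_local
  )
}

#' @describeIn detect_local one-row summary.
#' @export
glance.local_result <- function(x, ...) {
  tibble::tibble(step = "local", df = x$df, alpha = x$alpha,
                 n = length(x$LO), n_calls = length(x$calls))
}
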