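#' Mean scale factors: robust per-sample slope against a baseline profile
#'
#' The mean scale factor (MSF) of sample `j` is the slope of a robust
#' no-intercept regression of the sample's log-coverage on the cohort baseline
#' log profile. It captures the combined sequencing-depth / expression-level
#' factor of the multiplicative coverage model. Fitting is Huber-weighted
#' iteratively reweighted least squares through the origin (tuning constant
#' 1.345, 20 iterations, MAD residual scale). Samples whose log profile is
#' exactly constant (e.g. an unexpressed sample) get MSF 0.
#'
#' @param log_matrix `d x n` matrix of log-transformed coverage.
#' @param baseline length-`d` baseline log profile (not identically zero).
#' @param k Huber tuning constant.
#' @param iterations IRLS iteration count.
#' @return numeric vector of `n` mean scale factors.
#' @export
compute_msf <- function(log_matrix, baseline, k = 1.345, iterations = 20L) {
  stopifnot(is.matrix(log_matrix), length(baseline) == nrow(log_matrix))
  if (all(abs(baseline) < .Machine$double.eps)) {
    stop("baseline profile is identically zero")
  }
  bb <- sum(baseline^2)
  apply(log_matrix, 2L, function(y) {
    if (diff(range(y)) < .Machine$double.eps) return(0)
    beta <- sum(baseline * y) / bb
    for (it in seq_len(iterations)) {
      r <- y - beta * baseline
      s <- stats::mad(r)
      if (s < 1e-12) break
      w <- pmin(1, k * s / pmax(abs(r), .Machine$double.eps))
      beta_new <- sum(w * baseline * y) / sum(w * baseline^2)
      if (abs(beta_new - beta) < 1e-9 * (1 + abs(beta))) {
        beta <- beta_new
        break
      }
      beta <- beta_new
    }
    beta
  })
}

#' Select the log-shift (pseudo-count) by overall skewness minimisation
#'
#' For each candidate shift `c`, coverage is log-transformed as `log(R + c)`,
#' MSFs are computed against the trimmed-mean baseline, and the overall
#' skewness is summarised as the median of the absolute per-position skewness
#' of the MSF-adjusted residuals. The candidate minimising this summary is
#' returned; ties break toward the smaller shift.
#'
#' @param R `d x n` non-negative coverage matrix.
#' @param grid positive candidate shifts (default: 20-point logarithmic grid
#'   over `[0.01, 100]`).
#' @param trim trimmed-mean fraction per tail for the baseline profile.
#' @param summary_fn functional reducing the vector of per-position skewness
#'   values to one number (default `median(abs(.))`).
#' @param max_positions the grid search evaluates at most this many base
#'   positions (a deterministic stride subsample); the skewness summary is a
#'   robust functional over thousands of positions, so a coarse subsample
#'   selects the same grid point at a fraction of the cost.
#' @return list with the selected `c`, the candidate `grid` and the per-candidate
#'   `skewness` summaries.
#' @export
select_log_shift <- function(R, grid = log_grid(), trim = 0.1,
                             summary_fn = function(s) median(abs(s)),
                             max_positions = 1000L) {
  stopifnot(is_count_matrix(as.matrix(R)))
  R <- as.matrix(R)
  if (all(R == 0)) stop("gene not expressed: coverage matrix is all zero")
  if (nrow(R) > max_positions) {
    keep <- round(seq(1L, nrow(R), length.out = max_positions))
    R <- R[keep, , drop = FALSE]
  }
  grid <- sort(grid)
  scores <- vapply(grid, function(cc) {
    lm_ <- log(R + cc)
    b <- row_trimmed_means(lm_, trim = trim)
    a <- compute_msf(lm_, b)
    resid <- lm_ - outer(b, a)
    summary_fn(row_skewness(resid))
  }, numeric(1))
  list(c = grid[which.min(scores)], grid = grid, skewness = scores)
}

# Leave-one-out local-linear smoother matrix over the MSF axis: row i holds
# the weights predicting sample i's value from the *other* samples (restricted
# to the `train` set). Shared across positions, so the full d x n mean-bias
# surface is one matrix product.
loo_loclin_operator <- function(a, bw, train = rep(TRUE, length(a))) {
  n <- length(a)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xc <- a - a[i]
    w <- stats::dnorm(xc / bw)
    w[!train] <- 0
    if (train[i]) w[i] <- stats::dnorm(0) # self stabilises the local fit
    sw <- sum(w); swx <- sum(w * xc); swxx <- sum(w * xc^2)
    det <- sw * swxx - swx^2
    l <- if (abs(det) < 1e-12) w / max(sw, 1e-300) else
      (swxx * w - swx * (w * xc)) / det
    l[i] <- 0 # leave-one-out: drop self, renormalise
    sl <- sum(l)
    if (abs(sl) > 1e-12) l <- l / sl
    L[i, ] <- l
  }
  L
}

# Local-linear smoother with Gaussian kernel; returns a predict function.
loclin_smoother <- function(x, y, bw) {
  force(x); force(y); force(bw)
  function(x0) {
    vapply(x0, function(p) {
      w <- stats::dnorm((x - p) / bw)
      if (sum(w) < 1e-300) w <- rep(1, length(x))
      xc <- x - p
      sw <- sum(w); swx <- sum(w * xc); swxx <- sum(w * xc^2)
      swy <- sum(w * y); swxy <- sum(w * xc * y)
      det <- sw * swxx - swx^2
      if (abs(det) < 1e-12) swy / sw else (swxx * swy - swx * swxy) / det
    }, numeric(1))
  }
}

select_bandwidth <- function(x, y, bw_grid = NULL) {
  rng <- diff(range(x))
  if (rng <= 0) return(1)
  bw_grid <- bw_grid %||% (rng * c(0.1, 0.15, 0.25, 0.4, 0.6, 1))
  cv <- vapply(bw_grid, function(bw) {
    errs <- vapply(seq_along(x), function(i) {
      fit <- loclin_smoother(x[-i], y[-i], bw)
      (y[i] - fit(x[i]))^2
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  bw_grid[which.min(cv)]
}

#' Fit the mean-scale normalisation model
#'
#' Estimation follows three steps: (1) the baseline log profile `mu` as a
#' per-position trimmed mean of `log(R + c)`; (2) per-sample mean scale
#' factors `a` by robust no-intercept regression on the baseline
#' ([compute_msf()]); (3) the residual-scale curve `g` as a smooth function of
#' `a`, constrained to `g(1) = 1`, by local-linear smoothing of the per-sample
#' log residual scale (bandwidth by leave-one-out cross-validation, curve
#' clipped below at 0.1). The latent expression matrix is
#' `X = (log(R + c) - a_j * mu - h_i(a_j)) / g(a_j)`.
#'
#' The term `h_i(a)` (fitted when `bias_surface = TRUE`, the default) is a
#' position-specific smooth mean-bias surface over the MSF axis, estimated by
#' a leave-one-out local-linear smoother of the residuals against `a`
#' (Silverman rule-of-thumb bandwidth, one smoother matrix shared across
#' positions). It removes the residual expression-level dependence that the
#' single log-linear baseline term cannot capture — at low counts the
#' discreteness of read depth bends the log response, so samples at extreme
#' depth factors would otherwise carry a systematic, purely depth-driven
#' shape offset that masquerades as an outlying coverage shape. The
#' leave-one-out weights keep a sample's own profile out of its correction,
#' so genuine outliers are not absorbed.
#'
#' All-zero samples are treated as "off": their MSF is 0 and their latent
#' column is 0. With fewer than 5 distinct MSF values the curve `g` is fixed
#' to the constant 1 with a warning.
#'
#' @param R `d x n` non-negative coverage matrix (or a [coverage_matrix()]).
#' @param c positive log-shift; `NULL` selects it via [select_log_shift()].
#' @param trim trimmed-mean fraction per tail.
#' @param g_clip lower clip for the fitted scale curve.
#' @param bias_surface fit and subtract the position-specific mean-bias
#'   surface `h_i(a)` (needs >= 10 expressed samples with spread in `a`).
#' @param min_n cohort size below which a warning is emitted.
#' @param region_ids optional per-position region labels (taken from the
#'   layout when `R` is a [coverage_matrix()]); when available, samples whose
#'   deviation concentrates in a single region — candidate genuine events —
#'   are excluded from the bias-surface training set.
#' @return object of class `normalization_model` with elements `c`, `mu`
#'   (positive baseline profile), `mu_log`, `a`, `g` (vectorised function),
#'   `g_knots`, `X`, `off` (logical), `residual_scale`, `sample_ids`.
#' @export
fit_mean_scale_correction <- function(R, c = NULL, trim = 0.1, g_clip = 0.1,
                                      bias_surface = TRUE, min_n = 30L,
                                      region_ids = NULL) {
  sample_ids <- NULL
  if (inherits(R, "coverage_matrix")) {
    sample_ids <- R$sample_ids
    region_ids <- region_ids %||% R$layout$region_ids
    R <- R$R
  }
  R <- as.matrix(R)
  stopifnot(is_count_matrix(R))
  n <- ncol(R)
  sample_ids <- sample_ids %||% colnames(R) %||% paste0("s", seq_len(n))
  if (n < min_n) {
    warning("cohort size ", n, " is below the recommended minimum of ", min_n,
            "; outlyingness calibration may be unstable")
  }
  if (is.null(c)) c <- select_log_shift(R, trim = trim)$c
  stopifnot(c > 0)

  off <- colSums(R) == 0
  lm_ <- log(R + c)
  mu_log <- row_trimmed_means(lm_, trim = trim)
  a <- compute_msf(lm_, mu_log)
  a[off] <- 0
  resid <- lm_ - outer(mu_log, a)

  expressed <- which(!off)
  if (bias_surface && length(expressed) >= 10L &&
      stats::sd(a[expressed]) > 1e-8) {
    ae <- a[expressed]
    re <- resid[, expressed, drop = FALSE]
    bw <- max(1.06 * stats::sd(ae) * length(ae)^(-1 / 5), 1e-6)
    # two passes: the smoother is linear, so strongly deviating samples
    # (the very outliers being looked for) would leak into their
    # MSF-neighbours' corrections. A sample is excluded from the second-pass
    # training set when its corrected deviation concentrates in one layout
    # region — the signature of a genuine localised event. Depth-curvature
    # deviations spread over all low-count regions and stay in training, so
    # they keep being corrected.
    train <- rep(TRUE, length(ae))
    for (pass in 1:2) {
      L <- loo_loclin_operator(ae, bw, train = train)
      corrected <- re - re %*% t(L)
      if (pass == 1L && !is.null(region_ids)) {
        tot <- colSums(corrected^2)
        tot[tot < 1e-300] <- 1
        max_share <- rep(0, ncol(corrected))
        for (rg in unique(region_ids)) {
          rows <- region_ids == rg
          max_share <- pmax(max_share,
                            colSums(corrected[rows, , drop = FALSE]^2) / tot)
        }
        train <- max_share <= 0.5
        if (all(train)) break
      } else if (pass == 1L) {
        break
      }
    }
    # correction inflates a sample's residual variance by 1 + sum(l^2)
    # (largest where the smoother extrapolates, at the edges of the MSF
    # range); standardise it out as for studentised regression residuals
    infl <- sqrt(1 + rowSums(L^2))
    resid[, expressed] <- sweep(corrected, 2L, infl, "/")
  }
  s <- apply(resid, 2L, stats::mad)

  fit_ok <- !off & s > 1e-10 & is.finite(a)
  if (sum(fit_ok) >= 5L && length(unique(round(a[fit_ok], 10))) >= 5L) {
    bw <- select_bandwidth(a[fit_ok], log(s[fit_ok]))
    m <- loclin_smoother(a[fit_ok], log(s[fit_ok]), bw)
    m1 <- m(1)
    g <- function(at) pmax(exp(m(at) - m1), g_clip)
    g_knots <- tibble::tibble(a = a[fit_ok], log_scale = log(s[fit_ok]),
                              bw = bw, m1 = m1)
  } else {
    if (any(fit_ok)) {
      warning("fewer than 5 distinct mean scale factors; scale curve g fixed to 1")
    }
    g <- function(at) rep(1, length(at))
    g_knots <- tibble::tibble(a = numeric(), log_scale = numeric(),
                              bw = numeric(), m1 = numeric())
  }

  ga <- g(a)
  X <- sweep(resid, 2L, ga, "/")
  X[, off] <- 0
  dimnames(X) <- list(NULL, sample_ids)
  structure(
    list(c = c, mu = exp(mu_log), mu_log = mu_log, a = a, g = g,
         g_knots = g_knots, X = X, off = off, residual_scale = s,
         sample_ids = sample_ids),
    class = "normalization_model"
  )
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf(
    "<normalization_model> d = %d x n = %d; shift c = %.4g; %d off sample(s); g(1) = %.6f\n",
    nrow(x$X), ncol(x$X), x$c, sum(x$off), x$g(1)
  ))
  invisible(x)
}

#' @describeIn fit_mean_scale_correction per-sample tidy summary (`sample_id`,
#'   MSF `a`, residual scale, fitted `g(a)`, `off` flag).
#' @param x a `normalization_model`.
#' @param ... unused.
#' @export
tidy.normalization_model <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids,
    a = x$a,
    residual_scale = x$residual_scale,
    g_a = x$g(x$a),
    off = x$off
  )
}

#' @describeIn fit_mean_scale_correction one-row model summary.
#' @export
glance.normalization_model <- function(x, ...) {
  tibble::tibble(
    d = nrow(x$X), n = ncol(x$X), c = x$c,
    n_off = sum(x$off), g_at_1 = x$g(1)
  )
}

#' Serialise a normalization model to JSON
#'
#' Stores the shift, baseline profile, MSFs and the `g`-curve knots; the
#' latent matrix is recomputable from the raw counts.
#' @param model a `normalization_model`.
#' @param path output path.
#' @export
write_normalization_json <- function(model, path) {
  jsonlite::write_json(
    list(c = model$c, mu_log = model$mu_log, a = model$a,
         off = model$off, g_knots = model$g_knots,
         sample_ids = model$sample_ids),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
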