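# Internal helpers shared across modules.

# Moment skewness; NA-safe, 0 for (near-)constant input.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= .Machine$double.eps) return(0)
  mean((x - m)^3) / s2^1.5
}

# Row-wise moment skewness, vectorised; 0 for (near-)constant rows.
row_skewness <- function(m) {
  mu <- rowMeans(m)
  m2 <- rowMeans(m^2) - mu^2
  m3 <- rowMeans(m^3) - 3 * mu * rowMeans(m^2) + 2 * mu^3
  out <- ifelse(m2 > .Machine$double.eps, m3 / m2^1.5, 0)
  out[!is.finite(out)] <- 0
  out
}

# Two-sided quantile winsorization.
winsorize <- function(x, frac = 0.05) {
  if (frac <= 0) return(x)
  qs <- quantile(x, c(frac, 1 - frac), names = FALSE, type = 7)
  pmin(pmax(x, qs[1]), qs[2])
}

# Unscaled median absolute deviation (no 1.4826 consistency factor).
mad_raw <- function(x) median(abs(x - median(x)))

# Gaussian consistency constant for the sd of a two-sided winsorized sample:
# sqrt(E[W^2]) where W is a standard normal clipped at +-qnorm(1 - f).
winsor_sd_consistency <- function(f) {
  q <- qnorm(1 - f)
  sqrt(1 - 2 * (q * dnorm(q) + f) + 2 * f * q^2)
}

# Trimmed mean by row of a matrix, `trim` fraction per tail.
row_trimmed_means <- function(m, trim = 0.1) {
  apply(m, 1L, mean, trim = trim)
}

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v)
  v / nv
}

is_count_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(is.finite(m)) && all(m >= 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Logarithmic grid of candidate pseudo-counts.
log_grid <- function(from = 0.01, to = 100, length.out = 20L) {
  exp(seq(log(from), log(to), length.out = length.out))
}
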