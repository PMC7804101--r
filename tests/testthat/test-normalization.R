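test_that("mean scale factors recover exact scalings", {
  withr::local_seed(41)
  d <- 80
  base <- rnorm(d, 4, 1)
  Y <- cbind(base, 2 * base, 0.5 * base + rnorm(d, sd = 1e-9))
  a <- compute_msf(Y, base)
  expect_equal(unname(a), c(1, 2, 0.5), tolerance = 1e-6)
  # constant column -> MSF 0
  expect_equal(unname(compute_msf(cbind(rep(3, d)), base)), 0)
})

test_that("MSF equals an independent Huber IRLS oracle on random data", {
  withr::local_seed(42)
  huber_oracle <- function(y, b, k = 1.345, iters = 20) {
    beta <- sum(b * y) / sum(b * b)
    for (i in seq_len(iters)) {
      r <- y - beta * b
      s <- mad(r)
      if (s < 1e-12) break
      w <- pmin(1, k * s / pmax(abs(r), .Machine$double.eps))
      bn <- sum(w * b * y) / sum(w * b * b)
      if (abs(bn - beta) < 1e-9 * (1 + abs(beta))) { beta <- bn; break }
      beta <- bn
    }
    beta
  }
  for (rep in 1:20) {
    b <- rnorm(50, 3, 1)
    y <- runif(1, 0.5, 2) * b + rnorm(50, sd = 0.3)
    expect_equal(unname(compute_msf(cbind(y), b)), huber_oracle(y, b),
                 tolerance = 1e-6)
  }
})

test_that("MSF is robust and close to MASS::rlm on contaminated data", {
  skip_if_not_installed("MASS")
  withr::local_seed(43)
  b <- rnorm(200, 4, 1)
  y <- 1.3 * b + rnorm(200, sd = 0.2)
  y[1:10] <- y[1:10] + 8 # gross outliers
  ours <- unname(compute_msf(cbind(y), b))
  ref <- unname(coef(MASS::rlm(y ~ b - 1, k = 1.345, maxit = 50)))
  expect_equal(ours, ref, tolerance = 0.01)
  expect_lt(abs(ours - 1.3), 0.05)
})

test_that("log-shift selection finds the variance-stabilising pseudo-count", {
  withr::local_seed(44)
  # construct counts whose log(R + 5) is exactly Gaussian per position
  d <- 120; n <- 200
  mu <- rnorm(d, 3, 0.5)
  a <- rnorm(n, 1, 0.1)
  Y <- outer(mu, a) + matrix(rnorm(d * n, sd = 0.2), d, n)
  R <- pmax(exp(Y) - 5, 0)
  grid <- c(0.5, 1, 2, 5, 10, 20, 50)
  sel <- select_log_shift(R, grid = grid)
  step <- which(grid == 5)
  expect_true(sel$c %in% grid[(step - 1):(step + 1)])

  # argmin matches a brute-force scan of the same objective
  expect_equal(sel$c, sel$grid[which.min(sel$skewness)])
  expect_error(select_log_shift(matrix(0, 10, 10)), "not expressed")
})

test_that("model-exact input yields a latent matrix of zeros", {
  withr::local_seed(45)
  d <- 150; n <- 40; cc <- 2
  mu <- rnorm(d, 3, 0.6)
  a <- runif(n, 0.8, 1.25)
  R <- model_exact_matrix(mu, a, cc)
  nm <- fit_mean_scale_correction(R, c = cc, bias_surface = FALSE, min_n = 1)
  expect_lt(max(abs(nm$X)), 1e-6)
  # with the bias surface the identity is preserved as well
  nm2 <- fit_mean_scale_correction(R, c = cc, min_n = 1)
  expect_lt(max(abs(nm2$X)), 1e-6)
  expect_equal(nm$g(1), 1, tolerance = 1e-8)
})

test_that("all-zero samples are flagged off with zero MSF and latent column", {
  withr::local_seed(46)
  d <- 100
  R <- cbind(matrix(rpois(d * 30, 40), d, 30), 0)
  nm <- suppressWarnings(fit_mean_scale_correction(R, c = 1, min_n = 1))
  expect_true(nm$off[31])
  expect_equal(nm$a[31], 0)
  expect_equal(unname(nm$X[, 31]), rep(0, d))
})

test_that("the scale curve g is recovered from cohorts with known g", {
  withr::local_seed(47)
  d <- 300; n <- 300; cc <- 1
  g_true <- function(a) pmax(a, 0.1)^1.4
  mu <- rnorm(d, 3.5, 0.5)
  a <- rnorm(n, 1, 0.12)
  X <- matrix(rnorm(d * n, sd = 0.25), d, n)
  R <- exp(outer(mu, a) + sweep(X, 2, g_true(a), "*")) - cc
  R <- pmax(R, 0)
  nm <- fit_mean_scale_correction(R, c = cc, min_n = 1)
  # a recovered up to a common scale
  expect_gt(cor(nm$a, a), 0.99)
  # g recovered over the central 90% of a after mapping the MSF scale back
  k <- median(a / nm$a)
  inner <- nm$a >= quantile(nm$a, 0.05) & nm$a <= quantile(nm$a, 0.95)
  g_hat <- nm$g(nm$a[inner])
  g_ref <- g_true(k * nm$a[inner]) / g_true(k)
  expect_lt(max(abs(g_hat - g_ref) / g_ref), 0.10)
  # residual scale decorrelated from a after correction
  sx <- apply(nm$X, 2, mad)
  expect_lt(abs(cor(sx[inner], nm$a[inner], method = "spearman")), 0.1)
})

test_that("few distinct MSF values fix g to 1 with a warning", {
  withr::local_seed(117)
  d <- 60
  base <- rnorm(d, 3, 0.5)
  R <- matrix(rpois(d * 4, exp(base)), d, 4) # 4 samples -> < 5 distinct MSFs
  expect_warning(nm <- fit_mean_scale_correction(R, c = 1, min_n = 1),
                 "fewer than 5 distinct")
  expect_equal(nm$g(c(0.5, 1, 2)), rep(1, 3))
})

test_that("depth rescaling leaves the latent matrix essentially unchanged", {
  withr::local_seed(48)
  sim <- simulate_cohort(simulation_spec(n = 60, seed = 480))
  R <- sim$coverage$R
  nm1 <- fit_mean_scale_correction(R, c = 5, min_n = 1)
  nm2 <- fit_mean_scale_correction(R * 8, c = 40, min_n = 1)
  keep <- !nm1$off
  expect_gt(cor(as.numeric(nm1$X[, keep]), as.numeric(nm2$X[, keep])), 0.995)
  rel <- max(abs(nm1$X[, keep] - nm2$X[, keep])) / sd(nm1$X[, keep])
  expect_lt(rel, 0.35)
})

test_that("normalization model serialises to JSON", {
  withr::local_seed(49)
  R <- matrix(rpois(200 * 12, 30), 200, 12)
  nm <- suppressWarnings(fit_mean_scale_correction(R, c = 1, min_n = 1))
  path <- tempfile(fileext = ".json")
  write_normalization_json(nm, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$c, nm$c)
  expect_equal(back$a, nm$a, tolerance = 1e-12)
  t1 <- tidy(nm); g1 <- glance(nm)
  expect_equal(nrow(t1), 12L)
  expect_equal(g1$n, 12L)
})
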