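test_that("1-D outlyingness matches the median/MAD definition", {
  expect_equal(outlyingness_1d(c(1, 2, 3, 4, 5), 3), 0)
  # median 3, raw MAD 1, |100 - 3| / 1
  expect_equal(outlyingness_1d(c(1, 2, 3, 4, 100), 5), 97)
  expect_warning(s <- outlyingness_1d(c(5, 5, 5, 5, 9), 5), "zero MAD")
  expect_identical(s, Inf)
  expect_equal(suppressWarnings(outlyingness_1d(c(5, 5, 5, 5, 9), 1)), 0)
})

test_that("1-D outlyingness equals the closed-form oracle on random data", {
  withr::local_seed(101)
  for (rep in 1:50) {
    v <- rnorm(sample(5:60, 1), sd = runif(1, 0.1, 10))
    j <- sample(length(v), 1)
    oracle <- abs(v[j] - median(v)) / median(abs(v - median(v)))
    expect_equal(outlyingness_1d(v, j), oracle, tolerance = 1e-12)
  }
})

test_that("winsorized Anderson-Darling screen separates normal from skewed", {
  withr::local_seed(202)
  normal_pass <- exp_fail <- 0L
  for (rep in 1:60) {
    if (as.numeric(normality_stat(rnorm(500))) <= 3) normal_pass <- normal_pass + 1L
    if (as.numeric(normality_stat(rexp(500))) > 3) exp_fail <- exp_fail + 1L
  }
  expect_gte(normal_pass, 57L) # >= 95%
  expect_gte(exp_fail, 57L)
  expect_identical(as.numeric(normality_stat(rep(2, 50))), Inf)
})

test_that("direction banks have unit-norm directions and seeded determinism", {
  withr::local_seed(7)
  Y <- matrix(rnorm(5 * 40), 5, 40)
  b1 <- direction_bank(directions = diag(5), Y = Y, n_random = 50, seed = 3)
  b2 <- direction_bank(directions = diag(5), Y = Y, n_random = 50, seed = 3)
  expect_equal(b1$directions, b2$directions)
  expect_equal(sqrt(colSums(b1$directions^2)),
               rep(1, ncol(b1$directions)), tolerance = 1e-10)
  expect_setequal(unique(b1$provenance$provenance),
                  c("structured", "data", "random"))
})

test_that("projection outlyingness finds a planted outlier and its direction", {
  withr::local_seed(303)
  Y <- matrix(rnorm(2 * 100), 2, 100)
  Y[1, 100] <- 10 # 10-sigma planted outlier along axis 1
  bank <- direction_bank(directions = diag(2), Y = Y, n_random = 200, seed = 1)
  res <- modified_projection_outlyingness(Y, bank)
  expect_equal(which.max(res$scores), 100L)
  expect_gt(abs(res$mod[1, 100]), 0.99) # |cos| with axis 1
  # dense 1-degree grid oracle over the half circle, same robust scale
  kons <- covershape:::winsor_sd_consistency(0.05)
  stat <- function(v, j) {
    w <- covershape:::winsorize(v, 0.05)
    abs(v[j] - median(v)) / (sd(w) / kons)
  }
  ang <- seq(0, pi, length.out = 181)
  H <- rbind(cos(ang), sin(ang))
  P <- crossprod(H, Y)
  o <- apply(P, 1, stat, j = 100)
  expect_lt(abs(res$scores[100] - max(o)) / max(o), 0.05)
})

test_that("scores are location and positive-scale invariant", {
  withr::local_seed(404)
  Y <- matrix(rnorm(3 * 50), 3, 50)
  bank <- direction_bank(Y = Y, n_random = 100, seed = 2)
  base <- modified_projection_outlyingness(Y, bank)$scores
  shifted <- modified_projection_outlyingness(Y + 5, bank)$scores
  scaled <- modified_projection_outlyingness(Y * 3.7, bank)$scores
  expect_equal(base, shifted, tolerance = 1e-10)
  expect_equal(base, scaled, tolerance = 1e-10)
})

test_that("enlarging the bank never decreases any score", {
  withr::local_seed(505)
  Y <- matrix(rnorm(4 * 60), 4, 60)
  small <- direction_bank(Y = Y, n_random = 20, seed = 9)
  big <- structure(list(
    directions = cbind(small$directions,
                       direction_bank(Y = NULL, directions = diag(4),
                                      n_random = 100, seed = 10)$directions),
    provenance = tibble::tibble(
      provenance = c(small$provenance$provenance, rep("extra", 104))
    ),
    rng_seed = 9L
  ), class = "direction_bank")
  s1 <- modified_projection_outlyingness(Y, small)$scores
  s2 <- modified_projection_outlyingness(Y, big)$scores
  expect_true(all(s2 >= s1 - 1e-12))
})

test_that("degenerate inputs give zero scores or the admissibility flag", {
  Y <- matrix(1, 3, 40) # all samples identical
  bank <- direction_bank(directions = diag(3), n_random = 10, seed = 1)
  res <- modified_projection_outlyingness(Y, bank)
  expect_equal(res$scores, rep(0, 40))
  expect_true(res$no_admissible_direction)

  # a single direction with a heavily skewed projection is screened out
  withr::local_seed(606)
  Y2 <- rbind(rexp(100), rnorm(100))
  skew_only <- structure(list(
    directions = matrix(c(1, 0), 2, 1),
    provenance = tibble::tibble(provenance = "structured"),
    rng_seed = 1L
  ), class = "direction_bank")
  res2 <- modified_projection_outlyingness(Y2, skew_only)
  expect_true(res2$no_admissible_direction)
  expect_equal(res2$scores, rep(0, 100))
})
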