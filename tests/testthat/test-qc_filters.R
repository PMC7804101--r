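test_that("decay rate equals closed-form OLS exactly", {
  # flat profile
  expect_equal(unname(decay_rate(rep(3, 50))["beta"]), 0)
  # exact line q = 2 * (i/d)
  d <- 40
  fit <- decay_rate(2 * seq_len(d) / d)
  expect_equal(unname(fit["beta"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit["alpha"]), 0, tolerance = 1e-10)

  withr::local_seed(31)
  for (rep in 1:30) {
    d <- sample(10:500, 1)
    q <- rnorm(d)
    strand <- sample(c("+", "-"), 1)
    fit <- decay_rate(q, strand)
    qq <- if (strand == "-") rev(q) else q
    lmfit <- lm(qq ~ I(seq_len(d) / d))
    expect_equal(unname(fit["alpha"]), unname(coef(lmfit)[1]), tolerance = 1e-10)
    expect_equal(unname(fit["beta"]), unname(coef(lmfit)[2]), tolerance = 1e-10)
  }
})

test_that("noisy decay slope is recovered within sampling error", {
  withr::local_seed(32)
  d <- 1000
  q <- 1.5 * seq_len(d) / d + rnorm(d, sd = 0.3)
  fit <- decay_rate(q)
  se <- 0.3 / (sd(seq_len(d) / d) * sqrt(d))
  expect_lt(abs(fit["beta"] - 1.5), 3 * se)
})

test_that("minus-strand profiles are reindexed so beta means 5' loss", {
  d <- 100
  ramp <- seq(0, 2, length.out = d) # rises toward high genomic coordinate
  plus <- decay_rate(ramp, "+")["beta"]
  minus <- decay_rate(ramp, "-")["beta"]
  expect_gt(plus, 0)  # + strand: 3' gain = degradation signature
  expect_lt(minus, 0) # - strand: same profile means 5' gain
})

test_that("degraded samples are flagged by complete-linkage clustering", {
  withr::local_seed(33)
  n_genes <- 50
  decay <- matrix(rnorm(n_genes * 100, 0, 0.3), n_genes, 100)
  degraded <- sample(100, 10)
  decay[, degraded] <- decay[, degraded] + 3
  colnames(decay) <- sprintf("s%03d", 1:100)
  out <- flag_degraded(decay)
  expect_setequal(out$degraded, sprintf("s%03d", degraded))

  # all clean: nothing flagged
  clean <- matrix(rnorm(n_genes * 40, 0, 0.3), n_genes, 40)
  expect_length(flag_degraded(clean)$degraded, 0L)

  # identical rows: degenerate, no flags
  expect_length(flag_degraded(matrix(1, 5, 6))$degraded, 0L)
})

test_that("generator degradation is recovered by the decay pipeline", {
  withr::local_seed(34)
  spec <- simulation_spec(n = 60, seed = 55,
                          degradation = list(samples = 1:6, beta = 3))
  sim <- simulate_cohort(spec)
  rates <- compute_decay_rates(sim$coverage)
  expect_gt(min(rates$beta[1:6]), max(rates$beta[-(1:6)]))
})

test_that("short genes attenuate the degradation slope signal", {
  # degradation acts along the transcript; with the same per-unit slope the
  # log-coverage range it spans is identical, but short genes carry fewer
  # informative positions -- the generator emulates length-dependent impact
  # by applying beta per unit of transcript fraction
  withr::local_seed(35)
  long_lay <- toy_layout(exon_lengths = c(600L, 700L, 700L),
                         intron_lengths = c(900L, 900L))
  short_lay <- build_gene_model(list(cbind(c(0, 500), c(400, 900))), L = 100L)
  for (lay in list(long_lay, short_lay)) {
    sim <- simulate_cohort(simulation_spec(
      layout = lay, n = 40, seed = 56,
      degradation = list(samples = 1:4, beta = 3)
    ))
    rates <- compute_decay_rates(sim$coverage)
    expect_gt(mean(rates$beta[1:4]), mean(rates$beta[-(1:4)]))
  }
})

test_that("on/off gene filter uses the angle criterion with a strict 20% rule", {
  lay <- small_layout(L = 200L)
  d <- length(lay$column_map)
  withr::local_seed(36)
  base <- exp(rnorm(d, log(40), 0.1))
  R <- sapply(1:10, function(j) rpois(d, base))

  # proportional low-depth sample stays "on"
  R_low <- cbind(R, rpois(d, base * 0.05))
  oo <- onoff_fraction(R_low)
  expect_false(oo$off[11])
  expect_lt(oo$theta[11], 30)

  # all-zero sample is off; orthogonal-noise sample is off
  R_bad <- cbind(R, 0, ifelse(runif(d) < 0.03, 500, 0))
  oo2 <- onoff_fraction(R_bad)
  expect_true(oo2$off[11])
  expect_true(oo2$off[12])

  # boundary: exactly 20% off is retained, strictly more is excluded
  R5 <- cbind(R[, 1:4], 0) # 1/5 off
  expect_false(onoff_fraction(R5)$excluded)
  R4 <- cbind(R[, 1:3], 0) # 1/4 off
  expect_true(onoff_fraction(R4)$excluded)

  # zero mean vector: excluded outright
  expect_true(onoff_fraction(matrix(0, d, 5))$excluded)
})

test_that("qc_report combines decay and on/off filters across genes", {
  withr::local_seed(37)
  lay <- toy_layout()
  covs <- lapply(1:3, function(g) {
    simulate_cohort(simulation_spec(layout = lay, n = 30, seed = 100 + g,
                                    degradation = list(samples = 1:3, beta = 3))
    )$coverage
  })
  names(covs) <- paste0("gene", 1:3)
  rep <- qc_report(covs)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(rep$decay), 3L)
  expect_setequal(rep$degraded, sprintf("s%03d", 1:3))
  expect_false(any(rep$genes$excluded))
  expect_equal(glance(rep)$n_degraded, 3L)
})
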