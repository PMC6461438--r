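test_that("single-exponential fits recover the generating rate exactly", {
  tg <- seq(0.05, 10, by = 0.05)
  cdf <- list(time = tg, cdf = 1 - exp(-1.2 * tg))
  f <- fit_exp_cdf(cdf, n_phases = 1)
  expect_equal(f$k_obs, 1.2, tolerance = 1e-6)
  expect_lt(f$chi2, 1e-12)
})

test_that("double-exponential fits recover transient-block eigenvalues", {
  ## homopolymeric-DNA unbinding rates: apparent rates of the exact CDF
  ## equal the eigenvalues of [[-(km2+k3), km3], [k3, -km3]]
  r <- c(km2 = 0.66, k3 = 0.36, km3 = 0.222)
  cdf <- model_cdf("unbinding", r, NA_real_, tmax = 80)
  f <- fit_exp_cdf(cdf, n_phases = 2)
  Q <- transient_generator(unbinding_subscheme(), as.data.frame(as.list(r)))
  ev <- sort(-eigen(Q)$values, decreasing = TRUE)
  expect_equal(f$n_phases, 2L)
  expect_equal(f$k_obs, ev, tolerance = 1e-4)
  expect_equal(sum(f$amplitudes), 1)
  ## and for the binding side across random rate sets
  for (i in 1:10) {
    set.seed(700 + i)
    k <- runif(3, 0.05, 2)
    C <- runif(1, 1, 10)
    cdfb <- model_cdf("binding", c(k1 = k[1], km1 = k[2], k2 = k[3]), C,
                      tmax = 30 / min(k), dt = 0.02)
    fb <- fit_exp_cdf(cdfb, n_phases = 2)
    Qb <- transient_generator(binding_subscheme(),
                              rate_set(k[1], k[2], k[3]), C)
    evb <- sort(-eigen(Qb)$values, decreasing = TRUE)
    expect_equal(fb$k_obs, evb, tolerance = 1e-4)
  }
})

test_that("a double fit of single-exponential data is flagged degenerate", {
  tg <- seq(0.05, 12, by = 0.05)
  cdf <- list(time = tg, cdf = 1 - exp(-0.8 * tg))
  f <- fit_exp_cdf(cdf, n_phases = 2)
  expect_true(f$degenerate)
  expect_equal(f$n_phases, 1L)              # single-phase fallback
  expect_equal(f$k_obs, 0.8, tolerance = 1e-5)
})

test_that("double chi2 never exceeds single chi2; phase contrast is clean on exact CDFs", {
  ## sampled 4-state world: chi2 ordering always holds
  d4 <- simulate_dwells("unbinding", ref_rates(), n = 3000, seed = 42)
  c4 <- build_cdf(d4, frame_dt = 0.05)
  f1 <- fit_exp_cdf(c4, 1); f2 <- fit_exp_cdf(c4, 2)
  expect_lte(f2$chi2, f1$chi2)
  ## exact 4-state CDF: the second phase is overwhelmingly significant
  tg <- seq(0.05, 80, by = 0.05)
  e4 <- list(time = tg, cdf = predict_unbinding_cdf(
    c(km2 = 0.66, k3 = 0.36, km3 = 0.222), tg))
  g1 <- fit_exp_cdf(e4, 1); g2 <- fit_exp_cdf(e4, 2)
  N <- length(tg)
  Fstat <- (g1$chi2 - g2$chi2) / 2 / (g2$chi2 / (N - 3))
  expect_gt(Fstat, qf(0.9999, 2, N - 3))
  ## exact k3 = 0 (anchored regime): truth is single-exponential and the
  ## double fit collapses onto it
  eT <- list(time = tg, cdf = predict_unbinding_cdf(
    c(km2 = 0.48, k3 = 0, km3 = 0.31), tg))
  h2 <- fit_exp_cdf(eT, 2)
  expect_true(h2$degenerate)
  expect_equal(h2$k_obs, 0.48, tolerance = 1e-5)
})

test_that("F-test confidence intervals behave like profile intervals", {
  ## exact data: interval width collapses toward zero
  tg <- seq(0.05, 10, by = 0.05)
  f <- fit_exp_cdf(list(time = tg, cdf = 1 - exp(-1.5 * tg)), 1)
  ci <- ftest_ci(f, level = 0.68)
  expect_lt(ci$upper - ci$lower, 1e-4 * f$k_obs)

  ## noisy single-exponential: F-test CI vs linearized (Gauss-Newton) SE
  set.seed(8)
  emp <- 1 - exp(-0.9 * tg) + rnorm(length(tg), 0, 0.01)
  fn <- fit_exp_cdf(list(time = tg, cdf = emp), 1)
  ci_n <- ftest_ci(fn, level = 0.68)
  k <- fn$k_obs
  J <- tg * exp(-k * tg)                    # d model / d k
  sigma2 <- fn$chi2 / (length(tg) - 1)
  se <- sqrt(sigma2 / sum(J^2))
  half_f <- (ci_n$upper - ci_n$lower) / 2
  half_t <- qt(0.84, length(tg) - 1) * se
  expect_equal(half_f, half_t, tolerance = 0.05)

  ## nested levels
  ci_lo <- ftest_ci(fn, level = 0.674)
  expect_gte(ci_n$upper, ci_lo$upper)
  expect_lte(ci_n$lower, ci_lo$lower)
})

test_that("runs test separates random from structured residuals", {
  set.seed(14)
  rnd <- rnorm(200)
  expect_gt(runs_test(rnd)$p.value, 0.05)
  structured <- sin(seq(0, 2 * pi, length.out = 200))
  expect_lt(runs_test(structured)$p.value, 1e-6)
})

test_that("apparent rates decompose into slope and mean against concentration", {
  ## exact bimolecular line
  s1 <- data.frame(conc = c(1, 5, 15), phase = 1,
                   k_obs = c(1.1, 5.5, 16.5))
  d1 <- concentration_decomposition(s1)
  expect_equal(d1$type, "dependent")
  expect_equal(d1$slope, 1.1, tolerance = 1e-12)
  expect_equal(d1$intercept, 0, tolerance = 1e-12)
  ## flat isomerization phase at the magnitude seen for the slow phase
  s2 <- data.frame(conc = c(1, 5, 15), phase = 2, k_obs = rep(0.14, 3))
  d2 <- concentration_decomposition(s2)
  expect_equal(d2$type, "flat")
  expect_equal(d2$mean_rate, 0.14)
  ## the fast apparent binding rate approaches slope k2 as k1, km1 -> 0
  concs <- c(2, 6, 12, 20)
  kfast <- vapply(concs, function(C) {
    cdf <- model_cdf("binding", c(k1 = 1e-4, km1 = 1e-4, k2 = 0.8), C,
                     tmax = 10, dt = 0.01)
    fit_exp_cdf(cdf, 1)$k_obs
  }, numeric(1))
  dd <- concentration_decomposition(
    data.frame(conc = concs, phase = "fast", k_obs = kfast))
  expect_equal(dd$type, "dependent")
  expect_equal(dd$slope, 0.8, tolerance = 1e-3)
  ## override and error paths
  ov <- concentration_decomposition(s1, classify = c("1" = "flat"))
  expect_equal(ov$type, "flat")
  expect_error(concentration_decomposition(
    data.frame(conc = 1, phase = 1, k_obs = 0.5)), ">= 2")
})
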