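test_that("fret_efficiency applies the leakage/background corrections", {
  tr <- data.frame(donor = c(55, 100, 100, 10), acceptor = c(45, 0, 20, -10))
  e0 <- fret_efficiency(tr)
  expect_equal(e0$E[1], 0.45)
  expect_equal(e0$E[2], 0)                       # donor-only limit
  e1 <- fret_efficiency(data.frame(donor = 100, acceptor = 20), leakage = 0.1)
  expect_equal(e1$E, 10 / 110)
  ## invalid frame: corrected total <= 0
  e2 <- fret_efficiency(data.frame(donor = 5, acceptor = 5),
                        background_d = 10, background_a = 10)
  expect_false(e2$valid)
  ## scale invariance with zero corrections
  set.seed(2)
  d <- runif(50, 10, 100); a <- runif(50, 10, 100)
  eA <- fret_efficiency(data.frame(donor = d, acceptor = a))
  eB <- fret_efficiency(data.frame(donor = 3.7 * d, acceptor = 3.7 * a))
  expect_equal(eA$E, eB$E)
  expect_error(fret_efficiency(tr, leakage = 1), "leakage")
})

test_that("fret_histogram pools leading frames and flags bad inputs", {
  mk <- function(E, n = 10) data.frame(donor = 100 * (1 - E) ,
                                       acceptor = 100 * E,
                                       frame = seq_len(n))[seq_len(n), ]
  donors <- replicate(20, mk(0), simplify = FALSE)
  br <- seq(-0.225, 1.225, by = 0.05)      # bin centers on the level values
  h <- fret_histogram(donors, n_frames = 5, breaks = br)
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts[abs(h$mids) < 0.026]), 100)
  mixed <- c(replicate(10, mk(0), simplify = FALSE),
             replicate(10, mk(0.45), simplify = FALSE))
  h2 <- fret_histogram(mixed, n_frames = 5, breaks = br)
  expect_equal(sum(h2$counts[abs(h2$mids) < 0.026]), 50)
  expect_equal(sum(h2$counts[abs(h2$mids - 0.45) < 0.026]), 50)
  expect_error(fret_histogram(list(mk(0, n = 3)), n_frames = 5), "shorter")
})

test_that("two-limit idealization implements hysteresis", {
  ## noiseless square wave: segments match the plateaus exactly
  sq <- rep(c(0, 1, 0, 1, 0), times = c(10, 5, 8, 7, 4))
  id <- threshold_idealize(sq, 0.3, 0.7, frame_dt = 0.05)
  expect_equal(id$class, c("low", "high", "low", "high", "low"))
  expect_equal(id$end_frame - id$start_frame + 1L, c(10L, 5L, 8L, 7L, 4L))

  ## always above the high limit: one segment
  id2 <- threshold_idealize(rep(0.9, 25), 0.3, 0.7)
  expect_equal(nrow(id2), 1)
  expect_equal(id2$class, "high")

  ## dead-band excursions do not switch the class
  sig <- c(0.1, 0.1, 0.5, 0.6, 0.1, 0.8, 0.8, 0.5, 0.35, 0.8, 0.1)
  id3 <- threshold_idealize(sig, 0.3, 0.7)
  expect_equal(id3$class, c("low", "high", "low"))
  expect_equal(id3$start_frame, c(1L, 6L, 11L))

  ## constant signal between the limits: initial class by nearest limit
  expect_warning(id4 <- threshold_idealize(rep(0.65, 10), 0.3, 0.7), "never crosses")
  expect_equal(id4$class, "high")
  expect_warning(id5 <- threshold_idealize(rep(0.4, 10), 0.3, 0.7), "never crosses")
  expect_equal(id5$class, "low")
  expect_error(threshold_idealize(sq, 0.7, 0.3), "low_limit")
})

test_that("idealization recovers simulated transitions through noise", {
  ## slow four-state world at 10% intensity noise; truth transitions are
  ## quantized to the first full frame of the new class, recovery is
  ## within +-1 frame of that, and "spurious" means a boundary more than
  ## 3 frames from any true transition (late detections are not spurious)
  rs <- rate_set(k1 = 0.1, km1 = 0.4, k2 = 0.06, km2 = 0.4, k3 = 0.15,
                 km3 = 0.15)
  n_true <- 0; n_found <- 0; n_spur <- 0
  for (i in 1:15) {
    cfg <- sim_config(rs, dna = 5, t_max = 300, frame_dt = 0.05,
                      noise_sd = 10, total_intensity = 100, seed = 500 + i)
    p <- gillespie_simulate(cfg)
    E <- fret_efficiency(emit_trace(p, cfg))
    id <- suppressWarnings(threshold_idealize(E$E, 0.15, 0.36,
                                              frame_dt = 0.05))
    cls <- rle(p$class)
    t_true <- p$t_entry[cumsum(cls$lengths)[-length(cls$lengths)] + 1L]
    f_true <- floor(t_true / 0.05) + 1L
    f_found <- id$start_frame[-1] - 1L
    n_true <- n_true + length(f_true)
    for (ft in f_true)
      if (any(abs(f_found - ft) <= 1)) n_found <- n_found + 1
    for (ff in f_found)
      if (!any(abs(f_true - ff) <= 3)) n_spur <- n_spur + 1
  }
  expect_gt(n_true, 100)
  expect_gte(n_found / n_true, 0.95)
  expect_lte(n_spur / n_true, 0.05)
})

test_that("extract_dwells counts frames and censors the trace ends", {
  id <- threshold_idealize(rep(c(0, 1, 0, 1, 0), times = c(10, 5, 8, 7, 4)),
                           0.3, 0.7, frame_dt = 0.05)
  d <- extract_dwells(id)
  expect_equal(d$class, c("high", "low", "high"))
  expect_equal(d$dwell_s, c(0.25, 0.40, 0.35))
  expect_false(any(d$censored))
  dall <- extract_dwells(id, keep_censored = TRUE)
  expect_equal(nrow(dall), 5)
  expect_equal(sum(dall$censored), 2)

  two_seg <- threshold_idealize(rep(c(0, 1), each = 6), 0.3, 0.7, frame_dt = 0.1)
  expect_warning(d2 <- extract_dwells(two_seg), "fewer than 3")
  expect_equal(nrow(d2), 0)
})

test_that("noiseless idealization reproduces ground truth to frame precision", {
  rs <- rate_set(k1 = 0.1, km1 = 0.1, k2 = 0.1, km2 = 0.2, k3 = 0.05, km3 = 0.05)
  cfg <- sim_config(rs, dna = 5, t_max = 400, frame_dt = 0.05, noise_sd = 0,
                    seed = 77)
  p <- gillespie_simulate(cfg)
  tr <- emit_trace(p, cfg)
  id <- threshold_idealize(fret_efficiency(tr)$E, 0.15, 0.30, frame_dt = 0.05)
  ## every true class boundary whose flanking dwells exceed one frame has
  ## a recovered boundary within one frame (sub-frame dwells are below
  ## the quantization floor by construction and are exempt)
  cls <- rle(p$class)
  idx <- cumsum(cls$lengths)
  t_bound <- p$t_entry[idx[-length(idx)] + 1L]
  starts <- p$t_entry[c(1, idx[-length(idx)] + 1L)]
  ends <- c(t_bound, attr(p, "t_max"))
  dw_len <- ends - starts
  ok_flank <- dw_len[-length(dw_len)] > 0.05 & dw_len[-1] > 0.05
  f_true <- floor(t_bound / 0.05) + 1L
  f_found <- id$start_frame[-1] - 1L
  expect_gt(sum(ok_flank), 20)
  for (ft in f_true[ok_flank])
    expect_true(any(abs(f_found - ft) <= 1))
  ## occupancy is conserved: total idealized high time matches the true
  ## bound time to within one frame per transition
  high_s <- sum((id$end_frame - id$start_frame + 1L)[id$class == "high"]) * 0.05
  true_bound_s <- sum((p$t_exit - p$t_entry)[p$class == "bound"])
  expect_lt(abs(high_s - true_bound_s), 0.05 * (length(f_true) + 1))
})

test_that("build_cdf counts dwells on the exposure-time grid", {
  d <- dwell_set(rep("low", 4), c(0.05, 0.10, 0.10, 0.20), rep(FALSE, 4),
                 frame_dt = 0.05)
  cdf <- build_cdf(d)
  expect_equal(cdf$time, c(0.05, 0.10, 0.15, 0.20))
  expect_equal(cdf$cdf, c(0.25, 0.75, 0.75, 1.0))
  ## single dwell: one step to 1
  c1 <- build_cdf(dwell_set("low", 0.30, FALSE, frame_dt = 0.1))
  expect_equal(c1$cdf[length(c1$cdf)], 1)
  expect_true(all(diff(c1$cdf) >= 0))
  ## order invariance
  set.seed(4)
  x <- rexp(500, 2)
  ca <- build_cdf(x, frame_dt = 0.01)
  cb <- build_cdf(sample(x), frame_dt = 0.01)
  expect_identical(ca$cdf, cb$cdf)
  ## analytic check against the exponential law
  set.seed(5)
  y <- rexp(10000, 1)
  cy <- build_cdf(y, frame_dt = 0.01)
  expect_lt(max(abs(cy$cdf - (1 - exp(-cy$time)))), 0.02)
  expect_error(build_cdf(numeric(), frame_dt = 0.05), "no complete dwells")
})
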