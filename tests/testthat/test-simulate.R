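two_state <- function() kinetic_scheme(
  data.frame(id = c("A", "B"), class = c("u", "b")),
  data.frame(from = c("A", "B"), to = c("B", "A"),
             rate = c("k2", "km2"), ligand_order = c(0L, 0L)))

test_that("gillespie paths are contiguous, deterministic and seeded", {
  cfg <- sim_config(ref_rates(), dna = 5, t_max = 200, seed = 42)
  p1 <- gillespie_simulate(cfg)
  p2 <- gillespie_simulate(cfg)
  expect_identical(p1, p2)
  p3 <- gillespie_simulate(sim_config(ref_rates(), dna = 5, t_max = 200, seed = 43))
  expect_false(identical(p1, p3))
  expect_equal(p1$t_entry[1], 0)
  expect_equal(p1$t_entry[-1], p1$t_exit[-nrow(p1)])
  expect_true(all(diff(p1$t_entry) > 0))
  expect_equal(p1$t_exit[nrow(p1)], 200)
})

test_that("dwells in a single-exit state are Exp(k) with the right mean", {
  ## one long reversible two-state run: ~1e5 dwells in A, each Exp(1)
  rates <- c(k2 = 1, km2 = 20)
  cfg <- sim_config(rate_set(k2 = 1, km2 = 20), dna = 1, t_max = 21000,
                    frame_dt = 0.05, seed = 7)
  path <- gillespie_simulate(cfg, two_state(), init = "A")
  dw <- dwells_from_path(path, class_map = c(A = "u", B = "b"))
  a <- dw$dwell_s[dw$class == "u"]
  expect_gt(length(a), 15000)
  expect_equal(mean(a), 1.0, tolerance = 0.03)
  ## KS against the analytic exponential law, alpha = 0.01
  set.seed(1)
  ks <- stats::ks.test(sample(a, 10000), "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("absorbing traps are reported, not looped on", {
  pure_decay <- kinetic_scheme(
    data.frame(id = c("A", "B"), class = c("u", "b")),
    data.frame(from = "A", to = "B", rate = "k2", ligand_order = 0L))
  cfg <- sim_config(rate_set(k2 = 1), dna = 1, t_max = 100, seed = 3)
  expect_warning(p <- gillespie_simulate(cfg, pure_decay, init = "A"),
                 "absorbing trap")
  expect_true(attr(p, "trapped"))
  expect_equal(p$state[nrow(p)], "B")
  expect_equal(p$t_exit[nrow(p)], 100)
})

test_that("occupancy converges to the stationary distribution", {
  rs <- ref_rates()
  cfg <- sim_config(rs, dna = 15, t_max = 1e4, seed = 11)
  p <- gillespie_simulate(cfg)
  occ_bound <- sum((p$t_exit - p$t_entry)[p$class == "bound"]) / 1e4
  pi_ <- stationary_distribution(four_state_scheme(), rs, dna = 15)
  expect_equal(occ_bound, sum(pi_[c("TALE*~DNA", "TALE++~DNA")]),
               tolerance = 0.02)
})

test_that("dwells_from_path merges classes and censors the terminal dwell", {
  p <- make_path(c("A", "B", "A"), c("unbound", "unbound", "unbound"),
                 c(0, 1.0, 1.5), c(1.0, 1.5, 4.0))
  d0 <- dwells_from_path(p)
  expect_equal(nrow(d0), 0)                 # lone dwell is right-censored
  dc <- dwells_from_path(p, keep_censored = TRUE)
  expect_equal(nrow(dc), 1)
  expect_equal(dc$dwell_s, 4.0)
  expect_true(dc$censored)

  p2 <- make_path(c("U", "B", "U"), c("unbound", "bound", "unbound"),
                  c(0, 2.0, 3.0), c(2.0, 3.0, 3.5))
  d2 <- dwells_from_path(p2)
  expect_equal(d2$class, c("unbound", "bound"))
  expect_equal(d2$dwell_s, c(2.0, 1.0))

  expect_warning(de <- dwells_from_path(make_path(character(), character(),
                                                  numeric(), numeric())),
                 "empty")
  expect_equal(nrow(de), 0)

  expect_error(dwells_from_path(p2, class_map = c(U = "unbound")),
               "class_map missing")
})

test_that("mean unbound dwell matches the condensed-scheme MFPT oracle", {
  rs <- ref_rates()
  d <- simulate_dwells("binding", rs, dna = 5, n = 20000, seed = 99)
  ## oracle: mean first-passage time = -1' Q^-1 p0 on the transient block
  Q <- transient_generator(binding_subscheme(), rs, 5)
  p0 <- c("TALE" = 0, "TALE*" = 1)[rownames(Q)]
  mfpt <- -sum(solve(Q, p0))
  expect_equal(mean(d), mfpt, tolerance = 0.03)
})

test_that("emit_trace averages the FRET level over each frame", {
  rs <- rate_set(k1 = 1)                     # rates irrelevant to emission
  cfg <- sim_config(rs, dna = 1, t_max = 0.25, frame_dt = 0.05,
                    noise_sd = 0, total_intensity = 100, seed = 5)
  ## entirely high-FRET path
  p_hi <- make_path("X", "bound", 0, 0.25)
  tr <- emit_trace(p_hi, cfg)
  expect_equal(nrow(tr), 5)
  expect_equal(tr$acceptor, rep(45, 5))
  expect_equal(tr$donor, rep(55, 5))

  ## transition exactly at a frame boundary: clean step, no blur
  p_edge <- make_path(c("U", "X"), c("unbound", "bound"),
                      c(0, 0.10), c(0.10, 0.25))
  tr2 <- emit_trace(p_edge, cfg)
  expect_equal(tr2$acceptor, c(0, 0, 45, 45, 45))

  ## mid-frame transition: time-weighted average 0.6*0 + 0.4*0.45 = 0.18
  p_mid <- make_path(c("U", "X"), c("unbound", "bound"),
                     c(0, 0.03), c(0.03, 0.25))
  tr3 <- emit_trace(p_mid, cfg)
  expect_equal(tr3$acceptor[1], 100 * 0.18)
  expect_equal(tr3$acceptor[2], 45)
})

test_that("sim_config rejects invalid worlds", {
  expect_error(sim_config(ref_rates(), dna = -1), "dna")
  expect_error(sim_config(ref_rates(), frame_dt = 0), "frame_dt")
  expect_error(sim_config(ref_rates(), t_max = 0.01, frame_dt = 0.05), "t_max")
  expect_error(sim_config(ref_rates(), fret_levels = c(unbound = -0.1, bound = 2)),
               "fret_levels")
  expect_error(rate_set(k1 = -1), "rate constants")
})
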