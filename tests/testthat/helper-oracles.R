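## Independent oracles used across the suite. None of these share code
## with the package's solution paths.

## survival via Matrix::expm (third, external route for first-passage CDFs)
expm_surv <- function(Q, p0, tgrid) {
  vapply(tgrid, function(t)
    sum(as.matrix(Matrix::expm(Q * t)) %*% p0), numeric(1))
}

## fixed-step RK4 integration of dp/dt = Q p, suitable for mild stiffness
rk4_surv <- function(Q, p0, tgrid, h = NULL) {
  if (is.null(h)) h <- 0.002 / max(abs(diag(Q)))
  f <- function(p) Q %*% p
  p <- matrix(p0, ncol = 1)
  t <- 0
  out <- numeric(length(tgrid))
  for (i in seq_along(tgrid)) {
    while (t < tgrid[i] - 1e-12) {
      hh <- min(h, tgrid[i] - t)
      k1 <- f(p); k2 <- f(p + hh / 2 * k1)
      k3 <- f(p + hh / 2 * k2); k4 <- f(p + hh * k3)
      p <- p + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[i] <- sum(p)
  }
  out
}

## closed-form double-exponential binding CDF derived independently from
## the eigenvalues of [[-k1, km1], [k1, -(km1+b)]] with p0 = (0, 1)
closed_binding_cdf <- function(k1, km1, b, t) {
  s <- k1 + km1 + b
  p <- k1 * b
  lp <- (s + sqrt(s^2 - 4 * p)) / 2
  lm <- (s - sqrt(s^2 - 4 * p)) / 2
  ap <- (b - lm) / (lp - lm)
  am <- (lp - b) / (lp - lm)
  1 - ap * exp(-lp * t) - am * exp(-lm * t)
}

## Boltzmann statistical-weight ratio oracle for Ising conformations:
## w(conf) computed multiplicatively per element, ddG = -RT log ratio
weight_ddG <- function(model, conf) {
  w <- function(folded, intact) {
    prod(exp(-model$dg_intrinsic[folded] / model$RT)) *
      prod(exp(-model$dg_interface[intact] / model$RT))
  }
  n <- model$n_repeats
  -model$RT * log(w(conf$folded, conf$intact) /
                    w(rep(TRUE, n), rep(TRUE, n - 1)))
}

## random strictly positive rate sets under the fixed seed of the caller
random_rates <- function(lo = 0.01, hi = 10) {
  r <- stats::runif(6, log(lo), log(hi))
  rate_set(exp(r[1]), exp(r[2]), exp(r[3]), exp(r[4]), exp(r[5]), exp(r[6]))
}

## hand-built state path with the attributes gillespie_simulate() sets
make_path <- function(state, class, t_entry, t_exit, dna = NA_real_) {
  structure(data.frame(state = state, class = class,
                       t_entry = t_entry, t_exit = t_exit,
                       stringsAsFactors = FALSE),
            seed = 0L, dna = dna, t_max = t_exit[length(t_exit)],
            class = c("state_path", "data.frame"))
}

## reference rates: the eight-repeat construct bound to homopolymeric DNA
ref_rates <- function() rate_set(0.17, 0.13, 1.1, 0.66, 0.36, 0.222)

## model-exact CDF packaged as a dwell_cdf for the fitters
model_cdf <- function(side, rates, conc, tmax = 60, dt = 0.05) {
  tg <- seq(dt, tmax, by = dt)
  v <- if (side == "binding") predict_binding_cdf(rates, conc, tg)
       else predict_unbinding_cdf(rates, tg)
  structure(list(time = tg, cdf = v, n_dwells = NA_integer_,
                 concentration = conc, frame_dt = dt),
            class = "dwell_cdf")
}
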