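## Model-independent exponential-mixture analysis of dwell-time CDFs.

exp_mix_cdf <- function(k, A, tgrid) {
  m <- 0
  for (i in seq_along(k)) m <- m + A[i] * exp(-k[i] * tgrid)
  1 - m
}

exp_ssr1 <- function(logk, tgrid, emp) sum((1 - exp(-exp(logk) * tgrid) - emp)^2)

exp_ssr2 <- function(par, tgrid, emp) {
  k <- exp(par[1:2]); A1 <- stats::plogis(par[3])
  sum((exp_mix_cdf(k, c(A1, 1 - A1), tgrid) - emp)^2)
}

#' Single- or double-exponential fit of an empirical dwell-time CDF
#'
#' Fits `CDF(t) = 1 - sum(A_i exp(-k_i t))` with amplitudes constrained to
#' sum to one, by least squares on the CDF grid (the same surface the
#' deterministic model is fitted on, so apparent rates are directly
#' comparable with transient-generator eigenvalues). For `n_phases = 2`,
#' rates are reported sorted descending with matching amplitudes; a double
#' fit that collapses (equal rates, or a vanishing amplitude) is flagged
#' degenerate and the single-phase result is returned as fallback.
#'
#' @param cdf a `dwell_cdf` (or list with `time`, `cdf`).
#' @param n_phases 1 or 2.
#' @return An `exp_fit`: `n_phases`, `k_obs` (s^-1, descending),
#'   `amplitudes`, `residuals`, `chi2` (SSR), `dof`, `degenerate`,
#'   `concentration`.
#' @export
fit_exp_cdf <- function(cdf, n_phases = 2) {
  stopifnot(n_phases %in% 1:2)
  tgrid <- cdf$time; emp <- cdf$cdf
  npar <- if (n_phases == 2) 3L else 1L
  if (length(tgrid) < 5 * npar)
    stop("need at least ", 5 * npar, " grid points for a ", n_phases, "-phase fit")
  ## crude rate scale: time to reach CDF = 0.63
  i63 <- which(emp >= 0.632)[1]
  k0 <- 1 / tgrid[if (is.na(i63)) length(tgrid) else i63]
  o1 <- stats::optim(log(k0), exp_ssr1, method = "Brent",
                     lower = log(1e-8), upper = log(1e6),
                     tgrid = tgrid, emp = emp)
  fit1 <- list(n_phases = 1L, k_obs = exp(o1$par), amplitudes = 1,
               chi2 = o1$value,
               residuals = emp - (1 - exp(-exp(o1$par) * tgrid)),
               dof = length(tgrid) - 1L, degenerate = FALSE,
               time = tgrid, emp = emp,
               concentration = cdf$concentration %||% NA_real_)
  class(fit1) <- "exp_fit"
  if (n_phases == 1) return(fit1)
  ## tail-based start: the late log-survival slope estimates the slow rate
  ## and amplitude; the fast rate starts a decade above it
  surv <- pmax(1 - emp, 1e-12)
  tail_i <- which(surv < 0.5 & surv > 1e-6)
  starts <- list(c(o1$par + log(3), o1$par - log(3), 0),
                 c(o1$par + log(10), o1$par - log(10), 0))
  if (length(tail_i) > 5) {
    co <- stats::coef(stats::lm(log(surv[tail_i]) ~ tgrid[tail_i]))
    k_slow <- max(-co[2], 1e-8)
    a_slow <- min(max(exp(co[1]), 1e-6), 1 - 1e-6)
    starts <- c(list(c(log(k_slow * 10), log(k_slow),
                       stats::qlogis(1 - a_slow))), starts)
  }
  o2 <- NULL
  for (p0 in starts) {
    o <- stats::optim(p0, exp_ssr2, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14),
                      tgrid = tgrid, emp = emp)
    if (is.null(o2) || o$value < o2$value) o2 <- o
  }
  k <- exp(o2$par[1:2]); A <- stats::plogis(o2$par[3]); A <- c(A, 1 - A)
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; A <- A[ord]
  ## degenerate double fits: rates collapsed together, a vanishing
  ## amplitude, or no real improvement over the single fit
  degen <- (k[1] - k[2]) < 5e-3 * k[1] || min(A) < 1e-3 ||
    o2$value >= fit1$chi2 * (1 - 1e-9)
  if (degen) {
    fit1$degenerate <- TRUE
    return(fit1)
  }
  structure(list(n_phases = 2L, k_obs = k, amplitudes = A,
                 chi2 = o2$value,
                 residuals = emp - exp_mix_cdf(k, A, tgrid),
                 dof = length(tgrid) - 3L, degenerate = FALSE,
                 time = tgrid, emp = emp,
                 concentration = cdf$concentration %||% NA_real_),
            class = "exp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%d-phase exponential CDF fit (chi2 = %.4g, dof = %d)%s\n",
              x$n_phases, x$chi2, x$dof,
              if (x$degenerate) " [degenerate double fit: single returned]" else ""))
  for (i in seq_len(x$n_phases))
    cat(sprintf("  k%d = %.4g s-1  (amplitude %.3f)\n",
                i, x$k_obs[i], x$amplitudes[i]))
  invisible(x)
}

## objective with parameter j of the full parameterization fixed
profile_chi2 <- function(fit, j, value) {
  tgrid <- fit$time; emp <- fit$emp
  if (fit$n_phases == 1L) return(exp_ssr1(log(value), tgrid, emp))
  full <- c(log(fit$k_obs), stats::qlogis(fit$amplitudes[1]))
  fx <- if (j <= 2) log(value) else stats::qlogis(value)
  free0 <- full[-j]
  obj <- function(free) {
    par <- numeric(3); par[-j] <- free; par[j] <- fx
    exp_ssr2(par, tgrid, emp)
  }
  stats::optim(free0, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-13))$value
}

#' F-test (profile) confidence intervals for an exponential fit
#'
#' Profiles each parameter: with the parameter fixed away from its
#' estimate and all others re-optimized, the fit is accepted while
#' `F = (chi2_fixed / chi2_best - 1) * (N - P) <= qf(level, 1, N - P)`.
#' Interval bounds are bracketed by multiplicative stepping and refined by
#' bisection; an unbounded profile reports the search limit with a flag.
#'
#' @param fit an `exp_fit`.
#' @param level confidence level (0.68 or 0.674 are the conventional
#'   single-parameter choices).
#' @param search_factor multiplicative search limit around each estimate.
#' @return data.frame with `parameter`, `estimate`, `lower`, `upper`,
#'   `lower_limited`, `upper_limited`.
#' @export
ftest_ci <- function(fit, level = 0.68, search_factor = 1e3) {
  stopifnot(inherits(fit, "exp_fit"))
  N <- length(fit$time)
  P <- if (fit$n_phases == 2L) 3L else 1L
  if (N - P <= 0) stop("no residual degrees of freedom")
  fcrit <- stats::qf(level, 1, N - P)
  chi2_0 <- fit$chi2
  ## guard exact-data fits: a zero best chi2 makes the F ratio singular
  chi2_0 <- max(chi2_0, .Machine$double.eps * N)
  fstat <- function(j, v) (profile_chi2(fit, j, v) / chi2_0 - 1) * (N - P)
  pars <- c(paste0("k", seq_len(fit$n_phases)),
            if (fit$n_phases == 2L) "A1")
  est <- c(fit$k_obs, if (fit$n_phases == 2L) fit$amplitudes[1])
  one_bound <- function(j, e, dir) {
    is_amp <- fit$n_phases == 2L && j == 3L
    lim <- if (is_amp) {
      if (dir > 0) 1 - 1e-6 else 1e-6
    } else {
      if (dir > 0) e * search_factor else e / search_factor
    }
    step_to <- function(v, frac) if (is_amp) v + frac * (lim - v) else
      v * (lim / v)^frac
    ## bracket by geometric stepping toward the limit
    fr <- 0.02; v_in <- e; v_out <- NA; limited <- FALSE
    repeat {
      v <- step_to(e, fr)
      if (fstat(j, v) > fcrit) { v_out <- v; break }
      v_in <- v
      if (fr >= 1) { limited <- TRUE; v_out <- lim; break }
      fr <- min(fr * 2, 1)
    }
    if (limited) return(list(bound = lim, limited = TRUE))
    for (i in 1:40) {
      mid <- sqrt(abs(v_in * v_out)) * sign(v_in)
      if (is_amp) mid <- (v_in + v_out) / 2
      if (fstat(j, mid) > fcrit) v_out <- mid else v_in <- mid
      if (abs(v_out - v_in) < 1e-8 * max(abs(e), 1e-12)) break
    }
    list(bound = (v_in + v_out) / 2, limited = FALSE)
  }
  lo <- hi <- numeric(length(est)); lo_lim <- hi_lim <- logical(length(est))
  for (j in seq_along(est)) {
    bl <- one_bound(j, est[j], -1); bu <- one_bound(j, est[j], +1)
    lo[j] <- bl$bound; hi[j] <- bu$bound
    lo_lim[j] <- bl$limited; hi_lim[j] <- bu$limited
  }
  data.frame(parameter = pars, estimate = est, lower = lo, upper = hi,
             lower_limited = lo_lim, upper_limited = hi_lim,
             stringsAsFactors = FALSE)
}

#' Wald-Wolfowitz runs test for residual randomness
#'
#' Tests whether the signs of a residual vector alternate like exchangeable
#' noise (normal approximation). Large non-random residual stretches --
#' the diagnostic used to reject single-exponential fits -- give a small
#' p-value.
#'
#' @param x residual vector (zeros dropped).
#' @return list with `runs`, `n_pos`, `n_neg`, `z`, `p.value`.
#' @export
runs_test <- function(x) {
  s <- sign(x); s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(runs = 1, n_pos = n1, n_neg = n2, z = -Inf, p.value = 0))
  r <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / n
  v <- (mu - 1) * (mu - 2) / (n - 1)
  z <- (r - mu) / sqrt(v)
  list(runs = r, n_pos = n1, n_neg = n2, z = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Decompose apparent rates versus DNA concentration into rate constants
#'
#' Phases whose apparent rate rises linearly with concentration report a
#' bimolecular slope (nM^-1 s^-1) and intercept; concentration-independent
#' phases report their mean rate (s^-1). Classification defaults to a
#' linear-regression slope t-test at `alpha` and can be overridden.
#'
#' @param series data.frame with columns `conc` (nM), `phase`, `k_obs`
#'   (s^-1) and optionally `se` (used as inverse-variance weights).
#' @param alpha significance level of the slope test.
#' @param classify optional named character vector phase ->
#'   `"dependent"`/`"flat"` overriding the automatic call.
#' @param weighted use `1/se^2` weights when `se` is present.
#' @return data.frame with one row per phase: `phase`, `type`, `slope`
#'   (nM^-1 s^-1), `intercept` (s^-1), `mean_rate` (s^-1), `p_slope`.
#' @export
concentration_decomposition <- function(series, alpha = 0.05, classify = NULL,
                                        weighted = FALSE) {
  stopifnot(all(c("conc", "phase", "k_obs") %in% names(series)))
  out <- lapply(split(series, series$phase), function(d) {
    w <- if (weighted && !is.null(d$se)) 1 / d$se^2 else NULL
    if (nrow(d) < 2) stop("phase ", d$phase[1], ": need >= 2 concentrations")
    fm <- stats::lm(k_obs ~ conc, data = d, weights = w)
    co <- suppressWarnings(summary(fm)$coefficients)  # zero-residual lm warns
    p_slope <- if (nrow(co) >= 2 && is.finite(co[2, 4])) co[2, 4] else {
      ## zero-residual degenerate lm: classify by slope magnitude
      if (abs(stats::coef(fm)[2]) * diff(range(d$conc)) >
          1e-8 * max(abs(d$k_obs), 1e-300)) 0 else 1
    }
    type <- if (!is.null(classify) && d$phase[1] %in% names(classify))
      classify[[as.character(d$phase[1])]]
    else if (p_slope < alpha) "dependent" else "flat"
    mean_rate <- if (is.null(w)) mean(d$k_obs) else
      sum(w * d$k_obs) / sum(w)
    data.frame(phase = d$phase[1], type = type,
               slope = if (type == "dependent") unname(stats::coef(fm)[2]) else NA_real_,
               intercept = if (type == "dependent") unname(stats::coef(fm)[1]) else NA_real_,
               mean_rate = if (type == "flat") mean_rate else NA_real_,
               p_slope = p_slope, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
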