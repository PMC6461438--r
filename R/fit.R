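## Global deterministic fitting of dwell-time CDFs.
##
## The model CDF for either side of the scheme is a two-exponential
## survival complement with decay rates the eigenvalues of the 2x2
## transient generator; these closed forms are the hot path of the
## optimizer. The public predict_*_cdf() functions go through the general
## scheme machinery and are cross-checked against these in the tests.

dblexp_cdf <- function(s, p, dS0, tgrid) {
  disc <- max(s * s - 4 * p, 0)
  rp <- (s + sqrt(disc)) / 2
  rm <- (s - sqrt(disc)) / 2
  if ((rp - rm) > 1e-10 * max(rp, 1e-300)) {
    ap <- (-dS0 - rm) / (rp - rm)
    am <- 1 - ap
    1 - ap * exp(-rp * tgrid) - am * exp(-rm * tgrid)
  } else {
    r <- (rp + rm) / 2
    1 - (1 + (dS0 + r) * tgrid) * exp(-r * tgrid)
  }
}

binding_cdf_fast <- function(k1, km1, b, tgrid)
  dblexp_cdf(k1 + km1 + b, k1 * b, -b, tgrid)

unbinding_cdf_fast <- function(km2, k3, km3, tgrid)
  dblexp_cdf(km2 + k3 + km3, km2 * km3, -km2, tgrid)

fit_param_names <- function(side)
  if (side == "binding") c("k1", "km1", "k2") else c("km2", "k3", "km3")

## SSR over all concentrations for one side, parameters on log scale
global_ssr <- function(logpar, side, grids, emps, concs) {
  k <- exp(logpar)
  tot <- 0
  for (i in seq_along(grids)) {
    m <- if (side == "binding")
      binding_cdf_fast(k[1], k[2], k[3] * concs[i], grids[[i]])
    else
      unbinding_cdf_fast(k[1], k[2], k[3], grids[[i]])
    tot <- tot + sum((m - emps[[i]])^2)
  }
  tot
}

lhs_starts <- function(n, d, lo, hi) {
  u <- vapply(seq_len(d), function(j) (sample.int(n) - stats::runif(n)) / n,
              numeric(n))
  lo + u * (hi - lo)
}

## moment-style starting values: single-exponential apparent rates per CDF,
## decomposed into a concentration slope (k2) and intercept (isomerization)
default_init <- function(side, grids, emps, concs, bounds) {
  kobs <- vapply(seq_along(grids), function(i) {
    i63 <- which(emps[[i]] >= 0.632)[1]
    t63 <- grids[[i]][if (is.na(i63)) length(grids[[i]]) else i63]
    stats::optim(log(1 / t63), exp_ssr1, method = "Brent",
                 lower = log(1e-8), upper = log(1e6),
                 tgrid = grids[[i]], emp = emps[[i]])$par
  }, numeric(1))
  kobs <- exp(kobs)
  clamp <- function(x) pmin(pmax(x, bounds[1] * 1.0001), bounds[2] * 0.9999)
  if (side == "binding") {
    slope <- if (length(unique(concs)) > 1)
      unname(stats::coef(stats::lm(kobs ~ concs))[2]) else kobs[1] / concs[1]
    if (!is.finite(slope) || slope <= 0) slope <- mean(kobs / concs)
    base <- max(min(kobs) / 3, bounds[1] * 10)
    stats::setNames(clamp(c(base, base, slope)), c("k1", "km1", "k2"))
  } else {
    k <- mean(kobs)
    stats::setNames(clamp(c(k, k / 3, k / 3)), c("km2", "k3", "km3"))
  }
}

#' Global least-squares fit of microscopic rate constants to dwell CDFs
#'
#' Adjusts the three microscopic rate constants of one side of the scheme
#' (binding: k1, km1, k2; unbinding: km2, k3, km3) to minimize the plain
#' sum of squared residuals between the ODE-predicted CDF and empirical
#' dwell-time CDFs, fitted globally across DNA concentrations with shared
#' parameters. The model is evaluated exactly on each empirical grid.
#' Optimization is bounded (positivity via a log parameterization within
#' `bounds`) derivative-based least squares, optionally multi-started from
#' latin-hypercube points.
#'
#' @param cdfs list of `dwell_cdf` objects, one per concentration. For the
#'   binding side every CDF must carry its concentration; two or more
#'   distinct concentrations are recommended for identifiability.
#' @param side `"binding"` or `"unbinding"`.
#' @param init optional named starting values for the three rates.
#' @param bounds length-2 positivity bounds on every rate constant.
#' @param n_starts extra latin-hypercube starting points (log-uniform over
#'   `bounds` restricted to `[1e-3, 1e2]`) added to the moment-based
#'   default guess; the best final SSR wins. The global SSR surface has
#'   corner local minima (an instantly-saturating model), so multi-start
#'   is on by default.
#' @param seed RNG seed for the multi-start draw.
#' @return A `global_fit` object: fitted rates, `ssr`, per-concentration
#'   residual vectors, convergence and at-bound flags, and the inputs
#'   needed for bootstrapping.
#' @export
fit_global <- function(cdfs, side = c("binding", "unbinding"), init = NULL,
                       bounds = c(1e-6, 1e3), n_starts = 6, seed = 1L) {
  side <- match.arg(side)
  if (!length(cdfs)) stop("need at least one CDF")
  if (inherits(cdfs, "dwell_cdf")) cdfs <- list(cdfs)
  grids <- lapply(cdfs, `[[`, "time")
  emps <- lapply(cdfs, `[[`, "cdf")
  concs <- vapply(cdfs, `[[`, numeric(1), "concentration")
  if (side == "binding" && any(!is.finite(concs)))
    stop("binding-side CDFs must carry their DNA concentration")
  if (side == "unbinding") concs <- rep(1, length(cdfs))
  pn <- fit_param_names(side)
  if (is.null(init)) init <- default_init(side, grids, emps, concs, bounds)
  init <- init[pn]
  if (any(init < bounds[1] | init > bounds[2])) stop("init outside bounds")
  lo <- log(bounds[1]); hi <- log(bounds[2])
  starts <- matrix(log(init), nrow = 1)
  if (n_starts > 0) {
    set.seed(seed)
    starts <- rbind(starts,
                    lhs_starts(n_starts, 3, max(lo, log(1e-3)), min(hi, log(1e2))))
  }
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    o <- stats::optim(starts[r, ], global_ssr, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(factr = 1e4, pgtol = 1e-12, maxit = 500),
                      side = side, grids = grids, emps = emps, concs = concs)
    if (is.null(best) || o$value < best$value) best <- o
  }
  k <- stats::setNames(exp(best$par), pn)
  model <- lapply(seq_along(grids), function(i)
    if (side == "binding") binding_cdf_fast(k[1], k[2], k[3] * concs[i], grids[[i]])
    else unbinding_cdf_fast(k[1], k[2], k[3], grids[[i]]))
  res <- lapply(seq_along(grids), function(i) emps[[i]] - model[[i]])
  at_bound <- abs(best$par - lo) < 1e-6 | abs(best$par - hi) < 1e-6
  if (best$convergence == 52L) best$convergence <- 0L
  if (best$convergence != 0)
    warning("optimizer did not report convergence (code ", best$convergence,
            "); best point returned")
  if (any(at_bound))
    warning("parameter(s) at bound: ", paste(pn[at_bound], collapse = ", "))
  structure(list(side = side, rates = k, ssr = best$value,
                 residuals = res, model = model,
                 grids = grids, emps = emps, concs = concs,
                 converged = best$convergence == 0, at_bound = at_bound,
                 bounds = bounds, n_points = sum(lengths(grids))),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global %s-side fit over %d concentration(s), SSR = %.4g\n",
              x$side, length(x$grids), x$ssr))
  for (nm in names(x$rates)) {
    ci <- ""
    if (!is.null(x$bootstrap)) {
      b <- x$bootstrap
      ci <- sprintf("  [%.4g, %.4g] (%.0f%% bootstrap, mean %.4g)",
                    b$ci[1, nm], b$ci[2, nm], 100 * b$level, b$mean[nm])
    }
    cat(sprintf("  %-4s = %.4g%s\n", nm, x$rates[[nm]], ci))
  }
  if (!x$converged) cat("  (flagged: optimizer not converged)\n")
  invisible(x)
}

#' Residual-resampling bootstrap confidence intervals for a global fit
#'
#' For each iteration, synthetic CDFs are formed as the best-fit model
#' curves plus residuals resampled with replacement (separately within each
#' concentration's pool), then refitted starting from the best-fit point.
#' Percentile confidence intervals at `level` (15.9--84.1% for 0.68) and
#' the bootstrap mean of each parameter are reported.
#'
#' @param fit a converged `global_fit`.
#' @param n_iter bootstrap iterations (2000 is typical; 200 is enough for a
#'   coarse CI).
#' @param seed RNG seed.
#' @param level two-sided confidence level, default 0.68.
#' @return `fit` with a `bootstrap` element: `samples` (n_iter x 3),
#'   `ci` (2 x 3), `mean`, `level`, `n_fail`, `seed`.
#' @export
bootstrap_ci <- function(fit, n_iter = 2000, seed = 1L, level = 0.68) {
  stopifnot(inherits(fit, "global_fit"))
  if (!fit$converged)
    warning("bootstrapping a fit flagged as non-converged")
  set.seed(seed)
  pn <- names(fit$rates)
  lo <- log(fit$bounds[1]); hi <- log(fit$bounds[2])
  start <- log(fit$rates)
  samples <- matrix(NA_real_, n_iter, 3, dimnames = list(NULL, pn))
  n_fail <- 0L
  for (it in seq_len(n_iter)) {
    emps_b <- lapply(seq_along(fit$model), function(i)
      fit$model[[i]] + sample(fit$residuals[[i]], length(fit$residuals[[i]]),
                              replace = TRUE))
    o <- stats::optim(start, global_ssr, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(factr = 1e5, pgtol = 1e-10, maxit = 300),
                      side = fit$side, grids = fit$grids, emps = emps_b,
                      concs = fit$concs)
    ## code 52 is a line search stalled at machine precision (routine when
    ## the refit starts at, or lands on, an exact optimum)
    if (!o$convergence %in% c(0L, 52L)) n_fail <- n_fail + 1L
    samples[it, ] <- exp(o$par)
  }
  if (n_fail > 0.05 * n_iter)
    warning(n_fail, " of ", n_iter, " bootstrap refits failed to converge")
  a <- (1 - level) / 2
  ci <- apply(samples, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  ok <- ci["lower", ] <= fit$rates & fit$rates <= ci["upper", ]
  fit$bootstrap <- list(samples = samples, ci = ci,
                        mean = colMeans(samples), level = level,
                        n_iter = n_iter, n_fail = n_fail, seed = seed,
                        point_inside_ci = ok)
  fit
}
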