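#' Configuration for the end-to-end analysis pipeline
#'
#' Fixes every knob of the simulate -> idealize -> dwells -> cdf -> fit-exp
#' -> fit-model -> bootstrap -> derive chain. All stages are validated
#' before any stage runs; given the seeds the run is fully deterministic.
#'
#' @param out_dir run directory for artifacts.
#' @param rates ground-truth [rate_set()] for simulation, or `NULL` when
#'   `scheme_file` is given.
#' @param concentrations DNA concentrations, nM.
#' @param n_traces traces simulated per concentration.
#' @param t_max trace length, s.
#' @param frame_dt exposure time, s.
#' @param fret_levels class -> FRET efficiency map.
#' @param noise_sd,total_intensity emission model, intensity units.
#' @param thresholds two-limit idealization thresholds on the efficiency
#'   scale, `c(low =, high =)`.
#' @param n_boot bootstrap iterations per side.
#' @param ci_level bootstrap confidence level.
#' @param seed master integer seed; per-trace seeds are derived from it.
#' @param scheme_file optional scheme JSON (see [write_scheme()]) supplying
#'   the scheme and rates.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, rates = NULL, concentrations = c(1, 5, 15),
                            n_traces = 20, t_max = 200, frame_dt = 0.05,
                            fret_levels = c(unbound = 0, bound = 0.45),
                            noise_sd = 5, total_intensity = 100,
                            thresholds = c(low = 0.15, high = 0.30),
                            n_boot = 200, ci_level = 0.68, seed = 1L,
                            scheme_file = NULL) {
  cfg <- list(out_dir = out_dir, rates = rates,
              concentrations = concentrations, n_traces = n_traces,
              t_max = t_max, frame_dt = frame_dt, fret_levels = fret_levels,
              noise_sd = noise_sd, total_intensity = total_intensity,
              thresholds = thresholds, n_boot = n_boot, ci_level = ci_level,
              seed = as.integer(seed), scheme_file = scheme_file)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- doc[intersect(names(doc), names(formals(pipeline_config)))]
  if (!is.null(args$rates)) args$rates <- do.call(rate_set, as.list(args$rates))
  if (!is.null(args$fret_levels)) args$fret_levels <- unlist(args$fret_levels)
  if (!is.null(args$thresholds)) args$thresholds <- unlist(args$thresholds)
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration (and any referenced data) up front
#'
#' Checks file existence and schema, positivity of concentrations and
#' times, threshold ordering, and (when a dwell-file directory is given)
#' that every configured concentration has data. Problems are split into
#' errors (stop the pipeline) and warnings.
#'
#' @param config a `pipeline_config`.
#' @param dwell_dir optional directory of dwell CSVs to cross-check against
#'   `config$concentrations`.
#' @return list with `errors` and `warnings` character vectors; errors also
#'   raise a condition via [stop()] unless `quiet = TRUE`.
#' @param quiet return the report instead of stopping on errors.
#' @export
validate_inputs <- function(config, dwell_dir = NULL, quiet = FALSE) {
  errs <- character(); warns <- character()
  if (!is.null(config$scheme_file) && !file.exists(config$scheme_file))
    errs <- c(errs, paste0("scheme file not found: ", config$scheme_file))
  if (is.null(config$scheme_file) && is.null(config$rates))
    errs <- c(errs, "neither rates nor scheme_file supplied")
  if (any(config$concentrations <= 0))
    errs <- c(errs, "concentrations must be > 0")
  if (config$frame_dt <= 0 || config$t_max <= config$frame_dt)
    errs <- c(errs, "need frame_dt > 0 and t_max > frame_dt")
  if (!is.null(config$thresholds) &&
      !(config$thresholds[["low"]] < config$thresholds[["high"]]))
    errs <- c(errs, "thresholds: low must be < high")
  if (config$ci_level <= 0 || config$ci_level >= 1)
    errs <- c(errs, "ci_level must be in (0,1)")
  if (!is.null(dwell_dir)) {
    files <- list.files(dwell_dir, pattern = "\\.csv$", full.names = TRUE)
    found <- c()
    for (f in files) {
      d <- tryCatch(read_dwells(f), error = function(e)
        stop("malformed dwell file ", f, ": ", conditionMessage(e)))
      if (any(d$dwell_s < 0)) errs <- c(errs, paste0("negative dwell in ", f))
      found <- c(found, attr(d, "concentration"))
    }
    missing <- setdiff(config$concentrations, found)
    if (length(missing))
      warns <- c(warns, paste0("concentration(s) in config but not in data: ",
                               paste(missing, collapse = ", ")))
  }
  for (w in warns) warning(w, call. = FALSE)
  if (length(errs) && !quiet)
    stop("invalid pipeline configuration:\n  ", paste(errs, collapse = "\n  "))
  list(errors = errs, warnings = warns)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates `n_traces` molecules per DNA concentration from the four-state
#' scheme, idealizes the noisy traces with the two-limit threshold, pools
#' dwell times per concentration, builds empirical CDFs, performs the
#' model-independent exponential fits and the global deterministic fits of
#' both sides with bootstrap confidence intervals, and derives the
#' equilibrium summary. All artifacts (dwell CSVs, CDF CSVs, fit reports,
#' a machine-readable `summary.json`) are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stage("validate", validate_inputs(config))
  if (!is.null(config$scheme_file)) {
    sc <- read_scheme(config$scheme_file)
    scheme <- sc$scheme; rates <- sc$rates
  } else {
    scheme <- four_state_scheme(); rates <- as_rate_set(config$rates)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("master_seed = %d", config$seed)

  cls_map <- c(low = "unbound", high = "bound")
  cdfs_unbound <- list(); cdfs_bound <- list()
  exp_rows <- list()
  for (ci in seq_along(config$concentrations)) {
    conc <- config$concentrations[ci]
    pooled <- NULL
    for (tr in seq_len(config$n_traces)) {
      sd_i <- config$seed + 1000L * ci + 2L * tr
      cfg_i <- sim_config(rates, dna = conc, t_max = config$t_max,
                          frame_dt = config$frame_dt,
                          fret_levels = config$fret_levels,
                          noise_sd = config$noise_sd,
                          total_intensity = config$total_intensity,
                          seed = sd_i)
      path <- stage("simulate", gillespie_simulate(cfg_i, scheme))
      trace <- stage("simulate", emit_trace(path, cfg_i))
      E <- stage("idealize", fret_efficiency(trace))
      ideal <- stage("idealize", suppressWarnings(
        threshold_idealize(E$E, config$thresholds[["low"]],
                           config$thresholds[["high"]],
                           frame_dt = config$frame_dt)))
      dw <- stage("dwells", suppressWarnings(
        extract_dwells(ideal, concentration = conc)))
      pooled <- if (is.null(pooled)) dw else
        dwell_set(c(pooled$class, dw$class), c(pooled$dwell_s, dw$dwell_s),
                  c(pooled$censored, dw$censored),
                  concentration = conc, frame_dt = config$frame_dt)
    }
    pooled$class <- unname(cls_map[pooled$class])
    write_dwells(pooled, file.path(config$out_dir,
                                   sprintf("dwells_%gnM.csv", conc)))
    logf("concentration %g nM: %d complete dwells", conc, nrow(pooled))
    for (side_class in c("unbound", "bound")) {
      cdf <- stage("cdf", build_cdf(pooled, class_filter = side_class))
      write_cdf(cdf, file.path(config$out_dir,
                               sprintf("cdf_%s_%gnM.csv", side_class, conc)))
      if (side_class == "unbound") cdfs_unbound[[ci]] <- cdf
      else cdfs_bound[[ci]] <- cdf
      for (np in 1:2) {
        ef <- stage("fit-exp", fit_exp_cdf(cdf, n_phases = np))
        exp_rows[[length(exp_rows) + 1L]] <- data.frame(
          concentration = conc, class = side_class, n_phases = ef$n_phases,
          requested_phases = np, degenerate = ef$degenerate, chi2 = ef$chi2,
          k_obs = paste(fmt_num(ef$k_obs), collapse = ";"),
          amplitudes = paste(fmt_num(ef$amplitudes), collapse = ";"))
      }
    }
  }
  fit_b <- stage("fit-model", fit_global(cdfs_unbound, "binding",
                                         seed = config$seed + 11L))
  fit_u <- stage("fit-model", fit_global(cdfs_bound, "unbinding",
                                         seed = config$seed + 12L))
  fit_b <- stage("bootstrap", bootstrap_ci(fit_b, n_iter = config$n_boot,
                                           seed = config$seed + 21L,
                                           level = config$ci_level))
  fit_u <- stage("bootstrap", bootstrap_ci(fit_u, n_iter = config$n_boot,
                                           seed = config$seed + 22L,
                                           level = config$ci_level))
  write_fit_report(fit_b, file.path(config$out_dir, "fit_binding.json"))
  write_fit_report(fit_u, file.path(config$out_dir, "fit_unbinding.json"))
  write_bootstrap_samples(fit_b, file.path(config$out_dir, "bootstrap_binding.csv"))
  write_bootstrap_samples(fit_u, file.path(config$out_dir, "bootstrap_unbinding.csv"))
  utils::write.csv(do.call(rbind, exp_rows),
                   file.path(config$out_dir, "exp_fits.csv"), row.names = FALSE)

  all_rates <- rate_set(fit_b$rates[["k1"]], fit_b$rates[["km1"]],
                        fit_b$rates[["k2"]], fit_u$rates[["km2"]],
                        fit_u$rates[["k3"]], fit_u$rates[["km3"]])
  eq <- stage("derive", equilibrium_summary(all_rates))
  summary <- list(
    seed = config$seed,
    concentrations_nM = config$concentrations,
    n_traces = config$n_traces,
    rates = as.list(unclass(all_rates)),
    ci_lower = c(as.list(fit_b$bootstrap$ci["lower", ]),
                 as.list(fit_u$bootstrap$ci["lower", ])),
    ci_upper = c(as.list(fit_b$bootstrap$ci["upper", ]),
                 as.list(fit_u$bootstrap$ci["upper", ])),
    ssr = list(binding = fit_b$ssr, unbinding = fit_u$ssr),
    derived = list(Keq_free = eq$Keq_free, Keq_bound = eq$Keq_bound,
                   K2 = eq$K2, K_app = eq$K_app))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete")
  invisible(summary)
}
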