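## Flat-file plumbing: every artifact is CSV or JSON, numeric values are
## written at full double precision so files round-trip exactly, and each
## CSV carries '#' header comments recording seeds and parameters.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- formatC(v, digits = 17, format = "g")
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
  out
}

write_commented_csv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_commented_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lines <- readLines(path, n = 50)
  cm <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  meta <- list()
  for (l in cm[grepl("=", cm)]) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  attr(df, "meta") <- meta
  df
}

meta_num <- function(meta, key) {
  v <- suppressWarnings(as.numeric(meta[[key]]))
  if (length(v) != 1 || is.na(v)) NA_real_ else v
}

#' Write / read a dwell set as CSV
#'
#' Columns `class, dwell_s, censored`; concentration and frame time go into
#' `#`-comment headers.
#'
#' @param dwells a [dwell_set()].
#' @param path file path.
#' @return The path (write) or a [dwell_set()] (read).
#' @export
write_dwells <- function(dwells, path) {
  write_commented_csv(as.data.frame(dwells), path, c(
    paste0("concentration_nM = ", fmt_num(attr(dwells, "concentration"))),
    paste0("frame_dt_s = ", fmt_num(attr(dwells, "frame_dt")))))
}

#' @rdname write_dwells
#' @export
read_dwells <- function(path) {
  df <- read_commented_csv(path)
  need <- c("class", "dwell_s", "censored")
  if (!all(need %in% names(df)))
    stop("dwell file ", path, " missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  meta <- attr(df, "meta")
  dwell_set(df$class, df$dwell_s, as.logical(df$censored),
            concentration = meta_num(meta, "concentration_nM"),
            frame_dt = meta_num(meta, "frame_dt_s"))
}

#' Write / read a two-channel trace as CSV
#'
#' Columns `frame, time_s, donor, acceptor`; frame time and the emission
#' seed go into comment headers.
#'
#' @param trace an `sm_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)[c("frame", "time_s", "donor", "acceptor")]
  write_commented_csv(df, path, c(
    paste0("frame_dt_s = ", fmt_num(attr(trace, "frame_dt"))),
    paste0("seed = ", attr(trace, "seed"))))
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read_commented_csv(path)
  need <- c("frame", "time_s", "donor", "acceptor")
  if (!all(need %in% names(df)))
    stop("trace file ", path, " missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  meta <- attr(df, "meta")
  dt <- meta_num(meta, "frame_dt_s")
  if (is.na(dt) && nrow(df) > 1) dt <- df$time_s[2] - df$time_s[1]
  structure(df, frame_dt = dt, class = c("sm_trace", "data.frame"))
}

#' Write a simulated state path as CSV
#'
#' Columns `state, class, t_entry, t_exit` plus seed/concentration headers.
#'
#' @param path_obj a `state_path`.
#' @param path file path.
#' @export
write_state_path <- function(path_obj, path) {
  write_commented_csv(as.data.frame(path_obj), path, c(
    paste0("seed = ", attr(path_obj, "seed")),
    paste0("dna_nM = ", fmt_num(attr(path_obj, "dna"))),
    paste0("t_max_s = ", fmt_num(attr(path_obj, "t_max")))))
}

#' Write / read an empirical dwell-time CDF as CSV
#'
#' Columns `time_s, cdf`; dwell count, concentration and grid spacing in
#' comment headers.
#'
#' @param cdf a `dwell_cdf`.
#' @param path file path.
#' @export
write_cdf <- function(cdf, path) {
  write_commented_csv(data.frame(time_s = cdf$time, cdf = cdf$cdf), path, c(
    paste0("n_dwells = ", cdf$n_dwells),
    paste0("concentration_nM = ", fmt_num(cdf$concentration)),
    paste0("frame_dt_s = ", fmt_num(cdf$frame_dt))))
}

#' @rdname write_cdf
#' @export
read_cdf <- function(path) {
  df <- read_commented_csv(path)
  if (!all(c("time_s", "cdf") %in% names(df)))
    stop("CDF file ", path, " lacks time_s/cdf columns")
  if (is.unsorted(df$cdf)) stop("CDF file ", path, " has non-monotone values")
  if (any(df$cdf < 0 | df$cdf > 1)) stop("CDF file ", path, " has values outside [0,1]")
  meta <- attr(df, "meta")
  structure(list(time = df$time_s, cdf = df$cdf,
                 n_dwells = meta_num(meta, "n_dwells"),
                 concentration = meta_num(meta, "concentration_nM"),
                 frame_dt = meta_num(meta, "frame_dt_s")),
            class = "dwell_cdf")
}

#' Write a global-fit report (point estimates, SSR, bootstrap CIs) as JSON
#'
#' @param fit a `global_fit`, optionally with bootstrap results.
#' @param path JSON file path.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(side = fit$side,
              rates = as.list(fit$rates),
              ssr = fit$ssr,
              n_points = fit$n_points,
              concentrations_nM = fit$concs,
              converged = fit$converged,
              at_bound = as.list(stats::setNames(fit$at_bound, names(fit$rates))))
  if (!is.null(fit$bootstrap)) {
    b <- fit$bootstrap
    rep$bootstrap <- list(level = b$level, n_iter = b$n_iter,
                          n_fail = b$n_fail, seed = b$seed,
                          mean = as.list(b$mean),
                          ci_lower = as.list(b$ci["lower", ]),
                          ci_upper = as.list(b$ci["upper", ]))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write bootstrap samples as a flat CSV
#'
#' @param fit a `global_fit` carrying bootstrap samples.
#' @param path CSV file path.
#' @export
write_bootstrap_samples <- function(fit, path) {
  if (is.null(fit$bootstrap)) stop("fit has no bootstrap samples")
  write_commented_csv(as.data.frame(fit$bootstrap$samples), path, c(
    paste0("seed = ", fit$bootstrap$seed),
    paste0("n_iter = ", fit$bootstrap$n_iter)))
}
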