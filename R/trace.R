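#' Per-frame FRET efficiency from a two-channel trace
#'
#' Efficiency is computed as `E = IA' / (IA' + ID')` from donor-leakage and
#' background corrected intensities `ID' = ID - background_d`,
#' `IA' = IA - background_a - leakage * ID'`. Frames whose corrected total
#' `IA' + ID'` is non-positive are flagged invalid (no fluorophore signal)
#' and excluded from histograms. A clipped copy (to `[-0.2, 1.2]`) is kept
#' alongside the raw value for plotting.
#'
#' @param trace an `sm_trace` or data.frame with `donor`, `acceptor` columns.
#' @param leakage donor-to-acceptor leakage fraction in `[0, 1)`.
#' @param background_d,background_a per-channel background intensities.
#' @return data.frame with columns `frame`, `E` (raw), `E_plot` (clipped),
#'   `valid`.
#' @export
fret_efficiency <- function(trace, leakage = 0, background_d = 0,
                            background_a = 0) {
  if (leakage < 0 || leakage >= 1) stop("leakage must be in [0, 1)")
  if (!all(is.finite(c(background_d, background_a)))) stop("backgrounds must be finite")
  id <- trace$donor - background_d
  ia <- trace$acceptor - background_a - leakage * id
  tot <- ia + id
  valid <- is.finite(tot) & tot > 0
  E <- ifelse(valid, ia / tot, NA_real_)
  Eraw <- ia / tot
  data.frame(frame = if (!is.null(trace$frame)) trace$frame else seq_along(id),
             E = Eraw,
             E_plot = pmin(pmax(Eraw, -0.2), 1.2),
             valid = valid)
}

#' Pooled FRET histogram over the first frames of many traces
#'
#' Short movies are summarized by pooling the efficiencies of the first
#' `n_frames` frames of every trace (the standard way population
#' histograms are built from many molecules without dwell-time bias).
#'
#' @param traces list of `sm_trace` objects (or donor/acceptor data.frames).
#' @param n_frames number of leading frames pooled per trace.
#' @param breaks bin edges passed to [graphics::hist()] semantics.
#' @param leakage,background_d,background_a corrections, see
#'   [fret_efficiency()].
#' @return A list of class `fret_histogram` with `breaks`, `counts`, `mids`
#'   and `n_frames_pooled`.
#' @export
fret_histogram <- function(traces, n_frames = 5,
                           breaks = seq(-0.2, 1.2, by = 0.05),
                           leakage = 0, background_d = 0, background_a = 0) {
  if (!length(traces)) stop("no traces")
  pooled <- unlist(lapply(traces, function(tr) {
    if (nrow(tr) < n_frames)
      stop("trace shorter than n_frames (", nrow(tr), " < ", n_frames, ")")
    e <- fret_efficiency(tr[seq_len(n_frames), , drop = FALSE],
                         leakage, background_d, background_a)
    e$E[e$valid]
  }))
  if (!length(pooled)) stop("zero valid frames after correction")
  pooled_cl <- pmin(pmax(pooled, min(breaks)), max(breaks))
  h <- graphics::hist(pooled_cl, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 n_frames_pooled = length(pooled)),
            class = "fret_histogram")
}

#' Two-limit hysteresis idealization of a noisy binary signal
#'
#' Thresholding with two limits: the current class switches
#' low -> high only when the signal exceeds `high_limit` and high -> low
#' only when it drops below `low_limit`; values in the dead band between
#' the limits keep the previous class, which suppresses spurious
#' transitions from noise. The initial class is set by the nearer limit.
#'
#' @param signal numeric per-frame series (FRET efficiency or acceptor
#'   intensity for colocalization data).
#' @param low_limit,high_limit the two thresholds, `low_limit < high_limit`.
#' @param frame_dt exposure time, s, stored for downstream dwell extraction.
#' @return An `ideal_trace`: data.frame with `class` ("low"/"high"),
#'   `start_frame`, `end_frame` (inclusive, 1-based); thresholds and
#'   `frame_dt` kept as attributes.
#' @export
threshold_idealize <- function(signal, low_limit, high_limit, frame_dt = NA_real_) {
  if (!(low_limit < high_limit)) stop("low_limit must be < high_limit")
  n <- length(signal)
  if (!n) stop("empty signal")
  state <- ifelse(signal > high_limit, 1L, ifelse(signal < low_limit, 0L, NA_integer_))
  init <- if (is.na(state[1])) {
    if ((high_limit - signal[1]) < (signal[1] - low_limit)) 1L else 0L
  } else state[1]
  if (all(is.na(state)))
    warning("signal never crosses either limit; single segment of the initial class")
  ## last-observation-carried-forward from the initial class
  filled <- c(init, state[!is.na(state)])[cumsum(!is.na(state)) + 1L]
  r <- rle(filled)
  ends <- cumsum(r$lengths)
  structure(data.frame(class = ifelse(r$values == 1L, "high", "low"),
                       start_frame = ends - r$lengths + 1L,
                       end_frame = ends,
                       stringsAsFactors = FALSE),
            low_limit = low_limit, high_limit = high_limit,
            frame_dt = frame_dt,
            class = c("ideal_trace", "data.frame"))
}

#' Dwell times from an idealized trace
#'
#' Each segment becomes a dwell of duration (number of frames) x
#' `frame_dt`; the minimum resolvable dwell is one frame. The first and
#' last segments are censored (their entry/exit was not observed) and are
#' dropped unless `keep_censored = TRUE`.
#'
#' @param ideal an `ideal_trace` from [threshold_idealize()].
#' @param frame_dt exposure time, s; defaults to the value stored on `ideal`.
#' @param keep_censored keep flagged censored segments.
#' @param concentration optional DNA concentration tag, nM.
#' @return A [dwell_set()] with classes "low"/"high".
#' @export
extract_dwells <- function(ideal, frame_dt = attr(ideal, "frame_dt"),
                           keep_censored = FALSE, concentration = NA_real_) {
  if (is.na(frame_dt)) stop("frame_dt unknown; pass it explicitly")
  m <- nrow(ideal)
  if (m < 3 && !keep_censored)
    warning("fewer than 3 segments: no complete dwells")
  dur <- (ideal$end_frame - ideal$start_frame + 1L) * frame_dt
  cens <- seq_len(m) %in% c(1L, m)
  keep <- if (keep_censored) rep(TRUE, m) else !cens
  dwell_set(ideal$class[keep], dur[keep], cens[keep],
            concentration = concentration, frame_dt = frame_dt)
}

#' Empirical dwell-time cumulative distribution
#'
#' `CDF(t)` = fraction of complete dwells with duration <= t, evaluated on
#' a grid from `frame_dt` to the longest dwell with spacing equal to the
#' imaging exposure time.
#'
#' @param dwells a [dwell_set()] or bare numeric vector of dwell times, s.
#' @param frame_dt grid spacing (exposure time), s; defaults to the value
#'   stored on the dwell set.
#' @param concentration DNA concentration tag, nM; defaults to the stored
#'   value.
#' @param class_filter when `dwells` holds several observable classes,
#'   which one to use.
#' @return A `dwell_cdf`: list with `time`, `cdf`, `n_dwells`,
#'   `concentration`, `frame_dt`.
#' @export
build_cdf <- function(dwells, frame_dt = NULL, concentration = NULL,
                      class_filter = NULL) {
  if (inherits(dwells, "dwell_set")) {
    if (is.null(frame_dt)) frame_dt <- attr(dwells, "frame_dt")
    if (is.null(concentration)) concentration <- attr(dwells, "concentration")
    d <- dwells[!dwells$censored, , drop = FALSE]
    if (!is.null(class_filter)) d <- d[d$class == class_filter, , drop = FALSE]
    else if (length(unique(d$class)) > 1)
      stop("dwell set holds several classes; pass class_filter")
    x <- d$dwell_s
  } else {
    x <- dwells[is.finite(dwells)]
  }
  if (is.null(frame_dt) || is.na(frame_dt)) stop("frame_dt unknown; pass it explicitly")
  if (is.null(concentration)) concentration <- NA_real_
  if (!length(x)) stop("no complete dwells")
  x <- sort(x)
  grid <- frame_dt * seq_len(max(1L, ceiling(x[length(x)] / frame_dt - 1e-9)))
  cdf <- findInterval(grid + frame_dt * 1e-6, x) / length(x)
  structure(list(time = grid, cdf = cdf, n_dwells = length(x),
                 concentration = concentration, frame_dt = frame_dt),
            class = "dwell_cdf")
}

#' @export
print.dwell_cdf <- function(x, ...) {
  cat(sprintf("Empirical dwell-time CDF: n = %d dwells, grid %g..%g s (dt = %g s)",
              x$n_dwells, x$time[1], x$time[length(x$time)], x$frame_dt))
  if (is.finite(x$concentration)) cat(sprintf(", [DNA] = %g nM", x$concentration))
  cat("\n")
  invisible(x)
}
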