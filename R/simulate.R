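#' Simulation configuration for the four-state binding scheme
#'
#' Collects the stated experimental world: microscopic rates of the
#' magnitude obtained for consensus TALE arrays, bulk DNA held constant
#' (pseudo-first-order, the tethered protein never depletes it), camera
#' frame times of 50-100 ms, and two-level FRET emission (efficiency ~0
#' unbound, ~0.45-0.55 bound) with additive Gaussian intensity noise.
#'
#' @param rates a [rate_set()].
#' @param dna bulk DNA concentration, nM (constant during the run).
#' @param t_max total simulated time, s.
#' @param frame_dt camera exposure time, s.
#' @param fret_levels named efficiencies in `[0,1]` per observable class.
#' @param noise_sd Gaussian intensity noise s.d. per channel, intensity units.
#' @param total_intensity summed donor+acceptor intensity, intensity units.
#' @param seed integer RNG seed recorded in all outputs.
#' @param bleach_rate optional photobleach rate, s^-1; when set, the trace is
#'   truncated at an exponentially-drawn bleach time (off by default: the
#'   experiments use an oxygen-scavenging system).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rates, dna = 15, t_max = 1000, frame_dt = 0.05,
                       fret_levels = c(unbound = 0, bound = 0.45),
                       noise_sd = 5, total_intensity = 100, seed = 1L,
                       bleach_rate = NULL) {
  rates <- as_rate_set(rates)
  if (dna < 0) stop("dna must be >= 0")
  if (frame_dt <= 0) stop("frame_dt must be > 0")
  if (t_max <= frame_dt) stop("t_max must exceed frame_dt")
  if (any(fret_levels < 0 | fret_levels > 1)) stop("fret_levels must be in [0,1]")
  if (noise_sd < 0 || total_intensity <= 0) stop("invalid intensity parameters")
  structure(list(rates = rates, dna = dna, t_max = t_max, frame_dt = frame_dt,
                 fret_levels = fret_levels, noise_sd = noise_sd,
                 total_intensity = total_intensity, seed = as.integer(seed),
                 bleach_rate = bleach_rate),
            class = "sim_config")
}

#' Exact stochastic (Gillespie) simulation of a kinetic scheme
#'
#' Samples one continuous-time Markov chain path of the scheme: exponential
#' waiting times with the total exit propensity of the current state, jump
#' targets in proportion to individual propensities. The association step
#' has propensity k2*[DNA] with [DNA] constant. Identical seeds give
#' identical paths.
#'
#' @param config a [sim_config()].
#' @param scheme a [kinetic_scheme()] (default: the canonical four-state
#'   scheme).
#' @param init initial state id, or `"stationary"` to draw it from the
#'   stationary distribution of the full scheme.
#' @return A `state_path`: data.frame with columns `state`, `class`,
#'   `t_entry`, `t_exit`; the terminal segment ends open at `t_max`.
#'   Attributes record seed, concentration and whether an absorbing trap
#'   ended the walk.
#' @export
gillespie_simulate <- function(config, scheme = four_state_scheme(),
                               init = "stationary") {
  M <- rate_matrix(scheme, config$rates, config$dna)
  ids <- scheme$states$id
  cls <- stats::setNames(scheme$states$class, ids)
  n <- length(ids)
  exits <- lapply(seq_len(n), function(j) {
    w <- M[, j]; w[j] <- 0
    list(to = which(w > 0), w = w[w > 0], tot = sum(w[w > 0]))
  })
  set.seed(config$seed)
  if (identical(init, "stationary")) {
    pi0 <- suppressWarnings(stationary_distribution(scheme, config$rates, config$dna))
    s <- sample.int(n, 1, prob = pi0)
  } else {
    s <- match(init, ids)
    if (is.na(s)) stop("unknown initial state: ", init)
  }
  t_end <- config$t_max
  if (!is.null(config$bleach_rate) && config$bleach_rate > 0)
    t_end <- min(t_end, stats::rexp(1, config$bleach_rate))
  cap <- 256L
  st <- integer(cap); te <- numeric(cap)
  m <- 0L; t <- 0; trapped <- FALSE
  while (t < t_end) {
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      length(st) <- cap; length(te) <- cap
    }
    st[m] <- s; te[m] <- t
    ex <- exits[[s]]
    if (ex$tot <= 0) {                       # absorbing trap: stop the walk
      trapped <- TRUE
      t <- t_end
      break
    }
    t <- t + stats::rexp(1, ex$tot)
    if (t < t_end)
      s <- if (length(ex$to) == 1L) ex$to else
        ex$to[sample.int(length(ex$to), 1, prob = ex$w)]
  }
  if (trapped)
    warning("absorbing trap reached at state ", ids[st[m]],
            "; path held there until t_max")
  idx <- seq_len(m)
  out <- data.frame(state = ids[st[idx]],
                    class = unname(cls[ids[st[idx]]]),
                    t_entry = te[idx],
                    t_exit = c(te[idx][-1], t_end),
                    stringsAsFactors = FALSE)
  structure(out, seed = config$seed, dna = config$dna, t_max = t_end,
            trapped = trapped, class = c("state_path", "data.frame"))
}

#' Build a dwell set
#'
#' @param class observable class per dwell.
#' @param dwell_s dwell durations, s.
#' @param censored logical flags for incompletely observed dwells.
#' @param concentration DNA concentration the dwells were recorded at, nM.
#' @param frame_dt imaging exposure time, s (NA for continuous-time dwells).
#' @return A `dwell_set` data.frame.
#' @export
dwell_set <- function(class = character(), dwell_s = numeric(),
                      censored = logical(length(dwell_s)),
                      concentration = NA_real_, frame_dt = NA_real_) {
  if (any(dwell_s < 0, na.rm = TRUE)) stop("negative dwell")
  structure(data.frame(class = class, dwell_s = dwell_s, censored = censored,
                       stringsAsFactors = FALSE),
            concentration = concentration, frame_dt = frame_dt,
            class = c("dwell_set", "data.frame"))
}

#' Extract ground-truth dwells from a simulated state path
#'
#' Consecutive segments of the same observable class are merged into one
#' dwell. The terminal dwell is right-censored (the exit was never
#' observed) and is excluded by default; set `keep_censored = TRUE` to
#' retain it flagged.
#'
#' @param path a `state_path` from [gillespie_simulate()].
#' @param class_map optional named character vector state -> class
#'   overriding the classes stored in the path.
#' @param keep_censored keep the flagged right-censored terminal dwell.
#' @return A [dwell_set()].
#' @export
dwells_from_path <- function(path, class_map = NULL, keep_censored = FALSE) {
  if (nrow(path) == 0) {
    warning("empty state path; returning empty dwell set")
    return(dwell_set(concentration = attr(path, "dna")))
  }
  cls <- if (is.null(class_map)) path$class else {
    miss <- setdiff(unique(path$state), names(class_map))
    if (length(miss)) stop("class_map missing states: ", paste(miss, collapse = ", "))
    unname(class_map[path$state])
  }
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- path$t_exit[ends] - path$t_entry[starts]
  cens <- c(rep(FALSE, length(dur) - 1L), TRUE)
  if (!keep_censored) {
    keep <- !cens
    r$values <- r$values[keep]; dur <- dur[keep]; cens <- cens[keep]
  }
  dwell_set(r$values, dur, cens, concentration = attr(path, "dna"))
}

#' Emit a noisy two-channel intensity trace from a state path
#'
#' Frames of width `frame_dt` tile `[0, t_max)`. Within each frame the true
#' efficiency is the time-weighted average of the class levels occupied
#' during the frame; channel intensities are
#' `acceptor = total * E + N(0, noise_sd)` and
#' `donor = total * (1 - E) + N(0, noise_sd)`.
#'
#' @param path a `state_path`.
#' @param config the [sim_config()] used to simulate it.
#' @param seed RNG seed for the noise draw (defaults to `config$seed + 1`
#'   so the path and its noise are independently reproducible).
#' @return An `sm_trace` data.frame with columns `frame`, `time_s`,
#'   `donor`, `acceptor` and a hidden `E_true` column; `frame_dt` and the
#'   level map are stored as attributes.
#' @export
emit_trace <- function(path, config, seed = config$seed + 1L) {
  dt <- config$frame_dt
  n_frames <- floor(attr(path, "t_max") / dt + 1e-9)
  if (n_frames < 1) stop("path shorter than one frame")
  lv <- config$fret_levels
  miss <- setdiff(unique(path$class), names(lv))
  if (length(miss)) stop("fret_levels missing classes: ", paste(miss, collapse = ", "))
  Eacc <- numeric(n_frames)
  t_hi <- n_frames * dt
  for (i in seq_len(nrow(path))) {
    a <- path$t_entry[i]; b <- min(path$t_exit[i], t_hi)
    if (b <= a) next
    f0 <- max(floor(a / dt) + 1L, 1L)
    f1 <- min(ceiling(b / dt), n_frames)
    if (f1 < f0) next
    idx <- f0:f1
    ov <- pmin(b, idx * dt) - pmax(a, (idx - 1) * dt)
    Eacc[idx] <- Eacc[idx] + pmax(ov, 0) * lv[[path$class[i]]]
  }
  E <- Eacc / dt
  set.seed(seed)
  acc <- config$total_intensity * E + stats::rnorm(n_frames, 0, config$noise_sd)
  don <- config$total_intensity * (1 - E) + stats::rnorm(n_frames, 0, config$noise_sd)
  structure(data.frame(frame = seq_len(n_frames),
                       time_s = (seq_len(n_frames) - 1) * dt,
                       donor = don, acceptor = acc, E_true = E),
            frame_dt = dt, fret_levels = lv, seed = seed,
            noise_sd = config$noise_sd, total_intensity = config$total_intensity,
            class = c("sm_trace", "data.frame"))
}

#' Sample first-passage dwell times directly from a condensed scheme
#'
#' A fast exact sampler for dwell durations in one observable class: the
#' walk starts in the entry state of the class (TALE* for unbound dwells,
#' TALE*~DNA for bound dwells, i.e. the direct product of the preceding
#' transition) and runs until absorption into the other class. Dwells from
#' a trapped walk (an exit rate of zero) are returned as `Inf`.
#'
#' @param side `"binding"` for unbound dwells (absorption = association) or
#'   `"unbinding"` for bound dwells (absorption = dissociation).
#' @param rates a [rate_set()] or named vector.
#' @param dna DNA concentration, nM (binding side only).
#' @param n number of dwells.
#' @param seed integer RNG seed.
#' @return Numeric vector of `n` dwell durations, s.
#' @export
simulate_dwells <- function(side = c("binding", "unbinding"), rates, dna = 0,
                            n, seed = 1L) {
  side <- match.arg(side)
  rs <- unclass(as_rate_set(rates))
  if (side == "binding") {
    ret <- rs[["km1"]]; absb <- rs[["k2"]] * dna; back <- rs[["k1"]]
  } else {
    ret <- rs[["k3"]]; absb <- rs[["km2"]]; back <- rs[["km3"]]
  }
  if (absb + ret <= 0) stop("entry state has zero exit rate")
  set.seed(seed)
  out <- numeric(n)
  p_abs <- absb / (absb + ret)
  tot <- absb + ret
  for (i in seq_len(n)) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, tot)
      if (stats::runif(1) < p_abs) break
      if (back <= 0) { t <- Inf; break }       # side state is a trap
      t <- t + stats::rexp(1, back)
    }
    out[i] <- t
  }
  out
}
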