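#' Build a kinetic scheme from states and transitions
#'
#' A scheme is data-driven: states carry an observable class (e.g. "unbound"
#' low-FRET vs "bound" high-FRET) and transitions name a rate-constant
#' symbol plus a ligand order (0 for unimolecular steps, 1 for the
#' pseudo-first-order association step whose propensity is k * [DNA]).
#'
#' @param states data.frame with columns `id`, `class`.
#' @param transitions data.frame with columns `from`, `to`, `rate`
#'   (a name in a [rate_set()]), `ligand_order` (0 or 1).
#' @param absorbing character vector of state ids with no exits (their
#'   declared outgoing transitions, if any, are disallowed).
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(states, transitions, absorbing = character()) {
  stopifnot(all(c("id", "class") %in% names(states)),
            all(c("from", "to", "rate", "ligand_order") %in% names(transitions)))
  states$id <- as.character(states$id)
  if (anyDuplicated(states$id)) stop("duplicate state ids")
  bad <- setdiff(c(transitions$from, transitions$to), states$id)
  if (length(bad)) stop("transitions reference unknown states: ",
                        paste(unique(bad), collapse = ", "))
  if (!all(transitions$ligand_order %in% c(0L, 1L)))
    stop("ligand_order must be 0 or 1")
  transitions$ligand_order <- as.integer(transitions$ligand_order)
  if (any(transitions$from %in% absorbing))
    stop("absorbing states cannot have outgoing transitions")
  structure(list(states = states, transitions = transitions,
                 absorbing = as.character(absorbing)),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("Kinetic scheme: %d states, %d transitions\n",
              nrow(x$states), nrow(x$transitions)))
  cat("States:\n")
  for (i in seq_len(nrow(x$states)))
    cat(sprintf("  %-12s class=%s%s\n", x$states$id[i], x$states$class[i],
                if (x$states$id[i] %in% x$absorbing) " (absorbing)" else ""))
  cat("Transitions:\n")
  for (i in seq_len(nrow(x$transitions)))
    cat(sprintf("  %-12s -> %-12s %s%s\n",
                x$transitions$from[i], x$transitions$to[i],
                x$transitions$rate[i],
                if (x$transitions$ligand_order[i] == 1) " * [DNA]" else ""))
  invisible(x)
}

#' The canonical four-state TALE-DNA binding scheme
#'
#' Two unbound conformers (binding-incompetent TALE, binding-competent
#' TALE*) interconvert with k1/km1; TALE* associates with DNA (k2 * [DNA])
#' to the directly-dissociating bound register TALE*~DNA (reverse km2),
#' which exchanges with the long-lived register TALE++~DNA (k3/km3).
#' Unbound states are observed as the low signal class, bound states as the
#' high class.
#'
#' @return A [kinetic_scheme()] with 4 states and 6 transitions.
#' @export
four_state_scheme <- function() {
  states <- data.frame(
    id = c("TALE", "TALE*", "TALE*~DNA", "TALE++~DNA"),
    class = c("unbound", "unbound", "bound", "bound"),
    stringsAsFactors = FALSE)
  transitions <- data.frame(
    from = c("TALE", "TALE*", "TALE*", "TALE*~DNA", "TALE*~DNA", "TALE++~DNA"),
    to = c("TALE*", "TALE", "TALE*~DNA", "TALE*", "TALE++~DNA", "TALE*~DNA"),
    rate = c("k1", "km1", "k2", "km2", "k3", "km3"),
    ligand_order = c(0L, 0L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  kinetic_scheme(states, transitions)
}

#' Condense a scheme for first-passage analysis out of one observable class
#'
#' States of `transient_class` keep their internal transitions; every
#' transition leaving that class is redirected into a single absorbing sink
#' state, and all other states/transitions are dropped. The accumulated
#' occupancy of the sink then equals the first-passage-time CDF of dwells in
#' `transient_class`.
#'
#' @param scheme a [kinetic_scheme()].
#' @param transient_class observable class whose dwells are analyzed.
#' @param sink_id id for the absorbing sink state.
#' @return A condensed [kinetic_scheme()] with the sink absorbing.
#' @export
condense_scheme <- function(scheme, transient_class, sink_id = "absorbed") {
  tr_states <- scheme$states$id[scheme$states$class == transient_class]
  if (!length(tr_states)) stop("no states of class ", transient_class)
  other_class <- setdiff(unique(scheme$states$class), transient_class)
  keep <- scheme$transitions$from %in% tr_states
  tt <- scheme$transitions[keep, , drop = FALSE]
  tt$to[!(tt$to %in% tr_states)] <- sink_id
  states <- rbind(
    scheme$states[scheme$states$id %in% tr_states, , drop = FALSE],
    data.frame(id = sink_id,
               class = if (length(other_class)) other_class[1] else "absorbed",
               stringsAsFactors = FALSE))
  kinetic_scheme(states, tt, absorbing = sink_id)
}

#' Condensed scheme for binding (unbound-dwell) analysis
#'
#' The bound product state is made absorbing: TALE and TALE* evolve with
#' k1/km1 while the association flux k2 * [DNA] drains irreversibly into the
#' sink, so sink occupancy over time is the unbound-dwell CDF.
#'
#' @param scheme the four-state scheme (or a variant with the same classes).
#' @return Condensed [kinetic_scheme()].
#' @export
binding_subscheme <- function(scheme = four_state_scheme()) {
  condense_scheme(scheme, "unbound", sink_id = "TALE*~DNA(abs)")
}

#' Condensed scheme for unbinding (bound-dwell) analysis
#'
#' The unbound product state is made absorbing: TALE*~DNA and TALE++~DNA
#' exchange with k3/km3 while dissociation km2 drains into the sink; sink
#' occupancy is the bound-dwell CDF.
#'
#' @inheritParams binding_subscheme
#' @return Condensed [kinetic_scheme()].
#' @export
unbinding_subscheme <- function(scheme = four_state_scheme()) {
  condense_scheme(scheme, "bound", sink_id = "TALE*(abs)")
}

#' Generator matrix of a scheme at a given DNA concentration
#'
#' Column convention: dp/dt = M p with `M[to, from]` the propensity of the
#' from -> to transition (rate * dna^ligand_order) and diagonal entries
#' minus the total exit rate. Columns of conservative schemes sum to zero;
#' columns of absorbing states are identically zero.
#'
#' @param scheme a [kinetic_scheme()].
#' @param rates a [rate_set()] (or named numeric) resolving the rate symbols.
#' @param dna DNA concentration, nM.
#' @return Square numeric matrix with state ids as dimnames.
#' @export
rate_matrix <- function(scheme, rates, dna = 0) {
  if (!is.numeric(dna) || length(dna) != 1 || !is.finite(dna) || dna < 0)
    stop("dna concentration must be a single non-negative number")
  rv <- unclass(rates)
  miss <- setdiff(unique(scheme$transitions$rate), names(rv))
  if (length(miss)) stop("rates missing symbols: ", paste(miss, collapse = ", "))
  if (any(rv[unique(scheme$transitions$rate)] < 0)) stop("negative rate constant")
  ids <- scheme$states$id
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(scheme$transitions))) {
    tr <- scheme$transitions[i, ]
    prop <- rv[[tr$rate]] * dna^tr$ligand_order
    M[tr$to, tr$from] <- M[tr$to, tr$from] + prop
    M[tr$from, tr$from] <- M[tr$from, tr$from] - prop
  }
  M[, scheme$absorbing] <- 0
  M
}

#' Transient generator block of a condensed scheme
#'
#' The sub-matrix of [rate_matrix()] over the non-absorbing states; its
#' matrix exponential propagates the survival of a dwell.
#'
#' @inheritParams rate_matrix
#' @return Square matrix over the transient states.
#' @export
transient_generator <- function(scheme, rates, dna = 0) {
  M <- rate_matrix(scheme, rates, dna)
  keep <- setdiff(scheme$states$id, scheme$absorbing)
  M[keep, keep, drop = FALSE]
}

#' Stationary distribution of a scheme
#'
#' Null-space vector of the generator, normalized to sum to one. For a
#' reducible scheme (e.g. dna = 0, where the bound states are unreachable)
#' the mass ends up on the reachable recurrent states and a warning is
#' emitted.
#'
#' @inheritParams rate_matrix
#' @return Named numeric vector of state fractions summing to 1.
#' @export
stationary_distribution <- function(scheme, rates, dna = 0) {
  M <- rate_matrix(scheme, rates, dna)
  n <- nrow(M)
  ## solve M p = 0, sum(p) = 1 by least squares on the augmented system
  A <- rbind(M, rep(1, n))
  b <- c(rep(0, n), 1)
  p <- stats::setNames(drop(qr.solve(A, b)), rownames(M))
  p[abs(p) < 1e-12] <- 0
  if (any(p < 0)) stop("stationary solve produced negative fractions")
  p <- p / sum(p)
  reach <- p > 0
  ## reducibility check: any transition with zero propensity both ways
  if (any(!reach))
    warning("scheme is reducible at this concentration; distribution is over reachable states only")
  p
}

#' Write / read a scheme plus rate values as a JSON document
#'
#' The document is the single source of truth shared by simulation and
#' fitting: states with class labels, transitions with rate symbols and
#' ligand order, and the numeric rate values with units.
#'
#' @param scheme a [kinetic_scheme()].
#' @param rates a [rate_set()].
#' @param path output file.
#' @return `write_scheme` returns `path` invisibly; `read_scheme` returns
#'   `list(scheme=, rates=)`.
#' @export
write_scheme <- function(scheme, rates, path) {
  doc <- list(states = scheme$states,
              transitions = scheme$transitions,
              absorbing = scheme$absorbing,
              rates = as.list(unclass(rates)),
              units = as.list(attr(rates, "units")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rv <- doc$rates
  sc <- kinetic_scheme(doc$states, doc$transitions,
                       absorbing = unlist(doc$absorbing))
  list(scheme = sc,
       rates = rate_set(rv$k1, rv$km1, rv$k2, rv$km2, rv$k3, rv$km3))
}
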