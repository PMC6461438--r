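#' Equilibrium constants and apparent affinity from microscopic rates
#'
#' Derives the three equilibrium constants of the scheme and the composite
#' apparent affinity:
#' `Keq_free = k1/km1` (unbound isomerization), `K2 = k2/km2` (nM^-1,
#' association), `Keq_bound = k3/km3` (bound register exchange), and
#' `K_app = Keq_free * K2 * (1 + Keq_bound) / (1 + Keq_free)`,
#' the ratio of total bound to free-times-DNA populations. `K_app` is
#' reported on the conventional printed scale (nM); note the expression is
#' algebraically an association-type ratio -- the arithmetic is reproduced
#' as conventionally printed rather than inverted.
#'
#' @param rates a [rate_set()].
#' @return list of class `equilibrium_summary` with `Keq_free`,
#'   `Keq_bound`, `K2`, `K_app`.
#' @examples
#' equilibrium_summary(rate_set(0.17, 0.13, 1.1, 0.66, 0.36, 0.222))$K_app
#' @export
equilibrium_summary <- function(rates) {
  k <- unclass(as_rate_set(rates))
  for (nm in c("km1", "km2", "km3"))
    if (k[[nm]] == 0) stop("cannot form equilibrium constants: ", nm, " is zero")
  keq_free <- k[["k1"]] / k[["km1"]]
  k2 <- k[["k2"]] / k[["km2"]]
  keq_bound <- k[["k3"]] / k[["km3"]]
  structure(list(Keq_free = keq_free, Keq_bound = keq_bound, K2 = k2,
                 K_app = keq_free * k2 * (1 + keq_bound) / (1 + keq_free)),
            class = "equilibrium_summary")
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  cat(sprintf("Keq(DNA-free)  = %.4g\nKeq(DNA-bound) = %.4g\nK2 = %.4g nM-1\nK_app = %.4g nM\n",
              x$Keq_free, x$Keq_bound, x$K2, x$K_app))
  invisible(x)
}

#' Nearest-neighbor Ising energy model for a repeat array
#'
#' Per-repeat intrinsic folding free energies (possibly heterogeneous by
#' repeat type) and per-interface coupling free energies, with the thermal
#' energy RT setting the temperature. Energies are in kcal/mol.
#'
#' @param dg_intrinsic numeric vector, one intrinsic free energy per repeat.
#' @param dg_interface numeric vector of length `n_repeats - 1`.
#' @param RT thermal energy, kcal/mol (0.593 at 298 K).
#' @return An `ising_model` list.
#' @export
ising_model <- function(dg_intrinsic, dg_interface, RT = 0.593) {
  n <- length(dg_intrinsic)
  if (length(dg_interface) != n - 1)
    stop("need n - 1 interface energies for n repeats")
  if (RT <= 0) stop("RT must be positive")
  structure(list(dg_intrinsic = dg_intrinsic, dg_interface = dg_interface,
                 n_repeats = n, RT = RT),
            class = "ising_model")
}

#' A partly folded conformation of a repeat array
#'
#' A conformation is a folded/unfolded mask over repeats and an
#' intact/broken mask over interfaces. An interface may be intact only if
#' both flanking repeats are folded.
#'
#' @param folded logical vector per repeat.
#' @param intact logical vector per interface (length `n - 1`); by default
#'   every interface between two folded repeats is intact.
#' @param name optional label.
#' @return A `conformation` list.
#' @export
conformation <- function(folded, intact = NULL, name = NULL) {
  n <- length(folded)
  flanks_ok <- folded[-n] & folded[-1]
  if (is.null(intact)) intact <- flanks_ok
  if (length(intact) != n - 1) stop("need n - 1 interface flags")
  if (any(intact & !flanks_ok))
    stop("interface intact next to an unfolded repeat")
  structure(list(folded = folded, intact = intact, name = name),
            class = "conformation")
}

#' Free energy of a conformation relative to the fully folded state
#'
#' Under the nearest-neighbor model the free energy of a conformation is
#' the sum of intrinsic energies over folded repeats plus interfacial
#' energies over intact interfaces. The reported quantity is
#' `ddG = -RT * ln(w(conf) / w(folded))` with Boltzmann weights
#' `w = exp(-G/RT)`, which reduces exactly to `G(conf) - G(folded)` --
#' no partition-function sum is needed for a pairwise state comparison.
#'
#' @param model an [ising_model()].
#' @param conf a [conformation()] with matching repeat count.
#' @return ddG in kcal/mol (0 for the fully folded state).
#' @export
conformation_free_energy <- function(model, conf) {
  stopifnot(inherits(model, "ising_model"), inherits(conf, "conformation"))
  if (length(conf$folded) != model$n_repeats)
    stop("conformation size does not match model")
  g <- function(folded, intact)
    sum(model$dg_intrinsic[folded]) + sum(model$dg_interface[intact])
  g(conf$folded, conf$intact) -
    g(rep(TRUE, model$n_repeats), rep(TRUE, model$n_repeats - 1))
}

#' Canonical catalog of partly folded states
#'
#' The fully folded state plus the three canonical partly folded states of
#' an n-repeat array: end-frayed (first repeat unfolded), internally
#' unfolded (repeat `ceiling(n/2)` unfolded), and interfacially fractured
#' (all repeats folded, interface `ceiling(n/2)` -- the one between the
#' middle repeat and its successor -- broken).
#'
#' @param n_repeats number of repeats, at least 3.
#' @return Named list of [conformation()] objects: `fully_folded`,
#'   `end_frayed`, `internally_unfolded`, `interfacially_fractured`.
#' @export
state_catalog <- function(n_repeats) {
  if (n_repeats < 3) stop("need at least 3 repeats")
  n <- n_repeats
  mid <- ceiling(n / 2)
  all_f <- rep(TRUE, n)
  ef <- all_f; ef[1] <- FALSE
  iu <- all_f; iu[mid] <- FALSE
  frac_intact <- rep(TRUE, n - 1); frac_intact[mid] <- FALSE
  list(fully_folded = conformation(all_f, name = "fully_folded"),
       end_frayed = conformation(ef, name = "end_frayed"),
       internally_unfolded = conformation(iu, name = "internally_unfolded"),
       interfacially_fractured = conformation(all_f, frac_intact,
                                              name = "interfacially_fractured"))
}

#' Read an Ising energy model from a JSON document
#'
#' Expects fields `dg_intrinsic` (per repeat), `dg_interface` (per
#' interface) and `RT`, all kcal/mol.
#'
#' @param path JSON file.
#' @return An [ising_model()].
#' @export
read_ising_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ising_model(doc$dg_intrinsic, doc$dg_interface, RT = doc$RT)
}
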