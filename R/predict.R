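## First-passage-time CDFs of condensed schemes.
##
## Dwell-time CDFs are survival complements of a linear ODE dp/dt = Q p on
## the transient states. Two independent numerical routes are provided:
## a closed-form eigen solution (exact for the canonical 2x2 blocks) and a
## Pade scaling-and-squaring matrix-exponential propagator that works for
## any scheme size and any stiffness ratio.

as_rate_set <- function(rates) {
  if (inherits(rates, "rate_set")) return(rates)
  rv <- unlist(rates)
  args <- as.list(stats::setNames(rep(0, 6), c("k1","km1","k2","km2","k3","km3")))
  for (nm in names(rv)) {
    if (!nm %in% names(args)) stop("unknown rate symbol: ", nm)
    args[[nm]] <- rv[[nm]]
  }
  do.call(rate_set, args)
}

## survival S(t) = 1' exp(Q t) p0 for a 2x2 transient generator, closed form
surv2_eigen <- function(Q, p0, tgrid) {
  s <- -(Q[1, 1] + Q[2, 2])                     # sum of decay rates
  p <- Q[1, 1] * Q[2, 2] - Q[1, 2] * Q[2, 1]    # product of decay rates
  disc <- max(s * s - 4 * p, 0)
  rplus <- (s + sqrt(disc)) / 2
  rminus <- (s - sqrt(disc)) / 2
  S0 <- sum(p0)
  dS0 <- sum(Q %*% p0)                          # S'(0)
  if ((rplus - rminus) > 1e-10 * max(rplus, 1e-300)) {
    aplus <- (-dS0 - S0 * rminus) / (rplus - rminus)
    aminus <- S0 - aplus
    aplus * exp(-rplus * tgrid) + aminus * exp(-rminus * tgrid)
  } else {                                      # defective/degenerate block
    r <- (rplus + rminus) / 2
    (S0 + (dS0 + r * S0) * tgrid) * exp(-r * tgrid)
  }
}

surv_eigen <- function(Q, p0, tgrid) {
  if (nrow(Q) == 1) return(sum(p0) * exp(Q[1, 1] * tgrid))
  if (nrow(Q) == 2) return(surv2_eigen(Q, p0, tgrid))
  e <- eigen(Q)
  if (rcond(e$vectors) < 1e-10)
    return(surv_expm(Q, p0, tgrid))             # near-defective: fall back
  coef <- solve(e$vectors, p0)
  amp <- colSums(e$vectors) * coef
  Re(vapply(tgrid, function(t) sum(amp * exp(e$values * t)), complex(1)))
}

## order-6 diagonal Pade approximant with scaling and squaring
expm_pade <- function(A) {
  n <- nrow(A)
  nrmA <- max(colSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin) / 0.5)))
  As <- A / 2^j
  c <- c(1, 1/2, 5/44, 1/66, 1/792, 1/15840, 1/665280)
  I <- diag(n)
  A2 <- As %*% As
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- As %*% (c[2] * I + c[4] * A2 + c[6] * A4)
  V <- c[1] * I + c[3] * A2 + c[5] * A4 + c[7] * A6
  E <- solve(V - U, V + U)
  for (k in seq_len(j)) E <- E %*% E
  E
}

surv_expm <- function(Q, p0, tgrid) {
  out <- numeric(length(tgrid))
  dts <- diff(c(0, tgrid))
  key <- match(dts, dts)   # memoize the propagator per distinct step size
  props <- vector("list", length(tgrid))
  p <- p0
  for (i in seq_along(tgrid)) {
    k <- key[i]
    if (is.null(props[[k]])) props[[k]] <- expm_pade(Q * dts[i])
    p <- props[[k]] %*% p
    out[i] <- sum(p)
  }
  out
}

fpt_cdf <- function(Q, p0, tgrid, method = c("eigen", "expm")) {
  method <- match.arg(method)
  S <- switch(method,
              eigen = surv_eigen(Q, p0, tgrid),
              expm = surv_expm(Q, p0, tgrid))
  pmin(pmax(1 - S, 0), 1)
}

check_tgrid <- function(tgrid) {
  if (!length(tgrid)) stop("tgrid is empty")
  if (any(!is.finite(tgrid)) || any(tgrid < 0) || is.unsorted(tgrid, strictly = FALSE))
    stop("tgrid must be non-negative and increasing")
}

#' Predicted unbound-dwell (binding) CDF from the condensed rate laws
#'
#' Integrates the condensed binding scheme -- the two unbound conformers
#' with the association flux k2*[DNA] draining into an absorbing bound
#' sink -- from the initial condition used for dwell analysis (all
#' population starts in the binding-competent conformer, since a dwell in
#' the unbound class begins with a dissociation event into TALE*). The
#' accumulated sink occupancy is the dwell-time CDF.
#'
#' @param rates a [rate_set()] or named vector with `k1`, `km1`, `k2`.
#' @param dna DNA concentration, nM.
#' @param tgrid increasing non-negative times, s.
#' @param method `"eigen"` for the closed-form double-exponential solution,
#'   `"expm"` for the matrix-exponential propagator (independent route).
#' @return Numeric vector of CDF values on `tgrid`.
#' @export
predict_binding_cdf <- function(rates, dna, tgrid, method = c("eigen", "expm")) {
  check_tgrid(tgrid)
  rs <- as_rate_set(rates)
  sub <- binding_subscheme()
  Q <- transient_generator(sub, rs, dna)
  p0 <- stats::setNames(c(0, 1), c("TALE", "TALE*"))[rownames(Q)]
  fpt_cdf(Q, p0, tgrid, method)
}

#' Predicted bound-dwell (unbinding) CDF from the condensed rate laws
#'
#' Integrates the condensed unbinding scheme -- the two bound registers
#' with dissociation km2 draining into an absorbing unbound sink -- from
#' the initial condition of all population in the directly-dissociating
#' register TALE*~DNA (the direct product of association).
#'
#' @param rates a [rate_set()] or named vector with `km2`, `k3`, `km3`.
#' @inheritParams predict_binding_cdf
#' @return Numeric vector of CDF values on `tgrid`.
#' @export
predict_unbinding_cdf <- function(rates, tgrid, method = c("eigen", "expm")) {
  check_tgrid(tgrid)
  rs <- as_rate_set(rates)
  sub <- unbinding_subscheme()
  Q <- transient_generator(sub, rs, dna = 0)
  p0 <- stats::setNames(c(1, 0), c("TALE*~DNA", "TALE++~DNA"))[rownames(Q)]
  fpt_cdf(Q, p0, tgrid, method)
}
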