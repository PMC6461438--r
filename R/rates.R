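#' Microscopic rate constants for the four-state TALE-DNA scheme
#'
#' Bundles the six microscopic rate constants of the binding mechanism:
#' unbound isomerization between the binding-incompetent (TALE) and
#' binding-competent (TALE*) conformers (`k1`, `km1`, both s^-1), the
#' bimolecular association step (`k2`, nM^-1 s^-1) and its reverse
#' dissociation (`km2`, s^-1), and the bound-state register exchange between
#' the directly-dissociating (TALE*~DNA) and long-lived (TALE++~DNA)
#' registers (`k3`, `km3`, both s^-1). Concentrations are in nM throughout.
#'
#' @param k1 TALE -> TALE* isomerization rate, s^-1.
#' @param km1 TALE* -> TALE isomerization rate, s^-1.
#' @param k2 TALE* + DNA -> TALE*~DNA association rate, nM^-1 s^-1.
#' @param km2 TALE*~DNA -> TALE* dissociation rate, s^-1.
#' @param k3 TALE*~DNA -> TALE++~DNA register-shift rate, s^-1.
#' @param km3 TALE++~DNA -> TALE*~DNA register-shift rate, s^-1.
#' @return An object of class `rate_set`: a named numeric vector with a
#'   units attribute.
#' @examples
#' rs <- rate_set(k1 = 0.17, km1 = 0.13, k2 = 1.1, km2 = 0.66,
#'                k3 = 0.36, km3 = 0.222)
#' rs
#' @export
rate_set <- function(k1 = 0, km1 = 0, k2 = 0, km2 = 0, k3 = 0, km3 = 0) {
  x <- c(k1 = unname(k1)[1], km1 = unname(km1)[1], k2 = unname(k2)[1],
         km2 = unname(km2)[1], k3 = unname(k3)[1], km3 = unname(km3)[1])
  if (any(!is.finite(x))) stop("rate constants must be finite")
  if (any(x < 0)) stop("rate constants must be >= 0")
  structure(x,
            units = c(k1 = "s-1", km1 = "s-1", k2 = "nM-1 s-1",
                      km2 = "s-1", k3 = "s-1", km3 = "s-1"),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  u <- attr(x, "units")
  cat("Microscopic rate constants:\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-4s = %-10g [%s]\n", nm, unclass(x)[[nm]], u[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.rate_set <- function(x, ...) {
  as.data.frame(as.list(unclass(x)))
}

#' Read a table of rate constants in the standard column layout
#'
#' Reads a CSV with one construct per row and columns
#' `construct, k1, km1, k2, km2, k3, km3` (extra columns are ignored), the
#' layout used for fitted-parameter tables.
#'
#' @param path CSV file path.
#' @return A named list of [rate_set()] objects, one per construct.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("construct", "k1", "km1", "k2", "km2", "k3", "km3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("rate table missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    rate_set(df$k1[i], df$km1[i], df$k2[i], df$km2[i], df$k3[i], df$km3[i]))
  names(out) <- df$construct
  out
}
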