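#' Carbon-normalized atomic property table
#'
#' Relative atomic polarizabilities and van der Waals volumes used as weights
#' in the Barysz distance matrix (`Dz(p)`) and the Burden matrix (`Bh(v)`).
#' Raw values are taken from standard compilations — static dipole
#' polarizabilities (CRC, in angstrom^3) and Bondi-radius van der Waals atomic
#' volumes (angstrom^3) — and divided by the carbon value, so the carbon entry
#' is exactly 1 for every property. The table ships with the package and is
#' never fetched at runtime, so descriptor values are bit-reproducible.
#'
#' @return A tibble with columns `element`, `polarizability`, `vdw_volume`
#'   (both dimensionless, carbon = 1), covering H, C, N, O, F, Si, P, S, Cl,
#'   Br and I.
#' @examples
#' atom_properties()
#' @export
atom_properties <- function() {
  raw <- tibble(
    element        = c("H", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
    polarizability = c(0.667, 1.760, 1.100, 0.802, 0.557, 5.380, 3.630, 2.900,
                       2.180, 3.050, 5.350),
    vdw_volume     = c(7.24, 20.58, 15.60, 14.71, 13.31, 38.79, 24.43, 24.43,
                       22.45, 26.52, 32.52)
  )
  raw$polarizability <- raw$polarizability / raw$polarizability[raw$element == "C"]
  raw$vdw_volume <- raw$vdw_volume / raw$vdw_volume[raw$element == "C"]
  raw
}

# Look up one property column for each atom of g, erroring on uncovered
# elements.
.atom_weights <- function(g, props, column) {
  idx <- match(g$atoms$element, props$element)
  if (anyNA(idx)) {
    missing <- unique(g$atoms$element[is.na(idx)])
    abort(paste0("Element(s) not covered by the atom property table: ",
                 paste(missing, collapse = ", ")))
  }
  w <- props[[column]][idx]
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort(paste0("Corrupt atom property table: non-positive or non-finite '",
                 column, "' entries."))
  }
  w
}
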