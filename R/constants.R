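## Physical constants and molar masses used throughout the package.

#' Physical and chemical constants
#'
#' Constants used by the speciation, stoichiometry and nutrient modules:
#' the gas constant `R` (J mol-1 K-1), the Faraday constant `F` (C mol-1),
#' and molar masses (g mol-1) of the nutrient and gas species handled by the
#' flux calculations.
#'
#' @return A named list with elements `gasConstant`, `faraday` and
#'   `molarMass` (a named numeric vector, g mol-1).
#' @examples
#' ferrokinConstants()$molarMass[["NH4+"]]
#' @export
ferrokinConstants <- function() {
  list(
    gasConstant = 8.314,
    faraday = 96485,
    molarMass = c(
      "CO2"    = 44.01,
      "NH4+"   = 18.04,
      "K+"     = 39.10,
      "Mg2+"   = 24.31,
      "SO42-"  = 96.06,
      "PO43-"  = 94.97,
      "Fe"     = 55.845
    )
  )
}

#' Molar mass lookup
#'
#' @param species Character vector of species names as used by
#'   [ferrokinConstants()].
#' @return Numeric vector of molar masses in g mol-1.
#' @examples
#' molarMassOf(c("NH4+", "K+"))
#' @export
molarMassOf <- function(species) {
  mm <- ferrokinConstants()$molarMass
  unknown <- setdiff(species, names(mm))
  if (length(unknown) > 0L) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  mm[species]
}
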