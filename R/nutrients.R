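## Nutrient consumption flux accounting from inlet/outlet concentration
## tables of the continuous cascade.

#' Create a nutrient record table
#'
#' @param species Character vector of species labels.
#' @param inlet,outlet Inlet/outlet concentrations, mg L-1 (nonnegative).
#' @param molarMass Molar masses, g mol-1; looked up from
#'   [ferrokinConstants()] when omitted.
#' @return A data frame with columns `species`, `inlet`, `outlet`,
#'   `molarMass` — the record format consumed by [concentrationDrop()] and
#'   [consumptionFlux()].
#' @examples
#' nutrientRecord("NH4+", 127, 59.3)
#' @export
nutrientRecord <- function(species, inlet, outlet, molarMass = NULL) {
  if (is.null(molarMass)) molarMass <- unname(molarMassOf(species))
  if (any(inlet < 0) || any(outlet < 0)) {
    stop("concentrations must be nonnegative")
  }
  if (any(molarMass <= 0)) stop("molar masses must be positive")
  data.frame(species = species, inlet = as.numeric(inlet),
             outlet = as.numeric(outlet), molarMass = as.numeric(molarMass))
}

#' Inlet-minus-outlet concentration drop
#'
#' Consumption is the difference between inlet and outlet flow
#' concentrations. A negative drop means net release in the reactor (as
#' observed for Mg2+ in the bioreduction stage) and is reported as is,
#' never clipped.
#'
#' @param record A [nutrientRecord()] data frame.
#' @return Named numeric vector of drops, mg L-1.
#' @examples
#' concentrationDrop(nutrientRecord("NH4+", 127, 59.3))  # 67.7
#' @export
concentrationDrop <- function(record) {
  stats::setNames(record$inlet - record$outlet, record$species)
}

#' Molar nutrient consumption flux
#'
#' Converts a concentration drop into a molar consumption flux on the
#' reactor-throughput basis: `drop * (volume / hrt) / molarMass` mmol h-1.
#' An alternative basis using a measured feed flow rate (mL h-1) directly is
#' available via `basis = "inflow"`; at nominal operation the two coincide
#' since throughput = volume/HRT.
#'
#' @param record A [nutrientRecord()] data frame.
#' @param volume Reactor volume, L (> 0).
#' @param hrt Hydraulic residence time, h (> 0).
#' @param basis `"throughput"` (volume/HRT, default) or `"inflow"`.
#' @param inflow Feed flow, mL h-1; required for `basis = "inflow"`.
#' @return Named numeric vector of fluxes, mmol h-1; negative values denote
#'   release.
#' @examples
#' consumptionFlux(nutrientRecord("NH4+", 127, 59.3), volume = 2, hrt = 73)
#' @export
consumptionFlux <- function(record, volume, hrt,
                            basis = c("throughput", "inflow"), inflow = NULL) {
  basis <- match.arg(basis)
  if (basis == "throughput") {
    if (volume <= 0 || hrt <= 0) stop("volume and hrt must be positive")
    throughput <- volume / hrt          # L/h
  } else {
    if (is.null(inflow) || inflow <= 0) {
      stop("basis = \"inflow\" requires a positive inflow in mL/h")
    }
    throughput <- inflow / 1000         # L/h
  }
  drop <- concentrationDrop(record)
  drop * throughput / record$molarMass  # mg/h / (g/mol) = mmol/h
}

#' Nutrient flux summary table
#'
#' Tabulates drops and molar fluxes for a whole nutrient record, labelling
#' each row as consumption or release. Species listed in `interference` are
#' flagged with a warning: their balance is confounded by reagent addition
#' (e.g. K+ when potash is dosed for pH control) and the computed flux is
#' not interpretable as microbial consumption.
#'
#' @inheritParams consumptionFlux
#' @param interference Character vector of species whose balance is
#'   confounded (default none).
#' @return Data frame with columns `species`, `drop`, `flux`, `direction`,
#'   `interference`.
#' @examples
#' tab <- nutrientRecord(c("NH4+", "Mg2+"), c(127, 55.7), c(59.3, 47.2))
#' nutrientFluxTable(tab, volume = 2, hrt = 73)
#' @export
nutrientFluxTable <- function(record, volume, hrt,
                              basis = c("throughput", "inflow"),
                              inflow = NULL, interference = character()) {
  flux <- consumptionFlux(record, volume, hrt, basis, inflow)
  drop <- concentrationDrop(record)
  flagged <- record$species %in% interference
  if (any(flagged)) {
    warning("flux not interpretable as microbial consumption for: ",
            paste(record$species[flagged], collapse = ", "),
            " (confounded by reagent addition)")
  }
  data.frame(species = record$species, drop = unname(drop),
             flux = unname(flux),
             direction = ifelse(drop >= 0, "consumption", "release"),
             interference = flagged)
}

#' Measured-to-stoichiometric nutrient demand ratio
#'
#' Compares a measured ammonium consumption flux with the stoichiometric
#' demand implied by a CO2 uptake rate through the cell-synthesis reaction
#' ([ammoniumDemandFromCO2()]).
#'
#' @param flux Measured flux, mmol h-1.
#' @param co2Uptake CO2 uptake rate, mg L-1 h-1.
#' @param volume Reactor volume, L.
#' @return The ratio measured/stoichiometric (dimensionless).
#' @examples
#' compareToBiomassDemand(0.104, 40, 2)  # ~0.23
#' @export
compareToBiomassDemand <- function(flux, co2Uptake, volume) {
  demand <- ammoniumDemandFromCO2(co2Uptake, volume)
  if (demand <= 0) stop("stoichiometric demand is zero: ratio undefined")
  flux / demand
}
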