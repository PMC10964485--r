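## Stoichiometry of the reductive bioleaching reaction network.
##
## Coefficients are exact rationals (integer numerator/denominator), so that
## element and charge balance residuals are exact; the cell-synthesis
## reaction is written in twentieths.

## built-in species compositions (element counts and net charge)
.speciesRegistry <- function() {
  list(
    "FeOOH"    = chemSpecies("FeOOH", c(Fe = 1, O = 2, H = 1), 0),
    "Fe3+"     = chemSpecies("Fe3+", c(Fe = 1), +3),
    "Fe2+"     = chemSpecies("Fe2+", c(Fe = 1), +2),
    "S0"       = chemSpecies("S0", c(S = 1), 0),
    "SO42-"    = chemSpecies("SO42-", c(S = 1, O = 4), -2),
    "MnO2"     = chemSpecies("MnO2", c(Mn = 1, O = 2), 0),
    "Mn2+"     = chemSpecies("Mn2+", c(Mn = 1), +2),
    "H+"       = chemSpecies("H+", c(H = 1), +1),
    "H2O"      = chemSpecies("H2O", c(H = 2, O = 1), 0),
    "O2"       = chemSpecies("O2", c(O = 2), 0),
    "CO2"      = chemSpecies("CO2", c(C = 1, O = 2), 0),
    "HCO3-"    = chemSpecies("HCO3-", c(H = 1, C = 1, O = 3), -1),
    "NH4+"     = chemSpecies("NH4+", c(N = 1, H = 4), +1),
    "C5H7O2N"  = chemSpecies("C5H7O2N", c(C = 5, H = 7, O = 2, N = 1), 0),
    "e-"       = chemSpecies("e-", numeric(0), -1)
  )
}

#' Look up a built-in chemical species
#'
#' @param name Species label, e.g. `"SO42-"`.
#' @return A [chemSpecies()] with its elemental composition and charge.
#' @examples
#' speciesByName("C5H7O2N")  # the standard biomass formula
#' @export
speciesByName <- function(name) {
  reg <- .speciesRegistry()
  if (!name %in% names(reg)) {
    stop("unknown species composition: ", name)
  }
  reg[[name]]
}

## normalise a user coefficient into c(num, den)
.asCoef <- function(x) {
  if (length(x) == 1L) x <- c(x, 1)
  if (length(x) != 2L || any(x <= 0) || any(x != round(x))) {
    stop("coefficients must be positive integers or c(numerator, denominator) pairs")
  }
  as.numeric(x)
}

#' @rdname reaction
#' @export
reaction <- function(name, reactants, products) {
  pack <- function(lst, side) {
    if (length(lst) == 0L) return(NULL)
    co <- lapply(lst, .asCoef)
    list(species = names(lst), side = rep(side, length(lst)),
         num = unname(vapply(co, `[`, numeric(1), 1L)),
         den = unname(vapply(co, `[`, numeric(1), 2L)))
  }
  r <- pack(reactants, -1)
  p <- pack(products, +1)
  new("Reaction", name = name,
      species = c(r$species, p$species), side = c(r$side, p$side),
      num = c(r$num, p$num), den = c(r$den, p$den))
}

#' Built-in reaction library
#'
#' The reaction network of reductive bioleaching:
#' \describe{
#'   \item{`goethite_dissolution`}{FeOOH + 3 H+ <-> Fe3+ + 2 H2O — acid
#'     dissolution of the ferric oxyhydroxide ore phase.}
#'   \item{`sulfur_iron_reduction`}{6 Fe3+ + S0 + 4 H2O -> 6 Fe2+ + SO42- +
#'     8 H+ — the anaerobic microbial reduction of ferric iron coupled to
#'     sulfur oxidation, the core reaction of the process.}
#'   \item{`mno2_reduction`}{MnO2 + 2 Fe2+ + 4 H+ -> Mn2+ + 2 Fe3+ + 2 H2O —
#'     ferrous-driven dissolution of Mn oxides.}
#'   \item{`cell_synthesis`}{1/5 CO2 + 1/20 HCO3- + 1/20 NH4+ + H+ + e- ->
#'     1/20 C5H7O2N + 9/20 H2O — cell synthesis with ammonium as nitrogen
#'     source, fixing the biomass C:N ratio at 5:1.}
#'   \item{`sulfur_aerobic_oxidation`}{S0 + 3/2 O2 + H2O -> SO42- + 2 H+ —
#'     the aerobic growth-stage sulfur oxidation. This one is an
#'     implementation addition used by the cascade simulator, written here
#'     in its textbook form.}
#' }
#'
#' @param name One of the reaction labels above.
#' @return A [reaction()] object with exact rational coefficients.
#' @examples
#' checkBalance(reactionByName("cell_synthesis"))
#' @export
reactionByName <- function(name) {
  lib <- list(
    goethite_dissolution = reaction("goethite_dissolution",
      reactants = list("FeOOH" = 1, "H+" = 3),
      products = list("Fe3+" = 1, "H2O" = 2)),
    sulfur_iron_reduction = reaction("sulfur_iron_reduction",
      reactants = list("Fe3+" = 6, "S0" = 1, "H2O" = 4),
      products = list("Fe2+" = 6, "SO42-" = 1, "H+" = 8)),
    mno2_reduction = reaction("mno2_reduction",
      reactants = list("MnO2" = 1, "Fe2+" = 2, "H+" = 4),
      products = list("Mn2+" = 1, "Fe3+" = 2, "H2O" = 2)),
    cell_synthesis = reaction("cell_synthesis",
      reactants = list("CO2" = c(1, 5), "HCO3-" = c(1, 20),
                       "NH4+" = c(1, 20), "H+" = 1, "e-" = 1),
      products = list("C5H7O2N" = c(1, 20), "H2O" = c(9, 20))),
    sulfur_aerobic_oxidation = reaction("sulfur_aerobic_oxidation",
      reactants = list("S0" = 1, "O2" = c(3, 2), "H2O" = 1),
      products = list("SO42-" = 1, "H+" = 2))
  )
  if (!name %in% names(lib)) {
    stop("unknown reaction: ", name, " (available: ",
         paste(names(lib), collapse = ", "), ")")
  }
  lib[[name]]
}

#' Check element and charge balance of a reaction
#'
#' Computes, in exact rational arithmetic, the product-minus-reactant
#' residual of every element appearing in the reaction and of the net
#' charge (electrons counted with charge -1). A reaction is balanced iff
#' all residuals are exactly zero.
#'
#' @param reaction A [reaction()].
#' @return A list with `residuals` (named numeric: one entry per element
#'   plus `"charge"`, exact zeros for balanced reactions) and `balanced`
#'   (logical).
#' @examples
#' checkBalance(reactionByName("sulfur_iron_reduction"))$balanced  # TRUE
#' @export
setMethod("checkBalance", "Reaction", function(reaction) {
  sp <- lapply(reaction@species, speciesByName)
  elements <- unique(unlist(lapply(sp, function(s) names(s@elements))))
  residuals <- c(
    vapply(elements, function(el) {
      counts <- vapply(sp, function(s) {
        if (el %in% names(s@elements)) s@elements[[el]] else 0
      }, numeric(1))
      .ratAsNumeric(.ratSum(reaction@side * reaction@num * counts,
                            reaction@den))
    }, numeric(1)),
    charge = .ratAsNumeric(.ratSum(
      reaction@side * reaction@num *
        vapply(sp, function(s) s@charge, numeric(1)),
      reaction@den))
  )
  list(residuals = residuals, balanced = all(residuals == 0))
})

## ------------------------------------------------- oxidation-state bookkeeping

#' Oxidation state of an element within a species
#'
#' Assigns oxygen -2 and hydrogen +1 (the usual bookkeeping rules for these
#' oxo/aqua species) and solves the charge balance for the remaining
#' element. This is how the electron couplings below are derived, rather
#' than hard-coding them.
#'
#' @param speciesName A species label known to [speciesByName()].
#' @param element The element whose oxidation state is wanted.
#' @return The oxidation state (numeric).
#' @examples
#' oxidationState("SO42-", "S")  # +6
#' oxidationState("MnO2", "Mn")  # +4
#' @export
oxidationState <- function(speciesName, element) {
  s <- speciesByName(speciesName)
  if (!element %in% names(s@elements)) {
    stop("species ", speciesName, " contains no ", element)
  }
  fixed <- c(O = -2, H = +1)
  if (element %in% names(fixed)) return(unname(fixed[element]))
  others <- setdiff(names(s@elements), element)
  unknown <- setdiff(others, names(fixed))
  if (length(unknown) > 0L) {
    stop("cannot assign oxidation states in ", speciesName,
         ": multiple non-O/H elements")
  }
  known <- sum(fixed[others] * s@elements[others])
  (s@charge - known) / s@elements[[element]]
}

#' Electrons transferred per atom in a redox couple
#'
#' @param fromSpecies,toSpecies Species labels of the reduced/oxidised forms.
#' @param element The redox-active element.
#' @return Oxidation-state change (positive when `fromSpecies` is oxidised
#'   to `toSpecies`, i.e. electrons released).
#' @examples
#' electronTransfer("S0", "SO42-", "S")  # 6 electrons released
#' @export
electronTransfer <- function(fromSpecies, toSpecies, element) {
  oxidationState(toSpecies, element) - oxidationState(fromSpecies, element)
}

#' Ferric iron demand per sulfur oxidised
#'
#' Moles of Fe3+ reduced per mole of elemental sulfur fully oxidised to
#' sulfate, from electron balance: S(0) -> S(+VI) releases six electrons,
#' each reducing one Fe3+ to Fe2+. Equals the coefficient ratio of the
#' `sulfur_iron_reduction` reaction.
#'
#' @return The molar ratio (6).
#' @examples
#' fe3PerS0()
#' @export
fe3PerS0 <- function() {
  electronTransfer("S0", "SO42-", "S") /
    abs(electronTransfer("Fe3+", "Fe2+", "Fe"))
}

#' Ferrous iron demand per Mn oxide reduced
#'
#' Moles of Fe2+ oxidised per mole of MnO2 dissolved: Mn(+IV) -> Mn(+II)
#' takes two electrons, each supplied by one Fe2+ -> Fe3+.
#'
#' @return The molar ratio (2).
#' @examples
#' fe2PerMnO2()
#' @export
fe2PerMnO2 <- function() {
  abs(electronTransfer("MnO2", "Mn2+", "Mn")) /
    electronTransfer("Fe2+", "Fe3+", "Fe")
}

## ------------------------------------------------------ biomass nitrogen demand

#' Biomass carbon-to-nitrogen ratio of the cell-synthesis reaction
#'
#' Molar C:N ratio implied by the cell-synthesis stoichiometry: carbon from
#' both CO2 and bicarbonate over nitrogen from ammonium,
#' (1/5 + 1/20) : 1/20 = 5 : 1 — consistent with the C5H7O2N biomass
#' formula.
#'
#' @return The ratio (5).
#' @examples
#' biomassCNRatio()
#' @export
biomassCNRatio <- function() {
  rxn <- reactionByName("cell_synthesis")
  co <- function(name) {
    i <- which(rxn@species == name)
    unname(rxn@num[i] / rxn@den[i])
  }
  (co("CO2") + co("HCO3-")) / co("NH4+")
}

#' Ammonium demand from carbon dioxide uptake
#'
#' Converts a volumetric CO2 uptake rate into the ammonium demand of biomass
#' synthesis: the molar CO2 flux is `co2Uptake * volume / 44.01` mmol h-1,
#' and each mole of CO2 fixed requires the NH4+/CO2 coefficient ratio of the
#' cell-synthesis reaction, i.e. one quarter mole of ammonium. At the
#' literature CO2 uptake of 40 mg L-1 h-1 in a 2 L reactor this gives about
#' 0.455 mmol h-1.
#'
#' @param co2Uptake Volumetric CO2 uptake rate, mg L-1 h-1 (>= 0).
#' @param volume Liquid volume, L (>= 0).
#' @return Ammonium demand, mmol h-1.
#' @examples
#' ammoniumDemandFromCO2(40, 2)  # ~0.455
#' @export
ammoniumDemandFromCO2 <- function(co2Uptake, volume) {
  if (co2Uptake < 0 || volume < 0) {
    stop("co2Uptake and volume must be nonnegative")
  }
  rxn <- reactionByName("cell_synthesis")
  co <- function(name) {
    i <- which(rxn@species == name)
    unname(rxn@num[i] / rxn@den[i])
  }
  co2Flux <- co2Uptake * volume / unname(molarMassOf("CO2"))   # mmol/h
  co2Flux * co("NH4+") / co("CO2")
}
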