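## S4 classes for the iron bioreduction kinetics toolkit.

## ---------------------------------------------------------------- speciation

#' Nernst calibration of the Fe(III)/Fe(II) couple
#'
#' A `RedoxCalibration` holds the effective (formal) midpoint potential of the
#' Fe3+/Fe2+ couple in the actual leaching medium and the temperature, which
#' together define the map between measured redox potential (mV vs SHE) and
#' the Fe(III)/Fe(II) concentration ratio. The Nernst slope
#' \eqn{s = \ln(10) R T / F} (mV per decade of concentration ratio) is derived
#' from the temperature; at 308.15 K it is about 61.1 mV.
#'
#' The default formal potential of 676.6 mV vs SHE is a calibration derived
#' from the two continuous-pilot steady states (680 mV at 53\% Fe(III) and
#' 650 mV at 27\% Fe(III)) at 35 degrees C; activity and sulfate-complexation
#' effects are absorbed into this single effective value.
#'
#' @param formalPotential Formal potential of the Fe3+/Fe2+ couple,
#'   mV vs SHE.
#' @param temperature Temperature in kelvin; must exceed 273.15 K.
#' @return `redoxCalibration()` returns a `RedoxCalibration` object.
#'   `formalPotential()` and `temperatureK()` return the slots; `nernstSlope()`
#'   the derived slope in mV per decade.
#' @examples
#' cal <- redoxCalibration()
#' nernstSlope(cal)                 # ~61.1 mV per decade at 308.15 K
#' ratioFromEh(680, cal)
#' @name redoxCalibration
#' @aliases RedoxCalibration-class
#' @export
setClass("RedoxCalibration",
  representation(formalPotential = "numeric", temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@formalPotential) != 1L || !is.finite(object@formalPotential))
      msg <- c(msg, "formalPotential must be a single finite number (mV vs SHE)")
    if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
        object@temperature <= 273.15)
      msg <- c(msg, "temperature must be a single value > 273.15 K")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname redoxCalibration
#' @export
redoxCalibration <- function(formalPotential = 676.6, temperature = 308.15) {
  new("RedoxCalibration", formalPotential = as.numeric(formalPotential),
      temperature = as.numeric(temperature))
}

#' Iron speciation
#'
#' An `IronSpeciation` partitions a total dissolved iron concentration into
#' its ferrous (Fe2+) and ferric (Fe3+) components, all in mg L-1. The two
#' components sum to the total to within 1e-9 relative by construction.
#'
#' @param feTotal,fe2,fe3 Numeric vectors of equal length, mg L-1.
#' @return An `IronSpeciation`. `fe2()`, `fe3()`, `feTotal()` return the
#'   components; `fe3Fraction()` the ferric fraction in \[0, 1\] (`NaN` where
#'   total iron is zero).
#' @examples
#' sp <- speciate(2400, 650, redoxCalibration())
#' fe3Fraction(sp)
#' @name ironSpeciation
#' @aliases IronSpeciation-class
#' @export
setClass("IronSpeciation",
  representation(feTotal = "numeric", fe2 = "numeric", fe3 = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@feTotal)
    if (length(object@fe2) != n || length(object@fe3) != n)
      msg <- c(msg, "feTotal, fe2 and fe3 must have equal length")
    if (any(object@feTotal < 0) || any(object@fe2 < 0) || any(object@fe3 < 0))
      msg <- c(msg, "concentrations must be nonnegative")
    tol <- 1e-9 * pmax(object@feTotal, 1)
    if (any(abs(object@fe2 + object@fe3 - object@feTotal) > tol))
      msg <- c(msg, "fe2 + fe3 must equal feTotal within 1e-9 relative")
    if (length(msg)) msg else TRUE
  }
)

## --------------------------------------------------------------------- rates

#' Bioreduction monitoring time series
#'
#' A `BioreductionSeries` holds the monitoring record of one reactor run:
#' sampling times (hours, strictly increasing, at least two points), the
#' Fe(II) concentration trace (mg L-1), and optional channels for redox
#' potential (mV vs SHE), total iron (mg L-1) and planktonic cell counts
#' (cells mL-1). Optional channels are either empty or the same length as
#' the time grid.
#'
#' @param times Sampling times in hours, strictly increasing, length >= 2.
#' @param fe2 Fe(II) concentrations, mg L-1, same length as `times`.
#' @param eh Optional redox potential channel, mV vs SHE.
#' @param feTotal Optional total iron channel, mg L-1.
#' @param cells Optional planktonic cell count channel, cells mL-1.
#' @return A `BioreductionSeries`; accessors return the channels (optional
#'   ones as `numeric(0)` when absent).
#' @examples
#' s <- bioreductionSeries(times = c(0, 24, 48), fe2 = c(0, 50, 95))
#' meanRate(s)
#' maxRate(s)
#' @name bioreductionSeries
#' @aliases BioreductionSeries-class
#' @export
setClass("BioreductionSeries",
  representation(times = "numeric", fe2 = "numeric", eh = "numeric",
                 feTotal = "numeric", cells = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@times)
    if (n < 2L) msg <- c(msg, "at least two time points are required")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(object@fe2) != n)
      msg <- c(msg, "fe2 must have the same length as times")
    if (any(object@fe2 < 0)) msg <- c(msg, "fe2 must be nonnegative")
    for (ch in c("eh", "feTotal", "cells")) {
      v <- slot(object, ch)
      if (length(v) != 0L && length(v) != n)
        msg <- c(msg, sprintf("%s must be empty or the same length as times", ch))
    }
    if (any(object@feTotal < 0) || any(object@cells < 0))
      msg <- c(msg, "feTotal and cells must be nonnegative")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname bioreductionSeries
#' @export
bioreductionSeries <- function(times, fe2, eh = NULL, feTotal = NULL,
                               cells = NULL) {
  new("BioreductionSeries",
      times = as.numeric(times), fe2 = as.numeric(fe2),
      eh = if (is.null(eh)) numeric(0) else as.numeric(eh),
      feTotal = if (is.null(feTotal)) numeric(0) else as.numeric(feTotal),
      cells = if (is.null(cells)) numeric(0) else as.numeric(cells))
}

#' Pair of batch rate estimates
#'
#' A `RateEstimate` bundles the two batch-mode kinetic summaries: the mean
#' Fe(II) production rate over the bioreduction period and the maximal rate
#' between two consecutive measurements, both in mg L-1 h-1. The maximal
#' rate is never below the mean rate, since the mean is a duration-weighted
#' average of the consecutive-increment rates.
#'
#' @name rateEstimate
#' @aliases RateEstimate-class
#' @seealso [maxRate()], [meanRate()], [bioreductionRates()]
#' @export
setClass("RateEstimate",
  representation(meanRate = "numeric", maxRate = "numeric"),
  validity = function(object) {
    if (length(object@meanRate) != 1L || length(object@maxRate) != 1L)
      return("meanRate and maxRate must be single numbers")
    if (object@maxRate < object@meanRate - 1e-9 * max(1, abs(object@meanRate)))
      return("maxRate must be >= meanRate")
    TRUE
  }
)

#' Linear biomass-rate law
#'
#' A `RateLaw` is the empirical affine relation between planktonic biomass
#' concentration and volumetric Fe(III) bioreduction rate,
#' \eqn{v = a X + b}, with `slope` \eqn{a} in mg L-1 h-1 per cells mL-1,
#' `intercept` \eqn{b} in mg L-1 h-1, and the coefficient of determination
#' `r2` of the fit (or `NA` for a law stated rather than fitted).
#'
#' @param slope Slope in mg L-1 h-1 per cells mL-1.
#' @param intercept Intercept in mg L-1 h-1.
#' @param r2 Coefficient of determination in \[0, 1\], or `NA`.
#' @return A `RateLaw`. `rateSlope()`, `rateIntercept()`, `rateR2()` return
#'   the slots; `coef()` returns `c(slope, intercept)`.
#' @examples
#' law <- rateLaw(3.46e-9, 1.55)
#' predictRate(law, 2e9)
#' @name rateLaw
#' @aliases RateLaw-class
#' @export
setClass("RateLaw",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@slope) != 1L || length(object@intercept) != 1L)
      msg <- c(msg, "slope and intercept must be single numbers")
    if (length(object@r2) != 1L ||
        (!is.na(object@r2) && (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)))
      msg <- c(msg, "r2 must be a single value in [0, 1] or NA")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname rateLaw
#' @export
rateLaw <- function(slope, intercept, r2 = NA_real_) {
  new("RateLaw", slope = as.numeric(slope), intercept = as.numeric(intercept),
      r2 = as.numeric(r2))
}

## ------------------------------------------------------------- stoichiometry

#' Chemical species with elemental composition and charge
#'
#' @param name Species label, e.g. `"Fe3+"`.
#' @param elements Named integer vector of element counts, e.g.
#'   `c(Fe = 1)`; counts must be nonnegative.
#' @param charge Integer net charge (electrons have charge -1).
#' @return A `Species`.
#' @examples
#' chemSpecies("SO42-", c(S = 1, O = 4), -2)
#' @name chemSpecies
#' @aliases Species-class
#' @export
setClass("Species",
  representation(name = "character", elements = "numeric", charge = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a nonempty string")
    if (length(object@elements) > 0L &&
        (is.null(names(object@elements)) || any(!nzchar(names(object@elements)))))
      msg <- c(msg, "elements must be a named vector")
    if (any(object@elements < 0) || any(object@elements != round(object@elements)))
      msg <- c(msg, "element counts must be nonnegative integers")
    if (length(object@charge) != 1L || object@charge != round(object@charge))
      msg <- c(msg, "charge must be a single integer")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname chemSpecies
#' @export
chemSpecies <- function(name, elements = numeric(0), charge = 0) {
  new("Species", name = name, elements = as.numeric(elements) |>
        stats::setNames(names(elements)), charge = as.numeric(charge))
}

#' Stoichiometric reaction with exact rational coefficients
#'
#' A `Reaction` stores reactant and product coefficients as exact rationals
#' (integer numerator/denominator pairs), so that element and charge balance
#' checks are exact even for reactions written with fractional coefficients
#' such as the twentieths of the cell-synthesis reaction.
#'
#' @param name Reaction label.
#' @param reactants,products Named lists mapping species names to
#'   coefficients; each coefficient is either a single positive number
#'   (integer) or a length-2 integer vector `c(numerator, denominator)`.
#' @return A `Reaction`.
#' @examples
#' rxn <- reactionByName("sulfur_iron_reduction")
#' checkBalance(rxn)
#' @name reaction
#' @aliases Reaction-class
#' @export
setClass("Reaction",
  representation(name = "character",
                 species = "character",   # species names, aligned
                 side = "numeric",        # -1 reactant, +1 product
                 num = "numeric", den = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@species)
    if (length(object@side) != n || length(object@num) != n ||
        length(object@den) != n)
      msg <- c(msg, "species, side, num and den must be aligned")
    if (any(!object@side %in% c(-1, 1)))
      msg <- c(msg, "side must be -1 (reactant) or +1 (product)")
    if (any(object@num <= 0) || any(object@den <= 0))
      msg <- c(msg, "coefficients must be positive rationals")
    if (any(object@num != round(object@num)) || any(object@den != round(object@den)))
      msg <- c(msg, "numerators and denominators must be integers")
    if (length(msg)) msg else TRUE
  }
)

## ------------------------------------------------------------------ reactors

#' Batch bioreduction reactor configuration
#'
#' Configuration of an anaerobic stirred-tank batch run: a fixed liquid
#' volume holding Fe(III)/Fe(II) with a constant planktonic biomass (no
#' anaerobic growth is observed in the liquid phase), reduction following a
#' [rateLaw()], and an optional first-order Fe(III) precipitation sink.
#'
#' @param volume Liquid volume, L.
#' @param initialFe3,initialFe2 Initial concentrations, mg L-1.
#' @param biomass Constant planktonic biomass, cells mL-1.
#' @param rateLaw A [rateLaw()] giving the volumetric reduction rate.
#' @param kPrecip First-order Fe(III) precipitation rate constant, h-1
#'   (default 0, i.e. no precipitation).
#' @param duration Simulated duration, h.
#' @param outputStep Output grid spacing, h.
#' @return A `BatchConfig`.
#' @examples
#' cfg <- batchConfig(biomass = 2e9, rateLaw = rateLaw(3.46e-9, 1.55))
#' @name batchConfig
#' @aliases BatchConfig-class
#' @export
setClass("BatchConfig",
  representation(volume = "numeric", initialFe3 = "numeric",
                 initialFe2 = "numeric", biomass = "numeric",
                 rateLaw = "RateLaw", kPrecip = "numeric",
                 duration = "numeric", outputStep = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("volume", "initialFe3", "initialFe2", "biomass", "kPrecip",
                "duration", "outputStep")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v < 0)
        msg <- c(msg, sprintf("%s must be a single nonnegative number", s))
    }
    if (length(object@duration) == 1L && object@duration <= 0)
      msg <- c(msg, "duration must be positive")
    if (length(object@outputStep) == 1L && object@outputStep <= 0)
      msg <- c(msg, "outputStep must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname batchConfig
#' @export
batchConfig <- function(volume = 2, initialFe3 = 4500, initialFe2 = 0,
                        biomass = 2e9, rateLaw = ferrokin::rateLaw(3.46e-9, 1.55),
                        kPrecip = 0, duration = 288, outputStep = 24) {
  new("BatchConfig", volume = as.numeric(volume),
      initialFe3 = as.numeric(initialFe3), initialFe2 = as.numeric(initialFe2),
      biomass = as.numeric(biomass), rateLaw = rateLaw,
      kPrecip = as.numeric(kPrecip), duration = as.numeric(duration),
      outputStep = as.numeric(outputStep))
}

#' Growth (sulfur oxidation) chemostat configuration
#'
#' First stage of the continuous cascade: an aerated CSTR where biomass grows
#' on elemental sulfur while nutrients are fed continuously. Growth is
#' modelled as logistic with dilution (the study reports only steady-state
#' cell densities, not growth kinetics); nutrient uptake is proportional to
#' biomass.
#'
#' @param volume Liquid volume, L.
#' @param inflow Feed flow rate, mL h-1.
#' @param inletConc Named numeric vector of inlet nutrient concentrations,
#'   mg L-1.
#' @param carryingCapacity Biomass carrying capacity, cells mL-1.
#' @param growthRate Maximal specific growth rate, h-1.
#' @param uptakeRates Named numeric vector, per-biomass nutrient uptake
#'   coefficients in mg L-1 h-1 per (cells mL-1); names must match
#'   `inletConc`.
#' @param initialBiomass Initial biomass, cells mL-1.
#' @return A `GrowthReactorConfig`.
#' @examples
#' cfg <- growthReactorConfig(inletConc = c("NH4+" = 127),
#'                            uptakeRates = c("NH4+" = 4.7e-10))
#' hydraulicResidenceTime(cfg)
#' @name growthReactorConfig
#' @aliases GrowthReactorConfig-class
#' @export
setClass("GrowthReactorConfig",
  representation(volume = "numeric", inflow = "numeric", inletConc = "numeric",
                 carryingCapacity = "numeric", growthRate = "numeric",
                 uptakeRates = "numeric", initialBiomass = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@volume <= 0) msg <- c(msg, "volume must be positive")
    if (object@inflow <= 0) msg <- c(msg, "inflow must be positive")
    if (any(object@inletConc < 0)) msg <- c(msg, "inletConc must be nonnegative")
    if (object@carryingCapacity <= 0)
      msg <- c(msg, "carryingCapacity must be positive")
    if (object@growthRate < 0) msg <- c(msg, "growthRate must be nonnegative")
    if (any(object@uptakeRates < 0))
      msg <- c(msg, "uptakeRates must be nonnegative")
    if (!setequal(names(object@inletConc), names(object@uptakeRates)))
      msg <- c(msg, "inletConc and uptakeRates must have matching names")
    if (object@initialBiomass < 0)
      msg <- c(msg, "initialBiomass must be nonnegative")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname growthReactorConfig
#' @export
growthReactorConfig <- function(volume = 2, inflow = 26.5,
                                inletConc = c("NH4+" = 127),
                                carryingCapacity = 2.2e9,
                                growthRate = 0.2,
                                uptakeRates = c("NH4+" = 4.7e-10),
                                initialBiomass = 1e8) {
  new("GrowthReactorConfig", volume = as.numeric(volume),
      inflow = as.numeric(inflow),
      inletConc = as.numeric(inletConc) |> stats::setNames(names(inletConc)),
      carryingCapacity = as.numeric(carryingCapacity),
      growthRate = as.numeric(growthRate),
      uptakeRates = as.numeric(uptakeRates[names(inletConc)]) |>
        stats::setNames(names(inletConc)),
      initialBiomass = as.numeric(initialBiomass))
}

#' Bioreduction chemostat configuration
#'
#' Second stage of the cascade: an anaerobic constant-volume CSTR receiving
#' the pulp outflow of the growth reactor plus a concentrated ferric sulfate
#' feed. Biomass behaves as a conservative tracer (no anaerobic growth in the
#' liquid phase); Fe(III) is reduced according to the biomass-rate law, with
#' an optional first-order precipitation sink.
#'
#' @param volume Liquid volume, L.
#' @param pulpInflow Pulp flow from the growth stage, mL h-1.
#' @param feedFe3 Fe(III) concentration of the ferric feed, mg L-1
#'   (default 22000, i.e. 22 g L-1).
#' @param feedFlow Ferric feed flow rate, mL h-1.
#' @param rateLaw A [rateLaw()].
#' @param kPrecip First-order Fe(III) precipitation constant, h-1.
#' @return A `ReductionReactorConfig`. The outflow equals the sum of the two
#'   inflows (constant volume).
#' @examples
#' cfg <- reductionReactorConfig()
#' hydraulicResidenceTime(cfg)
#' @name reductionReactorConfig
#' @aliases ReductionReactorConfig-class
#' @export
setClass("ReductionReactorConfig",
  representation(volume = "numeric", pulpInflow = "numeric",
                 feedFe3 = "numeric", feedFlow = "numeric",
                 rateLaw = "RateLaw", kPrecip = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@volume <= 0) msg <- c(msg, "volume must be positive")
    if (object@pulpInflow < 0 || object@feedFlow < 0)
      msg <- c(msg, "flows must be nonnegative")
    if (object@pulpInflow + object@feedFlow <= 0)
      msg <- c(msg, "total inflow must be positive")
    if (object@feedFe3 < 0) msg <- c(msg, "feedFe3 must be nonnegative")
    if (object@kPrecip < 0) msg <- c(msg, "kPrecip must be nonnegative")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname reductionReactorConfig
#' @export
reductionReactorConfig <- function(volume = 4, pulpInflow = 26.5,
                                   feedFe3 = 22000, feedFlow = 3,
                                   rateLaw = ferrokin::rateLaw(3.46e-9, 1.55),
                                   kPrecip = 0) {
  new("ReductionReactorConfig", volume = as.numeric(volume),
      pulpInflow = as.numeric(pulpInflow), feedFe3 = as.numeric(feedFe3),
      feedFlow = as.numeric(feedFlow), rateLaw = rateLaw,
      kPrecip = as.numeric(kPrecip))
}

#' Two-stage cascade configuration
#'
#' Couples a growth chemostat ([growthReactorConfig()]) to a downstream
#' bioreduction chemostat ([reductionReactorConfig()]), mirroring the pilot
#' layout: the growth-stage outflow is the pulp inflow of the reduction
#' stage.
#'
#' @param growth A `GrowthReactorConfig`.
#' @param reduction A `ReductionReactorConfig`; its `pulpInflow` should equal
#'   the growth-stage inflow (constant-volume stages).
#' @return A `CascadeConfig`.
#' @examples
#' cc <- cascadeConfig()
#' @name cascadeConfig
#' @aliases CascadeConfig-class
#' @export
setClass("CascadeConfig",
  representation(growth = "GrowthReactorConfig",
                 reduction = "ReductionReactorConfig"))

#' @rdname cascadeConfig
#' @export
cascadeConfig <- function(growth = growthReactorConfig(),
                          reduction = reductionReactorConfig()) {
  new("CascadeConfig", growth = growth, reduction = reduction)
}

#' Simulation result container
#'
#' Holds the output grid (hours), the state trajectories (one column per
#' state, units as in the configuring object), the final-state snapshot
#' taken as the steady-state estimate, and solver diagnostics including
#' mass-balance residuals.
#'
#' @name simulationResult
#' @aliases SimulationResult-class
#' @export
setClass("SimulationResult",
  representation(times = "numeric", states = "matrix",
                 steadyState = "numeric", diagnostics = "list"),
  validity = function(object) {
    if (nrow(object@states) != length(object@times))
      return("states must have one row per time point")
    if (any(object@states < -1e-8))
      return("states must be nonnegative")
    TRUE
  }
)

## ------------------------------------------------------------ synthetic data

#' Parameters of the synthetic batch-experiment generator
#'
#' Defines the study conditions the generator emulates: a true biomass-rate
#' law, the panel of biomass levels, the initial ferric iron charge, daily
#' sampling over twelve days, Gaussian noise on the redox electrode and
#' lognormal noise on microscopic cell counts. A seed fixes all randomness.
#'
#' @param rateLaw True generating [rateLaw()].
#' @param biomassLevels Biomass levels of the experiment panel, cells mL-1.
#' @param initialFe3 Initial Fe(III), mg L-1 (default 4500).
#' @param samplingInterval Sampling cadence, h (default 24: daily).
#' @param duration Experiment duration, h (default 288: twelve days).
#' @param ehNoiseSd Gaussian noise standard deviation on the redox channel,
#'   mV (default 5).
#' @param cellNoiseSigma Lognormal sigma of the cell-count noise
#'   (default 0.15).
#' @param kPrecip First-order Fe(III) precipitation constant, h-1.
#' @param seed Integer seed fixing all randomness.
#' @param calibration [redoxCalibration()] used to synthesise the redox
#'   channel.
#' @return A `SyntheticBatchParams`.
#' @examples
#' p <- syntheticBatchParams(seed = 1)
#' s <- generateBatchExperiment(p, 2e9)
#' @name syntheticBatchParams
#' @aliases SyntheticBatchParams-class
#' @export
setClass("SyntheticBatchParams",
  representation(rateLaw = "RateLaw", biomassLevels = "numeric",
                 initialFe3 = "numeric", samplingInterval = "numeric",
                 duration = "numeric", ehNoiseSd = "numeric",
                 cellNoiseSigma = "numeric", kPrecip = "numeric",
                 seed = "integer", calibration = "RedoxCalibration"),
  validity = function(object) {
    msg <- character()
    if (length(object@biomassLevels) < 1L || any(object@biomassLevels < 0))
      msg <- c(msg, "biomassLevels must be nonnegative")
    if (object@ehNoiseSd < 0 || object@cellNoiseSigma < 0)
      msg <- c(msg, "noise parameters must be nonnegative")
    if (object@samplingInterval <= 0 || object@duration <= 0)
      msg <- c(msg, "samplingInterval and duration must be positive")
    if (object@kPrecip < 0) msg <- c(msg, "kPrecip must be nonnegative")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname syntheticBatchParams
#' @export
syntheticBatchParams <- function(rateLaw = ferrokin::rateLaw(3.46e-9, 1.55),
                                 biomassLevels = c(3e8, 2e9, 5e9),
                                 initialFe3 = 4500, samplingInterval = 24,
                                 duration = 288, ehNoiseSd = 5,
                                 cellNoiseSigma = 0.15, kPrecip = 0,
                                 seed = 1L,
                                 calibration = redoxCalibration()) {
  new("SyntheticBatchParams", rateLaw = rateLaw,
      biomassLevels = as.numeric(biomassLevels),
      initialFe3 = as.numeric(initialFe3),
      samplingInterval = as.numeric(samplingInterval),
      duration = as.numeric(duration), ehNoiseSd = as.numeric(ehNoiseSd),
      cellNoiseSigma = as.numeric(cellNoiseSigma),
      kPrecip = as.numeric(kPrecip), seed = as.integer(seed),
      calibration = calibration)
}

## ----------------------------------------------------------------- accessors

#' @rdname redoxCalibration
setMethod("formalPotential", "RedoxCalibration", function(object)
  object@formalPotential)

#' @rdname redoxCalibration
setMethod("temperatureK", "RedoxCalibration", function(object)
  object@temperature)

#' @rdname redoxCalibration
setMethod("nernstSlope", "RedoxCalibration", function(object) {
  cst <- ferrokinConstants()
  log(10) * cst$gasConstant * object@temperature / cst$faraday * 1000
})

#' @rdname bioreductionSeries
setMethod("sampleTimes", "BioreductionSeries", function(object) object@times)

#' @rdname bioreductionSeries
setMethod("fe2", "BioreductionSeries", function(object) object@fe2)

#' @rdname bioreductionSeries
setMethod("feTotal", "BioreductionSeries", function(object) object@feTotal)

#' @rdname bioreductionSeries
setMethod("ehValues", "BioreductionSeries", function(object) object@eh)

#' @rdname bioreductionSeries
setMethod("cellCounts", "BioreductionSeries", function(object) object@cells)

#' @rdname ironSpeciation
setMethod("fe2", "IronSpeciation", function(object) object@fe2)

#' @rdname ironSpeciation
setMethod("fe3", "IronSpeciation", function(object) object@fe3)

#' @rdname ironSpeciation
setMethod("feTotal", "IronSpeciation", function(object) object@feTotal)

#' @rdname ironSpeciation
setMethod("fe3Fraction", "IronSpeciation", function(object)
  ifelse(object@feTotal > 0, object@fe3 / object@feTotal, NaN))

#' @rdname rateLaw
setMethod("rateSlope", "RateLaw", function(object) object@slope)

#' @rdname rateLaw
setMethod("rateIntercept", "RateLaw", function(object) object@intercept)

#' @rdname rateLaw
setMethod("rateR2", "RateLaw", function(object) object@r2)

#' @rdname rateLaw
#' @param object A `RateLaw`.
#' @param ... Ignored.
#' @export
setMethod("coef", "RateLaw", function(object, ...)
  c(slope = object@slope, intercept = object@intercept))

#' @rdname rateEstimate
#' @param series A `BioreductionSeries`.
#' @export
setMethod("meanRate", "RateEstimate", function(series, ...) series@meanRate)

#' @rdname rateEstimate
#' @export
setMethod("maxRate", "RateEstimate", function(series, ...) series@maxRate)

#' @rdname simulationResult
setMethod("sampleTimes", "SimulationResult", function(object) object@times)

#' @rdname simulationResult
setMethod("stateTrajectories", "SimulationResult", function(object)
  object@states)

#' @rdname simulationResult
setMethod("steadyStateOf", "SimulationResult", function(object)
  object@steadyState)

#' @rdname simulationResult
setMethod("diagnosticsOf", "SimulationResult", function(object)
  object@diagnostics)

## ---------------------------------------------------------------------- show

setMethod("show", "RedoxCalibration", function(object) {
  cat(sprintf(
    "RedoxCalibration: E0' = %.1f mV vs SHE, T = %.2f K (slope %.2f mV/decade)\n",
    object@formalPotential, object@temperature, nernstSlope(object)))
})

setMethod("show", "IronSpeciation", function(object) {
  cat(sprintf("IronSpeciation with %d sample(s)\n", length(object@feTotal)))
  n <- min(5L, length(object@feTotal))
  print(data.frame(feTotal = object@feTotal[seq_len(n)],
                   fe2 = object@fe2[seq_len(n)], fe3 = object@fe3[seq_len(n)]))
  if (length(object@feTotal) > n) cat("...\n")
})

setMethod("show", "BioreductionSeries", function(object) {
  cat(sprintf("BioreductionSeries: %d samples over %.1f h", length(object@times),
              diff(range(object@times))))
  opt <- c("eh", "feTotal", "cells")[c(length(object@eh) > 0,
                                       length(object@feTotal) > 0,
                                       length(object@cells) > 0)]
  if (length(opt)) cat(" (channels: fe2, ", paste(opt, collapse = ", "), ")", sep = "")
  cat("\n")
})

setMethod("show", "RateLaw", function(object) {
  cat(sprintf("RateLaw: v = %.3g * X + %.3g mg/L/h", object@slope,
              object@intercept))
  if (!is.na(object@r2)) cat(sprintf("  (R2 = %.3f)", object@r2))
  cat("\n")
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: mean %.3g, max %.3g mg/L/h\n", object@meanRate,
              object@maxRate))
})

setMethod("show", "Reaction", function(object) {
  fmtCoef <- function(num, den) {
    if (den == 1 && num == 1) "" else if (den == 1) paste0(num, " ")
    else paste0(num, "/", den, " ")
  }
  fmtSide <- function(keep) {
    paste(mapply(function(n, d, s) paste0(fmtCoef(n, d), s),
                 object@num[keep], object@den[keep], object@species[keep]),
          collapse = " + ")
  }
  cat(sprintf("Reaction '%s':\n  %s -> %s\n", object@name,
              fmtSide(object@side == -1), fmtSide(object@side == 1)))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d output times, states: %s\n",
              length(object@times), paste(colnames(object@states),
                                          collapse = ", ")))
  cat("steady state:\n")
  print(object@steadyState)
})
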