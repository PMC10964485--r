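## Seeded generators of synthetic batch experiments and cascade steady-state
## tables. These emulate the monitoring data the estimators consume: daily
## Fe(II)/Eh/cell-count trajectories in batch, and inlet/outlet nutrient
## tables plus steady-state records in continuous mode.

## clamp the Fe(III)/Fe(II) ratio so the synthetic Eh channel stays finite
## at full oxidation/reduction
.RATIO_CLAMP <- c(1e-8, 1e8)

#' Generate one synthetic batch bioreduction experiment
#'
#' Simulates a noiseless batch trajectory at the configured biomass level,
#' samples it at the monitoring cadence, and overlays the measurement
#' model: Gaussian noise on the redox-electrode channel (the Eh that a
#' probe would read given the true speciation) and multiplicative lognormal
#' noise on microscopic cell counts. The `fe2` channel carries the true
#' simulated concentrations; with all noise at zero the series is exactly
#' the simulator output. Reproducible: the same seed yields the same
#' series.
#'
#' @param params A [syntheticBatchParams()].
#' @param biomassLevel Biomass of this experiment, cells mL-1.
#' @param seed Integer seed (defaults to the seed in `params`).
#' @return A [bioreductionSeries()] with `fe2`, `eh`, `feTotal` and `cells`
#'   channels.
#' @examples
#' s <- generateBatchExperiment(syntheticBatchParams(seed = 7), 2e9)
#' @export
generateBatchExperiment <- function(params, biomassLevel, seed = params@seed) {
  stopifnot(is(params, "SyntheticBatchParams"))
  set.seed(seed)
  cfg <- batchConfig(initialFe3 = params@initialFe3, initialFe2 = 0,
                     biomass = biomassLevel, rateLaw = params@rateLaw,
                     kPrecip = params@kPrecip, duration = params@duration,
                     outputStep = params@samplingInterval)
  sim <- simulateBatch(cfg)
  st <- stateTrajectories(sim)
  fe3 <- st[, "fe3"]
  fe2 <- st[, "fe2"]
  feTot <- fe3 + fe2
  n <- length(fe2)
  ratio <- pmin(pmax(ifelse(fe2 > 0, fe3 / fe2, Inf),
                     .RATIO_CLAMP[1]), .RATIO_CLAMP[2])
  ehTrue <- ehFromRatio(ratio, params@calibration)
  eh <- ehTrue + stats::rnorm(n, 0, params@ehNoiseSd)
  cells <- biomassLevel * stats::rlnorm(n, 0, params@cellNoiseSigma)
  bioreductionSeries(sampleTimes(sim), fe2 = fe2, eh = eh, feTotal = feTot,
                     cells = cells)
}

## last index of the active bioreduction phase: samples with appreciable
## ferric iron remaining (5% of the initial charge)
.activePhaseEnd <- function(fe3est, initialFe3) {
  k <- which(fe3est > 0.05 * initialFe3)
  max(2L, if (length(k)) max(k) else 2L)
}

#' Generate a biomass-rate dataset from synthetic batch experiments
#'
#' Runs one synthetic batch experiment per biomass level (times
#' `replicates`) and applies the monitoring pipeline that the study design
#' implies: Fe(II) is estimated from the noisy redox channel via
#' [speciate()], the biomass from the geometric mean of the noisy cell
#' counts, and the mean rate from the active bioreduction phase (samples
#' with more than 5\% of the initial ferric charge remaining, so the
#' post-exhaustion plateau does not dilute the estimate).
#'
#' @param params A [syntheticBatchParams()].
#' @param replicates Number of replicate experiment panels (default 1).
#' @return Data frame with columns `biomass` (estimated, cells mL-1),
#'   `rate` (estimated mean rate, mg L-1 h-1), `level` (true biomass) and
#'   `replicate`.
#' @examples
#' d <- generateRateLawDataset(syntheticBatchParams(ehNoiseSd = 0,
#'                                                  cellNoiseSigma = 0))
#' fitRateLaw(d$biomass, d$rate)
#' @export
generateRateLawDataset <- function(params, replicates = 1L) {
  stopifnot(is(params, "SyntheticBatchParams"))
  rows <- list()
  for (rep in seq_len(replicates)) {
    for (i in seq_along(params@biomassLevels)) {
      level <- params@biomassLevels[i]
      s <- generateBatchExperiment(params, level,
                                   seed = params@seed + (rep - 1L) * 1000L + i)
      f <- fe3FractionFromEh(ehValues(s), params@calibration)
      fe2est <- feTotal(s) * (1 - f)
      fe3est <- feTotal(s) * f
      k <- .activePhaseEnd(fe3est, params@initialFe3)
      rate <- (fe2est[k] - fe2est[1]) / (sampleTimes(s)[k] - sampleTimes(s)[1])
      rows[[length(rows) + 1L]] <- data.frame(
        biomass = exp(mean(log(cellCounts(s)))), rate = rate,
        level = level, replicate = rep)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic cascade steady-state and nutrient tables
#'
#' Runs the two-stage cascade simulator to steady state and emits the two
#' tables the continuous-mode analysis consumes: an inlet/outlet nutrient
#' concentration table for the growth stage and a steady-state record for
#' the bioreduction stage (iron speciation, the redox potential a probe
#' would read, biomass, realised rate). Multiplicative lognormal
#' measurement noise is applied to all concentration and count entries;
#' with `noiseSigma = 0` the tables round-trip exactly through the nutrient
#' flux module.
#'
#' @param cascade A [cascadeConfig()].
#' @param noiseSigma Lognormal sigma of the measurement noise (default 0).
#' @param seed Integer seed.
#' @param calibration [redoxCalibration()] used for the synthetic Eh
#'   reading.
#' @return List with `nutrients` (data frame `species`, `inlet`, `outlet`),
#'   `steadyState` (named numeric for the reduction stage: `fe3`, `fe2`,
#'   `feTotal`, `fe3Fraction`, `eh`, `biomass`, `rate`), `growthBiomass`,
#'   `hrt` (growth-stage HRT, h) and `volume` (growth-stage volume, L).
#' @examples
#' tabs <- generateCascadeTables(cascadeConfig(), seed = 1)
#' tabs$steadyState
#' @export
generateCascadeTables <- function(cascade, noiseSigma = 0, seed = 1L,
                                  calibration = redoxCalibration()) {
  stopifnot(is(cascade, "CascadeConfig"))
  set.seed(seed)
  growth <- simulateGrowthReactor(cascade@growth)
  gss <- steadyStateOf(growth)
  red <- steadyState(cascade@reduction, growth)
  noisy <- function(x) x * stats::rlnorm(length(x), 0, noiseSigma)
  nut <- names(cascade@growth@inletConc)
  nutrients <- data.frame(species = nut,
                          inlet = noisy(unname(cascade@growth@inletConc)),
                          outlet = noisy(unname(gss[nut])))
  fe3n <- noisy(red[["fe3"]])
  fe2n <- noisy(red[["fe2"]])
  ratio <- pmin(pmax(fe3n / max(fe2n, 1e-12), .RATIO_CLAMP[1]), .RATIO_CLAMP[2])
  ss <- c(fe3 = fe3n, fe2 = fe2n, feTotal = fe3n + fe2n,
          fe3Fraction = fe3n / (fe3n + fe2n),
          eh = ehFromRatio(ratio, calibration),
          biomass = noisy(red[["biomass"]]), rate = red[["rate"]])
  list(nutrients = nutrients, steadyState = ss,
       growthBiomass = noisy(gss[["biomass"]]),
       hrt = hydraulicResidenceTime(cascade@growth),
       volume = cascade@growth@volume)
}
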