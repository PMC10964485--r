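test_that("noiseless generated series equals the simulator output and is seeded", {
  p <- syntheticBatchParams(ehNoiseSd = 0, cellNoiseSigma = 0, seed = 3L)
  s <- generateBatchExperiment(p, 2e9)
  sim <- simulateBatch(batchConfig(biomass = 2e9, rateLaw = p@rateLaw,
                                   initialFe3 = p@initialFe3,
                                   duration = p@duration,
                                   outputStep = p@samplingInterval))
  expect_equal(fe2(s), unname(stateTrajectories(sim)[, "fe2"]))
  expect_equal(cellCounts(s), rep(2e9, length(sampleTimes(s))))
  # the noiseless redox channel back-translates to the true ferric fraction
  f <- fe3FractionFromEh(ehValues(s), p@calibration)
  expect_equal(feTotal(s) * (1 - f), fe2(s), tolerance = 1e-6)

  # identical seeds give identical series; different seeds differ
  p2 <- syntheticBatchParams(seed = 9L)
  a <- generateBatchExperiment(p2, 2e9)
  b <- generateBatchExperiment(p2, 2e9)
  expect_identical(ehValues(a), ehValues(b))
  expect_identical(cellCounts(a), cellCounts(b))
  d <- generateBatchExperiment(p2, 2e9, seed = 10L)
  expect_false(identical(ehValues(a), ehValues(d)))
})

test_that("redox-channel noise has the configured spread", {
  p <- syntheticBatchParams(ehNoiseSd = 5, cellNoiseSigma = 0, seed = 21L)
  p0 <- syntheticBatchParams(ehNoiseSd = 0, cellNoiseSigma = 0, seed = 21L)
  truth <- ehValues(generateBatchExperiment(p0, 2e9))
  resid <- unlist(lapply(1:80, function(i)
    ehValues(generateBatchExperiment(p, 2e9, seed = 1000L + i)) - truth))
  expect_equal(sd(resid), 5, tolerance = 0.1 * 5)
})

test_that("noiseless dataset evaluates the law at each level and refits it exactly", {
  p <- syntheticBatchParams(ehNoiseSd = 0, cellNoiseSigma = 0, seed = 2L)
  d <- generateRateLawDataset(p)
  expect_equal(d$rate, c(2.588, 8.47, 18.85), tolerance = 1e-3)
  law <- fitRateLaw(d$biomass, d$rate)
  expect_equal(rateSlope(law), 3.46e-9, tolerance = 1e-3)
  expect_equal(rateIntercept(law), 1.55, tolerance = 1e-3)
})

test_that("parameter recovery from noisy replicated experiments is within 10%", {
  p <- syntheticBatchParams(seed = 17L)  # default 5 mV / 0.15 sigma noise
  d <- generateRateLawDataset(p, replicates = 20L)
  expect_equal(nrow(d), 60L)
  law <- fitRateLaw(d$biomass, d$rate)
  expect_lt(abs(rateSlope(law) - 3.46e-9) / 3.46e-9, 0.10)
  expect_lt(rateR2(law), 1)
})

test_that("cascade tables round-trip through the nutrient flux module", {
  cc <- cascadeConfig()
  tabs <- generateCascadeTables(cc, noiseSigma = 0, seed = 1L)
  rec <- nutrientRecord(tabs$nutrients$species, tabs$nutrients$inlet,
                        tabs$nutrients$outlet)
  flux <- consumptionFlux(rec, volume = tabs$volume, hrt = tabs$hrt)
  # configured uptake: q * X* * V / M
  xStar <- steadyStateOf(simulateGrowthReactor(cc@growth))[["biomass"]]
  q <- cc@growth@uptakeRates
  expected <- q * xStar * cc@growth@volume / molarMassOf(names(q))
  expect_equal(unname(flux), unname(expected), tolerance = 1e-9)

  # seeded reproducibility
  t2 <- generateCascadeTables(cc, noiseSigma = 0.05, seed = 4L)
  t3 <- generateCascadeTables(cc, noiseSigma = 0.05, seed = 4L)
  expect_identical(t2$steadyState, t3$steadyState)
  expect_identical(t2$nutrients, t3$nutrients)
})

test_that("noisy cascade fluxes recover the configured uptake within sampling error", {
  cc <- cascadeConfig()
  xStar <- steadyStateOf(simulateGrowthReactor(cc@growth))[["biomass"]]
  q <- cc@growth@uptakeRates[["NH4+"]]
  expected <- q * xStar * cc@growth@volume / molarMassOf("NH4+")
  sigma <- 0.03
  fluxes <- vapply(1:30, function(i) {
    tabs <- generateCascadeTables(cc, noiseSigma = sigma, seed = 100L + i)
    rec <- nutrientRecord(tabs$nutrients$species, tabs$nutrients$inlet,
                          tabs$nutrients$outlet)
    unname(consumptionFlux(rec, tabs$volume, tabs$hrt))
  }, numeric(1))
  expect_lt(abs(mean(fluxes) - unname(expected)),
            2 * sd(fluxes) / sqrt(length(fluxes)) + 0.05 * expected)
})
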