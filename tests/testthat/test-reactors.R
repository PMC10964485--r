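test_that("hydraulic residence time is volume over throughput", {
  expect_equal(hydraulicResidenceTime(4, 29.5), 135.6, tolerance = 1e-3)
  expect_equal(hydraulicResidenceTime(2, 26.5), 75.47, tolerance = 1e-3)
  expect_equal(hydraulicResidenceTime(3, 3000), 1)
  expect_error(hydraulicResidenceTime(2, 0), "positive")
  # config dispatch reports the implied HRT of the volume/flow pairing
  expect_equal(hydraulicResidenceTime(reductionReactorConfig()),
               4000 / 29.5)
  expect_equal(hydraulicResidenceTime(growthReactorConfig()), 2000 / 26.5)
})

test_that("batch run depletes ferric iron linearly then plateaus, conserving iron", {
  cfg <- batchConfig(biomass = 0, rateLaw = rateLaw(0, 2), initialFe3 = 4500,
                     initialFe2 = 0, duration = 4000, outputStep = 50)
  res <- simulateBatch(cfg)
  st <- stateTrajectories(res)
  t <- sampleTimes(res)
  # linear production at 2 mg/L/h until exhaustion near t = 2250 h
  pre <- t <= 2200
  expect_equal(unname(st[pre, "fe2"]), 2 * t[pre], tolerance = 1e-6)
  expect_equal(unname(st[t >= 3000, "fe2"]), rep(4500, sum(t >= 3000)),
               tolerance = 1e-3)
  # conservation without precipitation
  expect_lt(diagnosticsOf(res)$ironBalanceResidual, 1e-9)
  expect_true(all(st >= 0))
})

test_that("batch estimators recover the configured rate from the simulated trace", {
  law <- rateLaw(3.46e-9, 1.55)
  v <- predictRate(law, 2e9)
  res <- simulateBatch(batchConfig(biomass = 2e9, rateLaw = law,
                                   duration = 288, outputStep = 24))
  st <- stateTrajectories(res)
  s <- bioreductionSeries(sampleTimes(res), st[, "fe2"])
  expect_equal(meanRate(s), v, tolerance = 1e-7)
  expect_equal(maxRate(s), v, tolerance = 1e-7)
})

test_that("precipitation sink moves iron to the precipitated pool, inventory closed", {
  cfg <- batchConfig(biomass = 1e9, kPrecip = 0.005, duration = 200,
                     outputStep = 10)
  res <- simulateBatch(cfg)
  st <- stateTrajectories(res)
  expect_lt(diagnosticsOf(res)$ironBalanceResidual, 1e-9)
  expect_gt(st[nrow(st), "fePrecip"], 0)
  # dissolved total decreases when ferric iron precipitates
  expect_lt(st[nrow(st), "fe3"] + st[nrow(st), "fe2"], 4500)
})

test_that("growth chemostat: pure CSTR limit, chemostat algebra and washout", {
  # no growth, no biomass: nutrients relax to the inlet concentrations
  cfg <- growthReactorConfig(growthRate = 0, initialBiomass = 0,
                             inletConc = c("NH4+" = 127, "K+" = 70),
                             uptakeRates = c("NH4+" = 0, "K+" = 0))
  res <- simulateGrowthReactor(cfg)
  fin <- diagnosticsOf(res)$finalState
  expect_equal(unname(fin[c("NH4+", "K+")]), c(127, 70), tolerance = 1e-6)
  expect_true(diagnosticsOf(res)$washout)
  expect_equal(unname(steadyStateOf(res)[["biomass"]]), 0)

  # nonzero steady state satisfies mu * (1 - X*/K) = 1/HRT when mu*HRT > 1
  cfg <- growthReactorConfig()
  res <- simulateGrowthReactor(cfg)
  ss <- steadyStateOf(res)
  hrt <- hydraulicResidenceTime(cfg)
  expect_gt(cfg@growthRate * hrt, 1)
  expect_equal(cfg@growthRate * (1 - ss[["biomass"]] / cfg@carryingCapacity),
               1 / hrt, tolerance = 1e-12)
  # transient converges to the closed form
  expect_equal(unname(diagnosticsOf(res)$finalState[["biomass"]]),
               ss[["biomass"]], tolerance = 1e-5)

  # washout when the dilution rate exceeds the growth rate
  wo <- growthReactorConfig(growthRate = 0.01, initialBiomass = 1e8)
  expect_lt(wo@growthRate * hydraulicResidenceTime(wo), 1)
  reswo <- simulateGrowthReactor(wo)
  expect_true(diagnosticsOf(reswo)$washout)
  expect_lt(diagnosticsOf(reswo)$finalState[["biomass"]], 1e6)
})

test_that("growth-stage ammonium balance reproduces the stage-1 outlet level", {
  # uptake coefficient set so the steady-state uptake flux is 0.104 mmol/h
  # at 2e9 cells/mL in 2 L; inlet 127 mg/L at 73 h residence time
  hrt <- 73
  xStar <- 2e9
  q <- 0.104 * molarMassOf("NH4+") / 2 / xStar
  cfg <- growthReactorConfig(volume = 2, inflow = 2000 / hrt,
                             inletConc = c("NH4+" = 127),
                             carryingCapacity = xStar / (1 - 1 / (0.2 * hrt)),
                             growthRate = 0.2,
                             uptakeRates = c("NH4+" = unname(q)))
  res <- simulateGrowthReactor(cfg)
  ss <- steadyStateOf(res)
  expect_equal(ss[["biomass"]], xStar, tolerance = 1e-9)
  expect_equal(ss[["NH4+"]], 59, tolerance = 0.01)
  # and the implied molar uptake flux round-trips
  flux <- unname(q) * xStar * 2 / molarMassOf("NH4+")
  expect_equal(unname(flux), 0.104)
})

test_that("reduction chemostat: mixing limit, conservative biomass tracer, conservation", {
  cfg <- reductionReactorConfig(rateLaw = rateLaw(0, 0), kPrecip = 0)
  inlet <- list(fe3 = 0, fe2 = 50, biomass = 2e9)
  res <- simulateReductionReactor(cfg, inlet)
  ss <- steadyStateOf(res)
  # flux-weighted mean of the inlet concentrations
  q1 <- 26.5; q2 <- 3
  mixed <- (q1 * 50 + q2 * 22000) / (q1 + q2)
  expect_equal(ss[["feTotal"]], mixed, tolerance = 1e-12)
  expect_equal(ss[["biomass"]], q1 * 2e9 / (q1 + q2), tolerance = 1e-12)
  expect_lt(diagnosticsOf(res)$ironBalanceResidual, 1e-9)
})

test_that("closed-form steady state equals the long-horizon transient", {
  for (kp in c(0, 0.01)) {
    cfg <- reductionReactorConfig(kPrecip = kp)
    inlet <- list(fe3 = 10, fe2 = 120, biomass = 2e9)
    res <- simulateReductionReactor(cfg, inlet, duration = 5000)
    ss <- steadyStateOf(res)
    fin <- diagnosticsOf(res)$finalState
    for (nm in c("fe3", "fe2", "biomass")) {
      expect_equal(unname(fin[[nm]]), ss[[nm]], tolerance = 1e-6)
    }
    expect_lt(diagnosticsOf(res)$ironBalanceResidual, 1e-9)
  }
})

test_that("steady-state flux balance closes through the volumetric rate formula", {
  cfg <- reductionReactorConfig()
  inlet <- list(fe3 = 0, fe2 = 80, biomass = 2e9)
  ss <- steadyState(cfg, inlet)
  vrr <- volumetricReductionRate(ss[["fe2"]], 80, 29.5, 26.5, 4)
  expect_equal(vrr, ss[["rate"]], tolerance = 1e-6)
  # degenerate and scaling cases
  expect_equal(volumetricReductionRate(100, 100, 20, 20, 4), 0)
  expect_equal(volumetricReductionRate(1200, 10, 29.5, 26.5, 8),
               volumetricReductionRate(1200, 10, 29.5, 26.5, 4) / 2)
  expect_error(volumetricReductionRate(1, 1, 1, 1, 0), "positive")
})

test_that("steady-state ferric fraction falls as biomass or rate-law slope rises", {
  base <- steadyState(reductionReactorConfig(), list(biomass = 2e9))
  moreCells <- steadyState(reductionReactorConfig(), list(biomass = 4e9))
  steeper <- steadyState(reductionReactorConfig(
    rateLaw = rateLaw(6e-9, 1.55)), list(biomass = 2e9))
  expect_lt(moreCells[["fe3Fraction"]], base[["fe3Fraction"]])
  expect_lt(steeper[["fe3Fraction"]], base[["fe3Fraction"]])
})

test_that("full cascade runs growth into reduction", {
  res <- simulateCascade(cascadeConfig())
  gss <- steadyStateOf(res$growth)
  rss <- steadyStateOf(res$reduction)
  expect_gt(gss[["biomass"]], 1e9)
  # the reduction stage dilutes the pulp biomass by the feed stream
  expect_equal(rss[["biomass"]], gss[["biomass"]] * 26.5 / 29.5,
               tolerance = 1e-9)
  expect_true(rss[["fe3Fraction"]] > 0 && rss[["fe3Fraction"]] < 1)
})
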