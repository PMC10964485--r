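test_that("maximal rate is the best consecutive increment, ties and signs included", {
  expect_equal(maxRate(bioreductionSeries(c(0, 24), c(0, 48))), 2)
  expect_equal(maxRate(bioreductionSeries(c(0, 24, 48), c(0, 24, 96))), 3)
  expect_equal(maxRate(bioreductionSeries(c(0, 10, 20), c(5, 5, 5))), 0)
  # only decreasing: the maximal rate is negative, not clipped
  expect_lt(maxRate(bioreductionSeries(c(0, 10, 20), c(90, 60, 10))), 0)
  expect_error(bioreductionSeries(0, 0), "two time points")
})

test_that("mean rate is the endpoint slope over the requested period", {
  s <- bioreductionSeries(c(0, 24, 48), c(0, 24, 96))
  expect_equal(meanRate(s), 2)
  expect_equal(meanRate(s, 1, 2), 1)
  expect_equal(meanRate(s, 2, 3), 3)
  expect_error(meanRate(s, 2, 2), "startIndex")
  expect_error(meanRate(s, 1, 9), "startIndex")
})

test_that("maximal rate dominates the mean rate on random series, and both equal k on exact lines", {
  set.seed(42)
  for (i in 1:60) {
    s <- randomSeries()
    expect_gte(maxRate(s), meanRate(s))
    expect_equal(maxRate(s), maxRateOracle(sampleTimes(s), fe2(s)))
  }
  # exactly linear trajectory: both estimators return the slope
  k <- 3.7
  t <- c(0, 7, 20, 55, 100)
  s <- bioreductionSeries(t, 10 + k * t)
  expect_equal(maxRate(s), k)
  expect_equal(meanRate(s), k)
  est <- bioreductionRates(s)
  expect_equal(meanRate(est), k)
  expect_equal(maxRate(est), k)
})

test_that("series built from the redox channel reproduces speciation kinetics", {
  cal <- stage1Calibration()
  # constant potential at the formal potential: Fe(II) is half the total
  s <- seriesFromEh(c(0, 24, 48), rep(formalPotential(cal), 3), 2400, cal)
  expect_equal(fe2(s), rep(1200, 3))
  # decreasing potential at constant total iron: increasing Fe(II)
  s <- seriesFromEh(0:10, seq(700, 600, by = -10), 2400, cal)
  expect_true(all(diff(fe2(s)) > 0))
  # pilot endpoint arithmetic: 680 -> 650 mV over 111 h at 2.4 g/L
  s <- seriesFromEh(c(0, 111), c(680, 650), 2400, cal)
  expected <- (fe3FractionFromEh(680, cal) - fe3FractionFromEh(650, cal)) *
    2400 / 111
  expect_equal(meanRate(s), expected)
  expect_equal(meanRate(s), 5.6, tolerance = 0.02)
  expect_error(seriesFromEh(c(0, 1), c(650, 650, 650), 2400, cal), "length")
})

test_that("rate-law fitting matches the closed-form examples and the lm oracle", {
  law <- fitRateLaw(c(1e9, 2e9), c(5, 8))
  expect_equal(rateSlope(law), 3e-9)
  expect_equal(rateIntercept(law), 2)
  expect_equal(rateR2(law), 1)

  # exactly collinear data: coefficients recovered to 1e-12 relative
  x <- c(3e8, 2e9, 2e9, 2e9, 5e9)
  y <- 3.46e-9 * x + 1.55
  law <- fitRateLaw(x, y)
  expect_equal(rateSlope(law), 3.46e-9, tolerance = 1e-12)
  expect_equal(rateIntercept(law), 1.55, tolerance = 1e-12)

  # the five batch/continuous biomass-rate pairs of the study summary
  xTab <- c(3e8, 2e9, 2e9, 2e9, 5e9)
  yTab <- c(1.7, 9.8, 7.8, 8.8, 19.5)
  law <- fitRateLaw(xTab, yTab)
  o <- olsOracle(xTab, yTab)
  expect_equal(rateSlope(law), o$slope, tolerance = 1e-10)
  expect_equal(rateIntercept(law), o$intercept, tolerance = 1e-10)
  expect_equal(rateR2(law), o$r2, tolerance = 1e-10)
  expect_true(rateR2(law) >= 0 && rateR2(law) <= 1)

  expect_error(fitRateLaw(c(1e9, 1e9), c(1, 2)), "degenerate")
  expect_error(fitRateLaw(1e9, 5), "two")
})

test_that("random OLS instances agree with the lm oracle to 1e-10 relative", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    x <- runif(n, 1e8, 6e9)
    y <- runif(1, 0, 5e-9) * x + runif(1, -2, 3) + rnorm(n, 0, 2)
    law <- fitRateLaw(x, y)
    o <- olsOracle(x, y)
    expect_equal(rateSlope(law), o$slope, tolerance = 1e-10)
    expect_equal(rateIntercept(law), o$intercept, tolerance = 1e-10)
    expect_equal(rateR2(law), o$r2, tolerance = 1e-10)
  }
})

test_that("shuffling responses does not beat the true fit's R2 on average", {
  set.seed(5)
  x <- seq(1e8, 5e9, length.out = 12)
  y <- 3e-9 * x + 1 + rnorm(12, 0, 2)
  r2True <- rateR2(fitRateLaw(x, y))
  r2Shuffled <- replicate(60, rateR2(fitRateLaw(x, sample(y))))
  expect_lt(mean(r2Shuffled), r2True)
})

test_that("rate-law evaluation is affine with a nonnegativity guard on biomass", {
  law <- rateLaw(3.46e-9, 1.55)
  expect_equal(predictRate(law, 0), 1.55)
  expect_equal(predictRate(law, 1e9), 5.01)
  expect_equal(predictRate(rateLaw(0, 7), c(0, 1e9, 5e9)), rep(7, 3))
  expect_error(predictRate(law, -1), "nonnegative")
})
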