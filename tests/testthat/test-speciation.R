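test_that("Nernst ratio map has the exact decade structure and inverse", {
  cal <- redoxCalibration(676.6, 308.15)
  s <- nernstSlope(cal)
  expect_gt(s, 0)
  expect_equal(s, 61.14, tolerance = 0.01)

  # midpoint and one-decade anchors
  expect_equal(ratioFromEh(676.6, cal), 1)
  expect_equal(ratioFromEh(676.6 + s, cal), 10)
  expect_equal(ehFromRatio(1, cal), 676.6)
  expect_equal(ehFromRatio(10, cal), 676.6 + s)

  # round trip is the identity to 1e-10 mV, and the ratio multiplies by ten
  # per slope increment
  set.seed(11)
  for (eh in c(703.7, runif(20, 400, 900))) {
    expect_equal(ehFromRatio(ratioFromEh(eh, cal), cal), eh, tolerance = 1e-10)
    expect_equal(ratioFromEh(eh + s, cal) / ratioFromEh(eh, cal), 10,
                 tolerance = 1e-9)
  }
  expect_error(ehFromRatio(0, cal), "positive")
  expect_error(ehFromRatio(-2, cal), "positive")
})

test_that("ferric fraction is monotone with correct limits and midpoint", {
  cal <- redoxCalibration()
  expect_equal(fe3FractionFromEh(formalPotential(cal), cal), 0.5)
  expect_equal(fe3FractionFromEh(-1e6, cal), 0)
  expect_equal(fe3FractionFromEh(1e6, cal), 1)
  eh <- seq(300, 1000, by = 5)
  expect_true(all(diff(fe3FractionFromEh(eh, cal)) > 0))
})

test_that("one-point calibration recovers its anchor and the pilot's two steady states agree", {
  cal <- stage1Calibration()
  expect_equal(formalPotential(cal), 676.81, tolerance = 1e-2)
  expect_equal(fe3FractionFromEh(680, cal), 0.53, tolerance = 1e-12)

  # stage-2 prediction from the stage-1 anchor
  expect_equal(fe3FractionFromEh(650, cal), 0.267, tolerance = 1e-3)

  # the two printed (Eh, fraction) pairs imply formal potentials within 1 mV
  cal2 <- calibrateFormalPotential(650, 0.27)
  expect_lt(abs(formalPotential(cal) - formalPotential(cal2)), 1)

  # half-reduced anchor returns the potential itself
  expect_equal(formalPotential(calibrateFormalPotential(712, 0.5)), 712)
  expect_error(calibrateFormalPotential(680, 0), "between 0 and 1")
  expect_error(calibrateFormalPotential(680, 1), "between 0 and 1")
})

test_that("speciation conserves total iron and matches the calibrated fraction", {
  cal <- stage1Calibration()
  sp <- speciate(2400, 650, cal)
  expect_equal(fe3(sp), 2400 * fe3FractionFromEh(650, cal))
  expect_equal(fe3(sp), 641, tolerance = 0.5)
  expect_equal(fe2(sp), 1759, tolerance = 0.5)

  z <- speciate(0, 650, cal)
  expect_equal(fe3(z), 0)
  expect_equal(fe2(z), 0)

  set.seed(4)
  tot <- runif(50, 0, 5000)
  eh <- runif(50, 300, 1000)
  sp <- speciate(tot, eh, cal)
  expect_equal(fe2(sp) + fe3(sp), tot)
  expect_true(all(fe3Fraction(sp) >= 0 & fe3Fraction(sp) <= 1))
  expect_error(speciate(-1, 650, cal), "nonnegative")
})
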