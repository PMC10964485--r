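test_that("all reactions of the bioleaching network balance exactly", {
  for (name in c("goethite_dissolution", "sulfur_iron_reduction",
                 "mno2_reduction", "cell_synthesis",
                 "sulfur_aerobic_oxidation")) {
    bal <- checkBalance(reactionByName(name))
    expect_true(bal$balanced, info = name)
    expect_identical(unname(bal$residuals), rep(0, length(bal$residuals)))
  }
})

test_that("a deliberately broken reaction fails the balance check", {
  broken <- reaction("broken_sulfur_iron",
    reactants = list("Fe3+" = 5, "S0" = 1, "H2O" = 4),
    products = list("Fe2+" = 6, "SO42-" = 1, "H+" = 8))
  bal <- checkBalance(broken)
  expect_false(bal$balanced)
  expect_true(bal$residuals[["Fe"]] != 0)
  expect_true(bal$residuals[["charge"]] != 0)
  expect_error(checkBalance(reaction("nope", list("Xx2+" = 1),
                                     list("Xx2+" = 1))),
               "unknown species")
})

test_that("electron couplings emerge from oxidation-state bookkeeping", {
  # independent bookkeeping from scratch: O is -2, H is +1, solve the rest
  oxOracle <- function(counts, charge, element) {
    fixed <- c(O = -2, H = 1)
    other <- sum(fixed[intersect(names(counts), names(fixed))] *
                   counts[intersect(names(counts), names(fixed))])
    (charge - other) / counts[[element]]
  }
  expect_equal(oxidationState("SO42-", "S"),
               oxOracle(c(S = 1, O = 4), -2, "S"))  # +6
  expect_equal(oxidationState("MnO2", "Mn"), 4)
  expect_equal(oxidationState("S0", "S"), 0)
  expect_equal(oxidationState("Fe3+", "Fe"), 3)

  # six electrons per sulfur, each reducing one ferric ion
  expect_equal(fe3PerS0(), 6)
  expect_equal(fe3PerS0(),
               (oxOracle(c(S = 1, O = 4), -2, "S") - 0) / (3 - 2))
  expect_equal(fe2PerMnO2(), 2)

  # coefficient consistency with the stored reactions
  rxn <- reactionByName("sulfur_iron_reduction")
  coefOf <- function(rxn, sp) {
    i <- which(rxn@species == sp)
    rxn@num[i] / rxn@den[i]
  }
  expect_equal(coefOf(rxn, "Fe3+"), fe3PerS0())
  expect_equal(coefOf(rxn, "H+"), 8)   # acid release per sulfur oxidised
  mn <- reactionByName("mno2_reduction")
  expect_equal(coefOf(mn, "Fe2+"), fe2PerMnO2())
  expect_equal(coefOf(mn, "H+"), 4)    # acid demand per Mn oxide
})

test_that("cell synthesis fixes the 5:1 C:N ratio and the ammonium demand", {
  expect_equal(biomassCNRatio(), 5)
  # (1/5 + 1/20) : (1/20) computed from the stored exact coefficients
  expect_identical(biomassCNRatio(), (1 / 5 + 1 / 20) / (1 / 20))

  # worked example: 40 mg/L/h CO2 uptake in a 2 L reactor
  expect_equal(ammoniumDemandFromCO2(40, 2), 0.4544, tolerance = 1e-4)
  expect_equal(ammoniumDemandFromCO2(0, 5), 0)
  # one mmol/h of CO2 requires a quarter mmol/h of ammonium
  expect_equal(ammoniumDemandFromCO2(44.01, 1), 0.25)
  expect_error(ammoniumDemandFromCO2(-1, 2), "nonnegative")
})
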