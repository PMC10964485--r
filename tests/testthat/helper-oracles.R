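# Independent oracles and fixture builders shared by the test files.

# OLS oracle: R's own linear-model fitter, independent of the closed-form
# normal equations in fitRateLaw()
olsOracle <- function(x, y) {
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}

# brute-force maximal consecutive-increment rate
maxRateOracle <- function(times, fe2) {
  best <- -Inf
  for (i in seq_len(length(times) - 1L)) {
    best <- max(best, (fe2[i + 1L] - fe2[i]) / (times[i + 1L] - times[i]))
  }
  best
}

# random admissible monitoring series under a fixed RNG state
randomSeries <- function(n = sample(3:12, 1)) {
  times <- cumsum(runif(n, 0.5, 30))
  fe2 <- cumsum(rnorm(n, 5, 20))
  fe2 <- fe2 - min(fe2)  # keep nonnegative
  bioreductionSeries(times, fe2)
}

# stage-1 continuous-pilot calibration anchor used across tests
stage1Calibration <- function() calibrateFormalPotential(680, 0.53)
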