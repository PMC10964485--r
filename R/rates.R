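## Batch rate estimators and the linear biomass-rate law.

#' Maximal bioreduction rate
#'
#' The maximal increase of Fe(II) concentration between two consecutive
#' measurements, i.e. \eqn{\max_i (c_{i+1} - c_i)/(t_{i+1} - t_i)} over
#' consecutive sample pairs. Ties are broken by first occurrence; the value
#' can be negative if Fe(II) only decreases. Non-adjacent pairs are not
#' considered: with daily monitoring the consecutive-increment reading is
#' what "between two measures" means, and it dominates any coarser pair.
#'
#' @param series A [bioreductionSeries()] with at least two points.
#' @param ... Ignored.
#' @return Rate in mg L-1 h-1.
#' @examples
#' maxRate(bioreductionSeries(c(0, 24, 48), c(0, 24, 96)))  # 3
#' @seealso [meanRate()], [bioreductionRates()]
#' @export
setMethod("maxRate", "BioreductionSeries", function(series, ...) {
  max(diff(series@fe2) / diff(series@times))
})

#' Mean bioreduction rate
#'
#' Fe(II) production rate between the beginning and the end of the
#' bioreduction period: \eqn{(c_{end} - c_{start})/(t_{end} - t_{start})}.
#' Defaults to the full series; pass indices to restrict to the active
#' bioreduction window (e.g. up to the day the Fe(II) trace stabilises).
#'
#' @param series A [bioreductionSeries()].
#' @param startIndex,endIndex Sample indices delimiting the period;
#'   `endIndex` must exceed `startIndex`.
#' @param ... Ignored.
#' @return Rate in mg L-1 h-1. Never exceeds [maxRate()] of the same series.
#' @examples
#' meanRate(bioreductionSeries(c(0, 24, 48), c(0, 24, 96)))  # 2
#' @export
setMethod("meanRate", "BioreductionSeries",
          function(series, startIndex = 1L, endIndex = length(series@times), ...) {
  n <- length(series@times)
  if (startIndex < 1L || endIndex > n || endIndex <= startIndex) {
    stop("need 1 <= startIndex < endIndex <= ", n)
  }
  (series@fe2[endIndex] - series@fe2[startIndex]) /
    (series@times[endIndex] - series@times[startIndex])
})

#' Both batch rate estimates at once
#'
#' @param series A [bioreductionSeries()].
#' @param startIndex,endIndex Period passed to [meanRate()].
#' @return A [rateEstimate] holding the mean and maximal rates.
#' @examples
#' bioreductionRates(bioreductionSeries(c(0, 24, 48), c(0, 24, 96)))
#' @export
bioreductionRates <- function(series, startIndex = 1L,
                              endIndex = length(sampleTimes(series))) {
  new("RateEstimate",
      meanRate = meanRate(series, startIndex, endIndex),
      maxRate = maxRate(series))
}

#' Build a Fe(II) series from redox potential monitoring
#'
#' Bioreduction monitoring estimates Fe(II) from the redox potential (the
#' ferric iron tends to precipitate, the ferrous does not):
#' `fe2[i] = feTotal[i] * (1 - fe3FractionFromEh(eh[i]))`. The potential and
#' total-iron channels are retained on the returned series.
#'
#' @param times Sampling times, h.
#' @param eh Redox potentials, mV vs SHE, same length as `times`.
#' @param feTotal Total iron concentrations, mg L-1, same length or scalar.
#' @param calib A [redoxCalibration()].
#' @return A [bioreductionSeries()].
#' @examples
#' cal <- calibrateFormalPotential(680, 0.53)
#' s <- seriesFromEh(c(0, 111), c(680, 650), 2400, cal)
#' meanRate(s)  # ~5.6 mg/L/h
#' @export
seriesFromEh <- function(times, eh, feTotal, calib = redoxCalibration()) {
  if (length(feTotal) == 1L) feTotal <- rep(feTotal, length(times))
  if (length(eh) != length(times) || length(feTotal) != length(times)) {
    stop("times, eh and feTotal must have matching lengths")
  }
  f <- fe3FractionFromEh(eh, calib)
  bioreductionSeries(times, fe2 = feTotal * (1 - f), eh = eh,
                     feTotal = feTotal)
}

#' Fit the linear biomass-rate law
#'
#' Ordinary least squares fit of the affine relation between planktonic
#' biomass concentration and volumetric Fe(III) bioreduction rate,
#' \eqn{v = a X + b}, by the closed-form normal equations. The coefficient
#' of determination is \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, set to 1 when the
#' responses are constant (\eqn{SS_{tot} = 0}).
#'
#' @param biomass Biomass concentrations, cells mL-1 (>= 2 values, not all
#'   equal).
#' @param rate Matching bioreduction rates, mg L-1 h-1.
#' @return A [rateLaw()] with the fitted slope, intercept and \eqn{R^2}.
#' @examples
#' fitRateLaw(c(1e9, 2e9), c(5, 8))  # slope 3e-9, intercept 2, R2 1
#' @seealso [predictRate()]
#' @export
fitRateLaw <- function(biomass, rate) {
  x <- as.numeric(biomass)
  y <- as.numeric(rate)
  if (length(x) != length(y)) stop("biomass and rate must have equal length")
  if (length(x) < 2L) stop("at least two (biomass, rate) pairs are required")
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("degenerate design: all biomass values are identical")
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  ssTot <- sum((y - ybar)^2)
  ssRes <- sum((y - intercept - slope * x)^2)
  r2 <- if (ssTot == 0) 1 else 1 - ssRes / ssTot
  rateLaw(slope, intercept, min(max(r2, 0), 1))
}

#' Evaluate a biomass-rate law
#'
#' @param law A [rateLaw()].
#' @param biomass Biomass concentration(s), cells mL-1, nonnegative.
#' @return Predicted volumetric reduction rate(s), mg L-1 h-1.
#' @examples
#' predictRate(rateLaw(3.46e-9, 1.55), 0)  # the intercept
#' @export
predictRate <- function(law, biomass) {
  stopifnot(is(law, "RateLaw"))
  if (any(biomass < 0)) stop("biomass must be nonnegative")
  rateSlope(law) * biomass + rateIntercept(law)
}
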