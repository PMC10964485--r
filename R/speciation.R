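## Nernst-based conversion between redox potential and iron speciation.
##
## The ratio r = [Fe3+]/[Fe2+] follows r = 10^((Eh - E0')/s) with
## s = ln(10) R T / F in mV; E0' is an effective formal potential absorbing
## activity and complexation effects in the sulfate leaching medium.

#' Fe(III)/Fe(II) ratio from redox potential
#'
#' Converts a measured redox potential (mV vs SHE) into the concentration
#' ratio \eqn{r = [\mathrm{Fe^{3+}}]/[\mathrm{Fe^{2+}}]} via the Nernst
#' relation \eqn{r = 10^{(E_h - E^{0'})/s}} with slope
#' \eqn{s = \ln(10) R T / F} (mV per decade). Defined and strictly
#' increasing for all real potentials.
#'
#' @param eh Redox potential(s), mV vs SHE.
#' @param calib A [redoxCalibration()].
#' @return Positive ratio(s) \eqn{r}; `r = 1` at the formal potential.
#' @examples
#' cal <- redoxCalibration(676.6)
#' ratioFromEh(676.6, cal)  # 1
#' ratioFromEh(676.6 + nernstSlope(cal), cal)  # 10
#' @seealso [ehFromRatio()], [fe3FractionFromEh()], [speciate()]
#' @export
ratioFromEh <- function(eh, calib = redoxCalibration()) {
  stopifnot(is(calib, "RedoxCalibration"))
  10^((eh - formalPotential(calib)) / nernstSlope(calib))
}

#' Redox potential from Fe(III)/Fe(II) ratio
#'
#' Exact inverse of [ratioFromEh()].
#'
#' @param r Positive concentration ratio(s) \eqn{[Fe^{3+}]/[Fe^{2+}]}.
#' @inheritParams ratioFromEh
#' @return Redox potential(s), mV vs SHE.
#' @examples
#' cal <- redoxCalibration()
#' ehFromRatio(1, cal)  # the formal potential
#' @export
ehFromRatio <- function(r, calib = redoxCalibration()) {
  stopifnot(is(calib, "RedoxCalibration"))
  if (any(r <= 0)) {
    stop("ratio must be strictly positive: the potential is undefined at r <= 0")
  }
  formalPotential(calib) + nernstSlope(calib) * log10(r)
}

#' Ferric fraction from redox potential
#'
#' Fraction of dissolved iron present as Fe(III),
#' \eqn{f = r/(1+r)} with \eqn{r} from [ratioFromEh()]. Strictly monotone in
#' the potential, with limits 0 and 1 at minus/plus infinity.
#'
#' @inheritParams ratioFromEh
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' cal <- calibrateFormalPotential(680, 0.53)
#' fe3FractionFromEh(650, cal)  # ~0.27, the stage-2 steady state
#' @export
fe3FractionFromEh <- function(eh, calib = redoxCalibration()) {
  r <- ratioFromEh(eh, calib)
  ## r/(1+r), written to stay accurate when r is huge
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Calibrate the formal potential from one anchor point
#'
#' Fixes the effective formal potential of the Fe3+/Fe2+ couple so that a
#' given potential maps to a given ferric fraction:
#' \eqn{E^{0'} = E_h - s \log_{10}(f/(1-f))}. Calibrating on the stage-1
#' steady state of the continuous pilot (680 mV, 53\% Fe(III)) yields
#' about 676.8 mV at 308.15 K.
#'
#' @param eh Anchor potential, mV vs SHE.
#' @param fe3Fraction Ferric fraction at the anchor, strictly inside (0, 1).
#' @param temperature Temperature, K (default 308.15, i.e. 35 degrees C).
#' @return A [redoxCalibration()] whose [fe3FractionFromEh()] recovers the
#'   anchor exactly.
#' @examples
#' calibrateFormalPotential(680, 0.53)
#' @export
calibrateFormalPotential <- function(eh, fe3Fraction, temperature = 308.15) {
  if (length(fe3Fraction) != 1L || !is.finite(fe3Fraction) ||
      fe3Fraction <= 0 || fe3Fraction >= 1) {
    stop("fe3Fraction must lie strictly between 0 and 1 (the potential is infinite at the endpoints)")
  }
  calib <- redoxCalibration(0, temperature)
  redoxCalibration(eh - nernstSlope(calib) * log10(fe3Fraction / (1 - fe3Fraction)),
                   temperature)
}

#' Speciate total iron by redox potential
#'
#' Partitions a total iron concentration into ferric and ferrous components
#' using the ferric fraction implied by the measured potential. Total iron
#' is conserved exactly.
#'
#' @param feTotal Total dissolved iron, mg L-1 (vectorised; nonnegative).
#' @param eh Redox potential(s), mV vs SHE, recycled against `feTotal`.
#' @inheritParams ratioFromEh
#' @return An [ironSpeciation] object.
#' @examples
#' speciate(2400, 650, calibrateFormalPotential(680, 0.53))
#' @export
speciate <- function(feTotal, eh, calib = redoxCalibration()) {
  if (any(feTotal < 0)) stop("feTotal must be nonnegative")
  n <- max(length(feTotal), length(eh))
  feTotal <- rep_len(feTotal, n)
  eh <- rep_len(eh, n)
  f <- fe3FractionFromEh(eh, calib)
  fe3 <- feTotal * f
  new("IronSpeciation", feTotal = feTotal, fe2 = feTotal - fe3, fe3 = fe3)
}
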