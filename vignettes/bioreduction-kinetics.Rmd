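---
title: "Methods: Fe(III) bioreduction kinetics in stirred tank reactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fe(III) bioreduction kinetics in stirred tank reactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrokin)
```

This vignette documents the models implemented in **ferrokin**, the
assumptions behind them, the default parameter values with units and the
rationale for each, the synthetic-data design, and the known limitations.
The system modelled is anaerobic dissimilatory Fe(III) reduction by an
acidophilic consortium (dominated by *Sulfobacillus* spp.) with elemental
sulfur as electron donor, at 35 °C and low pH, operated either as batch
stirred tanks or as a two-stage continuous cascade (an aerobic growth
reactor feeding an anaerobic bioreduction reactor).

# 1. Redox speciation

## Model

With total soluble iron partitioned between Fe(III) and Fe(II), the
solution redox potential (mV vs SHE) is taken to obey a one-electron
Nernst relation with a single effective formal potential:

$$ \mathrm{Eh} = E^{0\prime} + s \,\log_{10}\frac{[\mathrm{Fe(III)}]}{[\mathrm{Fe(II)}]},
\qquad s = \frac{\ln 10 \cdot R\,T}{F}\ \text{(in mV)}. $$

At the default temperature of 308.15 K (35 °C), $s = 61.14$ mV per
decade. Inversion gives the concentration ratio
$r = 10^{(\mathrm{Eh}-E^{0\prime})/s}$ and the ferric fraction
$f = r/(1+r)$; `speciate()` then splits a measured total iron
concentration exactly (fe3 + fe2 = feTotal to machine precision).

## Assumptions

* The Fe(III)/Fe(II) couple controls the measured potential; other couples
  (e.g. S species) are kinetically silent at the electrode.
* Activity coefficients, ionic strength and complexation (sulfate media)
  are folded into the *effective* formal potential $E^{0\prime}$, which is
  therefore a conditional, medium-specific constant — not the standard
  potential of the aquo couple.
* The total concentration ratio equals the activity ratio (same folding).

## Calibration and defaults

`calibrateFormalPotential(eh, fe3Fraction, temperature)` solves the Nernst
relation for $E^{0\prime}$ from a single anchor point where both the
potential and the ferric fraction (from independent chemical assay) are
known. Fractions of exactly 0 or 1 are rejected (the logarithm diverges).

The default `redoxCalibration()` uses $E^{0\prime} = 676.6$ mV vs SHE at
308.15 K. This is the mean of two independent one-point calibrations from
steady-state operation of the continuous pilot: (680 mV, 53 % ferric)
gives 676.81 mV and (650 mV, 27 % ferric) gives 676.41 mV. Their
closeness (0.4 mV apart) is itself evidence that a single effective
$E^{0\prime}$ describes the medium.

```{r}
cal <- calibrateFormalPotential(680, 0.53)
formalPotential(cal)
fe3FractionFromEh(650, cal)
```

# 2. Rate estimators and the biomass–rate law

Given a monitoring series of net Fe(II) concentration over time:

* `maxRate()` is the largest finite-difference slope between two
  *consecutive* samples, $\max_i (c_{i+1}-c_i)/(t_{i+1}-t_i)$. It is the
  standard "maximal rate" read off a progress curve and is by construction
  never below the mean rate.
* `meanRate()` is the endpoint slope $(c_n - c_1)/(t_n - t_1)$ over the
  bioreduction period. When Fe(III) exhausts before the experiment ends,
  the period should be truncated to the active phase first (the synthetic
  generator does this; see §6), otherwise the idle tail dilutes the mean.

Both are *net* rates: they measure Fe(II) accumulation in solution, i.e.
gross bioreduction minus any re-oxidation or Fe(II) loss. Units are
mg L⁻¹ h⁻¹ throughout.

`fitRateLaw(biomass, rate)` fits the linear law
$v = a\,X_\mathrm{liq} + b$ (rate vs planktonic cell density in
cells mL⁻¹) by ordinary least squares using the closed-form normal
equations ($a = S_{xy}/S_{xx}$), with $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$
(defined as 1 when the response is constant). The default law used by the
reactor configurations is $a = 3.46\times10^{-9}$ mg L⁻¹ h⁻¹ per
cell mL⁻¹ and $b = 1.55$ mg L⁻¹ h⁻¹, the fit obtained from batch
experiments spanning roughly $3\times10^8$–$5\times10^9$ cells mL⁻¹. The
positive intercept reflects contributions not proportional to planktonic
density (e.g. mineral-attached cells and abiotic reduction); the law
should not be extrapolated to $X \to 0$ as a purely abiotic rate.

# 3. Stoichiometry

The reaction network (`reactionByName()`) is stored with exact rational
coefficients (integer numerator/denominator pairs), so `checkBalance()`
verifies element and charge conservation *exactly*, not to a floating
tolerance:

* goethite acid dissolution: FeOOH + 3 H⁺ ⇌ Fe³⁺ + 2 H₂O
* anaerobic sulfur-coupled iron reduction:
  6 Fe³⁺ + S⁰ + 4 H₂O → 6 Fe²⁺ + SO₄²⁻ + 8 H⁺
* Mn(IV) reduction by ferrous iron:
  MnO₂ + 2 Fe²⁺ + 4 H⁺ → Mn²⁺ + 2 Fe³⁺ + 2 H₂O
* cell synthesis (biomass formula C₅H₇O₂N):
  1/5 CO₂ + 1/20 HCO₃⁻ + 1/20 NH₄⁺ + H⁺ + e⁻ →
  1/20 C₅H₇O₂N + 9/20 H₂O

`fe3PerS0()` and `fe2PerMnO2()` re-derive the 6:1 and 2:1 electron ratios
from oxidation-state bookkeeping (O fixed at −2, H at +1, the remaining
element solved from species charge) rather than reading them off the
stored reactions — the two routes agreeing is a self-check.

`ammoniumDemandFromCO2(co2Rate, volume)` converts a volumetric CO₂ uptake
rate (mg L⁻¹ h⁻¹) into the NH₄⁺ demand (mmol h⁻¹) implied by the
synthesis stoichiometry: one N per five C (the C:N ratio of C₅H₇O₂N), of
which CO₂ supplies four-fifths of the carbon, giving
NH₄⁺/CO₂ = 1/4 mol/mol.

# 4. Reactor models

All reactors are modelled as ideally mixed tanks. Concentrations are
mg L⁻¹ (iron) or cells mL⁻¹ (biomass); flows mL h⁻¹; volumes L; time h.
ODEs are integrated with `deSolve::ode` (lsoda, `rtol = 1e-8`,
`atol = 1e-10`); integration failures raise an error rather than
returning partial trajectories.

## Rate clipping near substrate exhaustion

The linear law predicts a positive rate even when Fe(III) is exhausted.
The simulators therefore use
$v = \min\!\big(\max(0, a X + b),\ \mathrm{Fe(III)}/\tau\big)$ with
$\tau = 1$ h. The clip makes the rate vanish continuously with the
substrate (first-order below $v_\mathrm{law}\tau$), which keeps the ODE
Lipschitz and the steady state well defined. $\tau$ is a numerical
regularisation, not a measured affinity constant; any value well below
the hydraulic residence time and the batch duration gives
indistinguishable trajectories away from exhaustion.

## Batch reactor

States: fe3, fe2, fePrecip, biomass (constant). dFe2/dt = v,
dFe3/dt = −v − k_p·fe3, with optional first-order precipitation
k_p (h⁻¹, default 0) feeding the fePrecip pool. Tracking the precipitated
pool as a state makes total iron a linear invariant, which lsoda
preserves to round-off; `diagnosticsOf()` reports the iron-balance
residual (typically ~1e−15 relative).

Defaults (`batchConfig()`): 2 L working volume, 4500 mg L⁻¹ initial
Fe(III) (as ferric sulfate), 288 h duration sampled every 24 h — the
batch protocol of daily monitoring over 12 days.

## Growth reactor (stage 1)

An aerated chemostat growing the consortium on sulfur:
dX/dt = µX(1 − X/K) − X/HRT, plus nutrient balances
dC/dt = (C_in − C)/HRT − min(qX, C/τ). Logistic growth was chosen over
Monod on the growth substrate because the limiting resource (solid
sulfur surface) is not a dissolved state variable; K is the observed
plateau density. Closed form: X* = K(1 − 1/(µ·HRT)); µ·HRT ≤ 1 is
washout, reported as a diagnostic flag rather than an error. Defaults:
2 L, 26.5 mL h⁻¹ (HRT ≈ 75 h), K = 2.2×10⁹ cells mL⁻¹, µ = 0.2 h⁻¹.

## Bioreduction reactor (stage 2) and cascade

An anaerobic chemostat receiving the stage-1 pulp plus a concentrated
ferric sulfate feed. Biomass is conservative (no anaerobic growth is
assumed; *Sulfobacillus* reduces iron here without measurable net
growth), so X* = Q₁X_in/(Q₁+Q₂). Iron: dFe3/dt = influx − D·fe3 − v −
k_p·fe3, dFe2/dt = −D·fe2 + v, with D = (Q₁+Q₂)/(1000·V). `steadyState()`
evaluates the piecewise-linear closed form (law-limited or
exhaustion-clipped branch) and returns fe3, fe2, biomass, feTotal,
fe3Fraction and the realised rate; the tests verify it against the
transient simulator. Defaults: 4 L, 22 g L⁻¹ Fe(III) feed at 3 mL h⁻¹.

`volumetricReductionRate()` computes the achieved rate from boundary
fluxes, (Q_out·fe2_out − Q_in·fe2_in)/(1000·V), which at steady state
equals the kinetic rate.

# 5. Nutrient flux accounting

`consumptionFlux(record, volume, hrt)` converts an inlet/outlet
concentration drop (mg L⁻¹) into mmol h⁻¹ using the throughput basis
drop · (V/HRT) / M, i.e. the volumetric flow times the drop. An
`basis = "inflow"` option uses a separately metered inflow instead.
Negative drops (net release, e.g. K⁺ leached from the sulfur or mineral
phase) are reported as negative fluxes and flagged, not clipped —
`nutrientFluxTable()` warns when a species is confounded this way.
`compareToBiomassDemand()` puts the measured flux beside the
stoichiometric demand from §3.

# 6. Synthetic data generators

`generateBatchExperiment(params, biomassLevel, seed)` runs the noiseless
batch simulator and overlays the measurement model:

* Eh channel: true potential from the Nernst relation plus i.i.d.
  Gaussian noise, default sd 5 mV — typical platinum-electrode
  repeatability in sulfate media. The ferric/ferrous ratio is clamped to
  [1e−8, 1e8] before conversion so the potential stays finite when
  Fe(III) is exhausted.
* Cell counts: multiplicative lognormal noise, default σ = 0.15 —
  representative of direct-counting error.
* Sampling: every 24 h for 288 h (daily over 12 days), matching the
  batch monitoring protocol.

Default biomass levels are 3×10⁸, 2×10⁹ and 5×10⁹ cells mL⁻¹, the span
of the batch experiments; with the default law the noiseless rates are
2.59, 8.47 and 18.85 mg L⁻¹ h⁻¹.

`generateRateLawDataset()` estimates Fe(II) from the *noisy* Eh channel
(as an experimenter would), truncates each series to its active phase
(samples with estimated Fe(III) above 5 % of the initial value — the
highest biomass level exhausts Fe(III) at ~239 h), takes the mean rate
over that phase, and pairs it with the geometric-mean cell count.
Per-experiment seeds are derived deterministically from the dataset seed
(`seed + (rep−1)·1000 + i`), so any single experiment can be regenerated
in isolation.

The generators emulate measurement noise on a deterministic process. They
do **not** emulate biological replicate variability (lag phases,
adaptation), electrode drift/bias, sampling-volume effects, or partial
Fe(II) oxidation during handling. Generator defaults are the study
operating conditions, and the recovery tests use them unchanged.

# 7. Numerical and reproducibility notes

* All stochastic functions take explicit integer seeds; equal seeds give
  byte-identical output.
* `writeTimeseries()` formats at 6 significant digits so
  write/read/write round-trips are byte-stable.
* `runReport()` emits a single JSON document with provenance (package
  version, seed, configuration hash); deterministic inputs yield
  byte-identical reports.
* OLS is implemented from the normal equations; the test suite checks it
  against `stats::lm` as an independent oracle.

# 8. Known limitations

* The one-couple Nernst model fails if other redox couples poise the
  electrode, and the effective $E^{0\prime}$ is medium- and
  temperature-specific — recalibrate when either changes.
* The linear biomass–rate law is an interpolation over the studied
  biomass range; it has no saturation term and must not be extrapolated.
* The stage-2 model assumes zero anaerobic growth and no biofilm; wall
  growth or attachment would decouple X* from the inflow balance.
* Precipitation is a lumped first-order sink; jarosite formation is in
  reality pH- and monovalent-cation-dependent.
* The sulfur electron donor is assumed non-limiting in all simulations.

# Session info

```{r}
sessionInfo()
```
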