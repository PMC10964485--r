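# ferrokin

Kinetics analysis of anaerobic Fe(III) bioreduction by acidophilic microbial
consortia in stirred tank reactors — the central reaction of reductive
bioleaching of limonitic laterite ores, where microbially produced Fe(II)
drives the dissolution of goethite and Mn oxides and the release of Co and
Ni. The package is aimed at bioprocess engineers and environmental
microbiologists who monitor such reactors (redox potential, iron
concentrations, cell counts) and need reproducible rate estimates, mass
balances and design numbers.

## What it computes

* **Iron speciation from redox potential.** The Fe(III)/Fe(II) concentration
  ratio follows the Nernst relation
  `r = 10^((Eh − E°′)/s)`, `s = ln(10)·R·T/F` (≈61.1 mV per decade at
  308.15 K), with a single effective formal potential `E°′` calibratable
  from one (Eh, ferric-fraction) anchor. Ferric fraction `f = r/(1+r)`.
* **Batch rate estimators.** The *maximal* bioreduction rate is the largest
  Fe(II) increase between two consecutive measurements; the *mean* rate is
  the endpoint slope over the bioreduction period, both in mg·L⁻¹·h⁻¹.
* **The biomass–rate law.** Ordinary least squares fit of
  `v_Fe(III) = a·X_liq + b` (rate vs planktonic biomass, cells·mL⁻¹) by the
  closed-form normal equations, with R².
* **Stoichiometry.** The reductive bioleaching network
  (`FeOOH + 3H⁺ ⇌ Fe³⁺ + 2H₂O`;
  `6Fe³⁺ + S⁰ + 4H₂O → 6Fe²⁺ + SO₄²⁻ + 8H⁺`;
  `MnO₂ + 2Fe²⁺ + 4H⁺ → Mn²⁺ + 2Fe³⁺ + 2H₂O`;
  `1/5 CO₂ + 1/20 HCO₃⁻ + 1/20 NH₄⁺ + H⁺ + e⁻ → 1/20 C₅H₇O₂N + 9/20 H₂O`)
  with exact rational coefficients, electron-balance derivations (6 Fe³⁺
  per S⁰), the 5:1 biomass C:N ratio, and the ammonium demand implied by a
  CO₂ uptake rate.
* **Reactor simulation.** ODE mass balances (deSolve) for the anaerobic
  batch reactor and the two-stage continuous cascade (growth chemostat with
  logistic growth and dilution; bioreduction chemostat with conservative
  biomass), with closed-form steady states, iron-inventory diagnostics and
  an optional first-order Fe(III) precipitation sink.
* **Nutrient consumption fluxes.** `drop × (V/HRT) / M` in mmol·h⁻¹ from
  inlet/outlet tables, with release (negative) flagged rather than clipped.
* **Synthetic data.** Seeded generators of batch monitoring series (Gaussian
  electrode noise on Eh, lognormal cell-count noise) and cascade tables, for
  end-to-end parameter-recovery studies.

## Worked example

```r
library(ferrokin)

## calibrate the Nernst relation on a continuous-pilot steady state
cal <- calibrateFormalPotential(680, 0.53)
cal
#> RedoxCalibration: E0' = 676.8 mV vs SHE, T = 308.15 K (slope 61.14 mV/decade)

## speciate 2.4 g/L total iron at 650 mV: ~27% remains ferric
speciate(2400, 650, cal)
#> IronSpeciation with 1 sample(s)
#>   feTotal      fe2      fe3
#> 1    2400 1759.096 640.9045

## a synthetic batch experiment at 2e9 cells/mL, and its rate estimates
p <- syntheticBatchParams(seed = 42)
bioreductionRates(generateBatchExperiment(p, 2e9))
#> RateEstimate: mean 8.47, max 8.47 mg/L/h

## recover the generating biomass-rate law from a noisy replicated panel
d <- generateRateLawDataset(p, replicates = 5)
fitRateLaw(d$biomass, d$rate)
#> RateLaw: v = 3.47e-09 * X + 1.84 mg/L/h  (R2 = 0.992)

## nutrient flux accounting: stage-1 ammonium consumption in the 2 L
## growth reactor at 73 h residence time, vs the stoichiometric demand
consumptionFlux(nutrientRecord("NH4+", 127, 59.3), volume = 2, hrt = 73)  # mmol/h measured
#>      NH4+
#> 0.1028157
ammoniumDemandFromCO2(40, 2)  # mmol/h expected from 40 mg/L/h CO2 uptake
#> [1] 0.4544422

## closed-form steady state of the bioreduction chemostat
steadyState(reductionReactorConfig(), list(biomass = 2e9))
#>          fe3          fe2      biomass      feTotal  fe3Fraction         rate
#> 1.184234e+03 1.053054e+03 1.796610e+09 2.237288e+03 5.293169e-01 7.766271e+00
```

The mean batch rate (8.47 mg·L⁻¹·h⁻¹ at 2·10⁹ cells·mL⁻¹) is the law
evaluated at that biomass; the recovered slope/intercept approach the
generating values (3.46·10⁻⁹, 1.55) as noise or replication shrinks; the
measured stage-1 ammonium flux (≈0.10 mmol·h⁻¹) sits well below the
stoichiometric biomass demand (≈0.45 mmol·h⁻¹), i.e. nutrients are in
excess.

## Documentation

The methods vignette (`vignettes/bioreduction-kinetics.Rmd`) describes the
model assumptions, parameter defaults and units, the synthetic-data design,
numerical choices and known limitations.
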