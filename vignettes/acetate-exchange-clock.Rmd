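---
title: "The acetate–water hydrogen isotope exchange clock: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The acetate-water hydrogen isotope exchange clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoclock)
```

## The model

Acetate's three methyl hydrogens exchange abiotically with water through a
reversible keto–enol tautomerization. In an excess water reservoir the
acetate ²H mole fraction relaxes toward its equilibrium value as a
first-order process,

$$\frac{F_e - F_t}{F_e - F_i} = e^{-kt},$$

where $F$ is the ²H fractional abundance $R/(1+R)$ and $F_e$ is set by the
water's abundance and the equilibrium isotope effect (EIE),
$R_e = \alpha_{eq} R_w$. The rate constant follows an Arrhenius law,
$\ln k = \ln A - E_A/(RT)$, calibrated between 60 and 200 °C and
extrapolated to ambient temperature. Because a first-order process is
within $2^{-4} \approx 6\%$ of equilibrium after four half-times, we treat
$4\,t_{1/2}(T)$ as the equilibration time. Observed acetate–water
disequilibrium then bounds the acetate residence time *from above* by that
equilibration time, and at steady state the standing concentration divided
by the bound is a *minimum* turnover (production = consumption) rate.

The clock is one-sided by construction: equilibrium observations are
uninformative (the acetate could be old, or could be produced in
equilibrium), so `run_site_analysis()` emits no residence bound for an
equilibrated site.

## Isotope arithmetic

All per-mil arithmetic is done in ratio space — never by adding ε values —
because the calibration experiments use 5% ²H₂O media where the linear
approximation breaks down badly. Reference ratios are configuration
constants (VSMOW ²H/¹H = 1.5576×10⁻⁴, VPDB ¹³C/¹²C = 1.11802×10⁻²,
standard literature values). Conversions δ↔R↔F round-trip to machine
precision, which the test suite asserts across the full delta domain.
Only the methyl site is modelled; carboxyl H (rapidly exchanging, not
retained through measurement workup) is outside the bookkeeping.

## Rate-constant fitting

`fit_rate_constant()` fits $k$ per incubation with $F_e$ fixed at its
EIE-derived value. Two numerical choices matter:

* **Near-equilibrium discard.** Points with
  $|F_e - F_t| < 0.05\,|F_e - F_i|$ are excluded (and counted), because
  $\ln(F_e - F_t)$ is ill-conditioned as its argument approaches zero. The
  5% threshold is our quantification of the qualitative rule that points
  close to equilibrium are discarded; it keeps the logarithm
  well-conditioned while retaining ~3 half-times of signal.
* **Estimator.** The log-linear OLS of $\ln(F_e - F_t)$ on $t$ is used for
  initialization and is exact on noiseless data. As the *final* estimator,
  however, it is biased: analytical noise is additive in δ (hence, nearly,
  in $F$), the log transform skews it, and the discard rule selects on it.
  In seeded Monte-Carlo runs of the full eight-experiment campaign
  (noise sd 2‰) the log-linear estimator recovered a median activation
  energy ~6 kJ/mol low, driven by the small-amplitude natural-abundance
  200 °C series. The default therefore refines the estimate by nonlinear
  least squares in abundance space, $F_t = F_e - A e^{-kt}$ with $A$ and
  $k$ free, which removes the bias (median $E_A$ recovered to <0.2 kJ/mol)
  while leaving noiseless recovery exact. `method = "linearized"` restores
  the log-linear estimator for comparison.

A flat series returns $k = 0$ with a `"no-exchange"` flag rather than an
error; overshoot past $F_e$ (possible under noise) is excluded and flagged.

## Arrhenius regression and extrapolation

`fit_arrhenius()` is unweighted OLS of $\ln k$ on $1/T$; replicate
experiments enter as separate points (the calibration's replicates are
plotted individually, and no weighting scheme is stated for the original
regression — both deliberate reproduction choices). The extrapolation
uncertainty is $\pm 2\times\mathrm{RMSD}$ of the $\ln k$ residuals — the
shaded-band convention of an Arrhenius plot — not a formal prediction
interval; with the two-endpoint reconstruction (3 h at 200 °C, 810 yr at
60 °C) the residuals are identically zero and the band collapses to the
point estimate, which still lands inside the published 250 ± 70 kyr band
at 25 °C (the two-point closed form gives 274 kyr, $E_A$ = 137.4 kJ/mol
vs the published 138). Seconds per year is fixed at 3.156×10⁷ everywhere a
result is expressed in years; temperatures convert as T(K) = T(°C) + 273.15.

The residence bound uses the central extrapolation; the 2×RMSD band
propagates to a `(years_low, years_high)` pair in the report rather than
widening the headline bound, since the published bound is likewise the
central estimate.

## The EIE curve

Anchors (−192‰ at 25 °C, −108‰ at 250 °C) are interpolated linearly as
$\ln\alpha$ vs $1/T^2$ — the standard high-temperature limit of reduced
partition function ratios. This form is validated, not assumed: it
reproduces the independently calculated 200 °C value (α = 0.882) from the
two anchors to within 0.001, which is a required test. Outside a
250–600 K guard range evaluation warns. When per-temperature beta factors
are available they take precedence (`eie_curve_from_betas()`). The brine
salt effect multiplies the water beta factor by 1.015 (the empirical 15‰
effect for a 3 M CaCl₂ brine at 25 °C); the multiplier is applied
temperature-independently and flagged away from 25 °C. The fully
Ca-complexed end-member (−167‰ at 25 °C) is available as an alternative
equilibrium reference; site observations remain >50‰ out of equilibrium
against either, so the disequilibrium call is robust to speciation.

## Disequilibrium threshold

The default threshold is 50‰ — the generous qualitative margin by which
the field observations clear both equilibrium references, far beyond
analytical uncertainty (~2‰). A site is called disequilibrated only when
*every* measured acetate value clears the threshold; the per-sample
offsets are reported so users can substitute uncertainty-based thresholds.

## Bioenergetics

$\Delta G = \Delta G^\circ + RT\ln Q$ with $Q=\prod a_i^{\nu_i}$,
$a_i = \gamma_i c_i$. Activity-model internals are out of scope: gammas
are inputs defaulting to 1 (at the reference site's ionic strength the
published power densities are reproduced within tolerance under unit
gammas). ΔG° defaults are −47.6 kJ/mol (acetoclastic sulfate reduction)
and −31.0 kJ/mol (acetoclastic methanogenesis) at 25 °C — standard
literature values, config-overridable and echoed in every report; pressure
enters only through ΔG°. Sulfide below detection defaults to 10 nM.

The cell-density formula as conventionally written multiplies a turnover
*time* by ΔG over maintenance energy, which is dimensionally inconsistent;
we implement the only reading with consistent units:
rate (mol L⁻¹ s⁻¹) × |ΔG| (J mol⁻¹) / ME (W cell⁻¹) → cells L⁻¹, with
endergonic reactions supplying zero power (flagged). The maintenance-power
grid 10⁻²¹…10⁻¹⁷ W/cell (decade steps) is our choice — the underlying
estimates are not printed — and reproduces the published 10²–10⁶ cells/mL
span at the reference power supply.

## Radiolysis

Per-element alpha dose rates scale linearly from reference emissions
(6.9×10⁻¹² Gy/s per ppm U, 1.93×10⁻¹² per ppm Th, zero for K — potassium
decay emits no alpha; a published sentence transposes these element/value
pairings, and we use the physically consistent mapping). The water–rock
ratio includes the $(1-\phi)$ rock-mass factor,
$W = \phi\rho_w/((1-\phi)\rho_r)$; both conventions round to the canonical
0.37% at φ = 1%. Only alpha radiation carries a nonzero acetate G value
(6 nM/J default, the maximum net in-vitro yield; the measured 1.3–6.0
range is available for sweeps); the per-element framework keeps slots for
beta/gamma should yields be measured. The literal yield formula
$Y = E_{net} G \rho_{bulk}/\phi$ is implemented as published since it
reproduces the reference 0.007 nM/yr; its net porosity dependence (with
$W$ recomputed from φ) is established numerically in the tests — it is
weak and slightly increasing — rather than assumed.

## What the synthetic generator emulates — and what a green test shows

`simulate_exchange_series()` forward-models the exchange equation exactly,
converts to δ, and adds Gaussian noise **in δ space** (sd 2‰ by default —
the order of a triplicate δ²H analytical sd; not a printed number, so it
is configurable), because that is the space measurements are reported in.
`simulate_campaign()` reproduces the laboratory design: 60 °C triplicates
sampled over a month, one month at 100 °C, a week plus a month at 150 °C,
and two three-day 200 °C runs with −50/+110‰ waters sampled hourly at
first. The generator does *not* emulate Orbitrap scan statistics, ion-count
shot noise, memory effects between bracketing standards, or drift — so a
green Monte-Carlo recovery test establishes that the estimator chain is
unbiased and correctly banded under idealized Gaussian analytical error,
not that the original instrument-level data reduction is reproduced.
Seeded runs are bit-reproducible; the generator restores the caller's RNG
state.

## Known limitations

* The calibration rests on the two published endpoint half-times plus
  synthetic recovery; the full per-experiment rate table is not public, so
  RMSD-based bands from the two-point reconstruction are degenerate (zero).
* The EIE between the anchors is an interpolation in a validated but
  assumed functional form; anchor uncertainty is not propagated.
* The clock gives one-sided bounds only, and says nothing about *which*
  process (biotic or abiotic) carries the turnover.
* Temperature dependence of ΔG° and of the salt multiplier is not
  modelled; pH and ionic-strength dependence of the exchange rate is out
  of scope (the calibration was run at the field-relevant pH 6–7).
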