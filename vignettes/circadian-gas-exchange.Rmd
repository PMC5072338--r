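---
title: "Circadian regulation of leaf-to-canopy gas exchange: models and methods"
author: "circaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian regulation of leaf-to-canopy gas exchange: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaflux)
```

## The scientific question

Diurnal variation in plant CO2 and H2O fluxes is conventionally attributed
to direct physiological responses to light (PAR), air temperature and vapour
pressure deficit (VPD). Plants, however, also carry an endogenous circadian
clock that modulates photosynthesis and stomatal opening on a ~24 h cycle.
Whether that leaf-level rhythm survives aggregation over a whole canopy —
where shaded leaves receive weaker entrainment cues and may free-run out of
phase — is an empirical question with consequences for flux modelling: if a
sizeable share of the diurnal flux range is clock-driven rather than
environment-driven, models that ignore the clock misattribute variance to
the environment.

`circaflux` implements the analysis chain for the experimental design that
answers this question: entrain canopies under realistic diurnal cycles, then
hold PAR, temperature and VPD constant for 48 h starting at solar noon. Any
~24 h oscillation that persists under constant conditions is endogenous.
The chain has five stages, each a package module:

1. **Synthetic experiment generator** — an Ecotron-style protocol with known
   circadian ground truth, so every downstream stage is testable.
2. **Flux derivation** — canopy assimilation from an open-chamber CO2 mass
   balance; transpiration from the smoothed derivative of lysimeter mass.
3. **Trend smoothing** — penalized-spline fits with AR(1) residuals and
   first-derivative significance analysis.
4. **Clock quantification** — the clock-driven share of the diurnal flux
   range, from the extrema of the fitted smooths.
5. **Stomatal model selection** — Ball–Berry, Leuning and Medlyn models with
   and without a sinusoidal circadian oscillator on the slope, ranked by AIC
   and Akaike weights under three calibration/validation splits.

## The synthetic experiment

`generate_environment()` builds the driver series: `entrain_days` (default
5) diurnal cycles with air temperature 28/19 °C max/min, VPD 1.7/0.5 kPa,
and a 12 h photoperiod at PAR 500 µmol m⁻² s⁻¹ (lamps give constant PAR when
lit, hence a square wave); then `constant_hours` (default 48) of frozen
drivers starting at the solar noon after the last entrainment day.
Temperature and VPD follow a cosine peaking at solar noon with the minimum
at midnight: the simplest smooth curve that honours the stated extremes
*and* makes the constant phase — which freezes drivers at their solar-noon
values — sit exactly at the entrainment maxima (PAR 500, 28 °C, 1.7 kPa).
Lights-on at 06:00 is a convention; the subjective day under constant
conditions is the hour-of-day window that was lit during entrainment.

`simulate_fluxes()` generates, per species and macrocosm:

- **Leaf assimilation**: a non-rectangular hyperbola light response
  (convexity 0.9) times a 24 h sinusoid of relative amplitude `amp_a`
  (default 0.24 for bean, 0.27 for cotton), peaking at subjective noon.
  No dark respiration: assimilation is zero at PAR 0.
- **Leaf conductance**: the Medlyn model with minimal conductance
  `g0 = 0.01` mol m⁻² s⁻¹ and an oscillating slope
  g1(t) = g1m + g1a·sin(2πt/24 + g1p), defaults g1m = 4, g1a = 1.
  The default phase `g1p = 7π/4` puts the conductance peak at ~09:00.
  This is deliberate: stomatal conductance is characteristically *higher in
  the morning than in the afternoon at the same environmental conditions*,
  and that asymmetry is precisely what a circadian slope adds beyond the
  symmetric diurnal drivers. A noon-peaked oscillation would be nearly
  collinear with the drivers during entrainment and therefore close to
  unidentifiable from changing-condition data — the morning peak is both
  the realistic condition and the reason changing-condition calibration can
  detect the oscillator at all.
- **Canopy fluxes**: the same signals with the circadian amplitude
  multiplied by `dilution` ∈ (0, 1]. Bean (LAI 7.5) gets 0.5, cotton
  (LAI 4.5) gets 0.7: a denser canopy holds proportionally more shaded
  leaves whose rhythms are not expressed at canopy scale, so its
  canopy-integrated amplitude is damped more. Transpiration is converted to
  l h⁻¹ per macrocosm (gs × VPD/P × 2 m² ground area × molar mass of
  water), giving ~0.4–0.7 l h⁻¹, the realistic magnitude for these
  canopies. The raw measurement records are emitted alongside: inlet/outlet
  CO2 at constant molar flow (13.6 mol s⁻¹ ≈ two dome volumes per minute)
  and the lysimeter mass trace.
- **Noise**: additive Gaussian with AR(1) correlation at the sampling step
  (lag-1 ρ = 0.6), independent per macrocosm, plus small per-macrocosm
  intercepts. Defaults (leaf assimilation SD 0.5 µmol m⁻² s⁻¹, conductance
  SD 0.01 mol m⁻² s⁻¹) put the conductance oscillation's signal-to-noise
  ratio near 5. Leaf temperature is set equal to air temperature (the two
  are indistinguishable in well-mixed domes). CO2 is fixed at
  400 µmol mol⁻¹ (configurable).

What the generator does **not** emulate: leaf biochemistry (no
Farquhar-type model — PAR is the only assimilation driver, which suffices
because PAR is binary under the protocol), hydraulic or carbohydrate
feedbacks (which would produce monotone drifts, not 24 h cycles), soil
respiration (excluded by design in the emulated protocol), within-canopy
light gradients (dilution is a single multiplier, not a leaf-by-leaf
simulation), and weather variability. Passing tests therefore demonstrate
that the statistical machinery recovers known structure under the assumed
noise model — not that real canopies behave this way.

## Stomatal models and the circadian oscillator

All three families share the structure gs = g0 + g1·x(drivers) + offset:

- **Medlyn**: gs = g0 + 1.6·(1 + g1/√D)·A/Ca
- **Leuning**: gs = g0 + g1·A / ((Ca − Γ)(1 + D/D0))
- **Ball–Berry**: gs = g0 + g1·A·h/Ca, with h = 1 − D/esat(Tair) clipped
  to [0, 1]

with A observed assimilation, Ca chamber CO2, D = VPD. The Leuning
constants default to Γ = 50 µmol mol⁻¹ and D0 = 1.5 kPa and are
configurable, not fitted. Chamber Ca is used rather than a leaf-surface
value: boundary-layer gradients are minimized by dome air-mixing. The
Medlyn form is singular at D = 0 and the Leuning form requires Ca > Γ;
both are errors, not silent clipping.

The circadian oscillator replaces g1 by
g1(t) = g1m + g1a·sin(g1f·2πt/24 + g1p), with the frequency fixed at one
cycle per 24 h (g1f = 1) when fitting, following the convention of fixing
the free-running period at the entrained one.

**Fitting is exact least squares, not iterative optimization.** Expanding
the sinusoid, g1a·sin(θ + g1p)·x = a·(x sin θ) + b·(x cos θ) with
a = g1a·cos g1p, b = g1a·sin g1p: every model in the grid is *linear* in
its free parameters, so the global Gaussian MLE is a single OLS solve —
deterministic, with no local optima, no multi-starts and no convergence
tolerance. The amplitude/phase pair is recovered as g1a = √(a² + b²) ≥ 0,
g1p = atan2(b, a) mod 2π, which also resolves the reflection symmetry
(−g1a, g1p) ≡ (g1a, g1p + π); standard errors follow by the delta method.

Two conventions follow the fitting protocol of the emulated study:
oscillator variants inherit g1m from the *corresponding* non-oscillator fit
(same family, same g0 option) on the same calibration window, and
re-estimate g0 when present — only g1m and g1f are fixed. The AIC parameter
count includes only structural parameters (g0; g1 or g1a, g1p); the
residual σ is a constant +1 across all models and cancels from AIC
differences.

One consequence worth knowing: when another rhythm (e.g. in assimilation)
overlaps in phase with the g1 oscillation, the non-oscillator fit absorbs
part of it into its slope estimate, so the inherited g1m is biased and the
refitted g1a no longer estimates the generator's g1a exactly. The
parameter-recovery simulation therefore generates data in which the g1
oscillation is the only rhythm; with it, median amplitude error is ~3–4%
and phase error ~0.03 rad at the study conditions (4 h cadence, 3
macrocosms, 72 h, SNR ≈ 5).

## Calibration/validation schemes and model ranking

Three splits are supported: entire set → entire set; changing (the final
entrainment day) → constant (the 48 h free run); and constant → changing.
The last one is the strictest test of practical value: it asks whether a
model calibrated with *no environmental variation at all* transfers to
field-like conditions. Models are fitted independently per species;
observed and predicted values are pooled across species before computing
the validation R² (the squared Pearson correlation of observed versus
predicted). AIC is computed per specification from the summed
log-likelihoods and parameter counts of the per-species fits, and Akaike
weights normalize exp(−ΔAIC/2) within each scheme.

## Trend smoothing and derivative significance

`fit_smooth()` fits a cubic regression spline (basis dimension k = 20 per
72 h window, capped at the number of unique time points minus one) by
fast-REML smoothness selection in `mgcv`, with fixed per-macrocosm
intercepts — with three levels the random-versus-fixed distinction is
immaterial for the smooth's shape, which is what all downstream
quantities use (predictions average the intercepts out). AR(1) residual
correlation is handled by a two-stage plug-in: fit, estimate the lag-1
autocorrelation of the residuals within macrocosms, refit with the
whitened likelihood, iterating at most 5 times to a 0.01 tolerance. This
honours the assumed residual structure without a full joint mixed-model
maximization; in a 200-replicate null calibration study the joint-ML
alternative was in fact slightly *worse* calibrated.

The first derivative is computed by central finite differences of the
basis expansion (half-step 10⁻³ h on a 500-point uniform grid), with the
pointwise variance from the delta method. Two numerical choices matter for
honesty of the 95% bands (derivative ± 1.96 SE):

- **Coefficient covariance**: the smoothing-parameter-uncertainty corrected
  covariance (`Vc`, the Marra–Wood correction) is used rather than the
  plain Bayesian posterior covariance. On 200 simulated constant-mean AR(1)
  series the pointwise exclusion rate of zero is ~5.6% with the correction
  versus ~7.4% without (nominal 5%).
- **Degenerate input**: an exactly constant response carries no residual
  information and breaks penalized-likelihood fitting; it short-circuits
  to the constant smooth with zero derivative and an all-false
  significance mask.

A grid point is flagged significant iff the derivative CI excludes zero;
`significance_segments()` collapses the mask into maximal runs labelled
increasing/decreasing. On a high-SNR 24 h sinusoid the mask covers well
over 60% of the cycle and opens a non-significant gap around each
extremum, where the derivative crosses zero.

## Quantifying the clock-driven share

For each flux, `clock_range_summary()` takes the extrema of the *fitted
smooth* (not the raw data) over two windows: the final entrainment day and
the constant phase. The clock share is 100 × range(constant) /
range(entrainment), reported to two decimals with half-up rounding. Two
conventions shape the denominator and numerator:

- **Zero floor**: the entrainment minimum is forced to zero (assimilation
  is zero in the dark; nocturnal conductance and transpiration are set to
  zero for this calculation even though they are small but positive). This
  enlarges the denominator, so the reported clock share is an
  *under*-estimate whenever the true entrainment minimum is positive.
- **Cropping**: negative fitted values are floored at zero before taking
  extrema for non-negative quantities (spline overshoot at the square-wave
  light transitions can produce small negative dark-time values that lack
  biological meaning).

`subjective_day_percentage()` recomputes the share with the constant-phase
extrema restricted to subjective-day grid points. Since no canopy
assimilation occurs at night and transpiration is lower in a real night
than in the subjective night, the full-cycle share overstates the daytime
relevance of the clock; the restriction can only shrink the numerator.

## Flux derivation

`nee_from_chamber()` implements the open-chamber balance
A = flow·(c_in − c_out)/area on *molar* flow (mol s⁻¹); volumetric flows
must be converted by the caller. `transpiration_from_mass()` smooths the
lysimeter mass record (no AR(1) term — the mass trace is an integral, so
its measurement noise model differs) and returns E = −dm/dt with 1 kg ≡ 1 l
(water density fixed at 1.000 kg l⁻¹); negative rate estimates are floored
at zero and flagged. The noiseless round trip (simulate mass from a known
E, invert) recovers E within ~0.1% of its mean away from the outer 5% of
the window; derivative estimates at window edges are boundary-biased, as
for any spline.

## Problem sizes and runtime choices

The simulation studies run at the protocol's own sizes: leaf fitting uses
the 4 h cadence with 3 macrocosms over 24 h changing + 48 h constant
(≈ 54 observations per species); canopy smoothing uses the 12 min cadence.
Replicate counts are 50 for the model-selection and parameter-recovery
studies in the test suite (20 in the acceptance script), and 200 for the
derivative-CI null calibration — enough for the binomial slack used in the
assertions while keeping a full run in tens of seconds.

## Known limitations

- The oscillator is a fixed-period, fixed-amplitude sinusoid; real clock
  output can relax in amplitude and lengthen in period under prolonged
  constant conditions, which this package neither simulates nor fits.
- Dilution is a single canopy-level multiplier; no leaf-level light
  environment is simulated.
- The inheritance of g1m makes oscillator-model amplitude estimates
  protocol-dependent (see above); comparisons between models remain valid,
  but g1a should not be read as a bias-free amplitude when other rhythms
  co-occur.
- Validation R² is scale/offset invariant (a prediction equal to
  2·obs + 3 scores 1.0); it measures association, not calibration.
- Derivative CIs are pointwise, not simultaneous: over a long series some
  spurious short significant runs are expected at the 5% level.
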