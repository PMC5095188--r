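---
title: "Thermalling flight mechanics from 1 Hz GPS tracks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermalling flight mechanics from 1 Hz GPS tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soarflight)
```

## The question and the model

A soaring bird that climbs from dense low-altitude air into thin
high-altitude air must keep generating lift `L = ½ ρ v² S C_L` against a
near-constant weight. It can do so biophysically, by raising the lift
coefficient `C_L` (wing posture, angle of attack), or behaviourally, by
raising its airspeed `v` — which, in circling flight, also forces wider
circles if the bank angle is to stay constant. `soarflight` extracts all the
quantities needed to separate these hypotheses from 1 Hz GPS fixes alone.

The flight model is a balanced turn at constant airspeed, radius and bank
angle over each 30 s analysis window:

* vertical balance: `l cos θ = g`
* horizontal (centripetal) balance: `l sin θ = v² / r`
* hence `l = sqrt(g² + (v²/r)²)` and `θ = atan(v² / (g r))`
* lift coefficient: `C_L = 2 l (m/S) / (ρ v²)`, with wing loading `m/S`

where `l` is lift acceleration (lift force per unit mass) and `g = 9.81
m s⁻²` is treated as altitude-independent; buoyancy is ignored. Both
simplifications are far below GPS noise over the 0–7 km band of interest.

Two derived closed forms follow from the same balance. Holding `C_L` and
`m/S` fixed, flying from density `ρ_l` into `ρ_h < ρ_l` requires the
fractional airspeed increase `sqrt(ρ_l/ρ_h) − 1`
(`airspeed_compensation()`). And banking raises the equilibrium sink rate by
`cos(θ)^(−3/2)` relative to straight flight
(`sink_rate_turn_correction()`); we report both the penalty factor and its
complement, the best attainable improvement `1 − cos(θ)^{3/2}`, which are
exact mutual inverses.

## From fixes to per-loop kinematics

**Windows.** Fixes are grouped into 1 Hz bursts (any gap above 1 s splits a
burst; duplicate timestamps keep the first fix). Within a burst, 31-fix /
30 s windows are scanned left to right. Each window is projected onto a
local tangent plane about its own centroid (equirectangular, spherical
radius 6 371 000 m); over the few hundred metres a thermalling circle
covers, projection distortion is negligible, and centring per window keeps
it so.

**Velocities and full-circle detection.** Ground velocities are central
differences at interior fixes and one-sided differences at the two ends.
Headings `atan2(v_N, v_E)` are unwrapped and a window qualifies as a loop
when the cumulative turn reaches `2π` in magnitude and every speed exceeds
0.5 m s⁻¹ (far below any plausible soaring speed; near-zero speeds make
headings undefined, so such windows are rejected rather than erroring).
Accepted windows tile the burst in contiguous 30 s intervals — consecutive
segments share one boundary fix — and the scan advances a single fix after a
rejected window. The scan is deterministic, and segments never cross burst
boundaries. Headings are taken from *ground* velocity because the wind is
unknown at this stage; with wind well below airspeed the winding number is
unaffected.

**Two finite-difference corrections.** Differentiating a sampled rotation is
exact in phase but not in amplitude or span, and both effects matter at our
tolerances:

1. *Turn-span correction.* The one-sided end headings sit at effective times
   0.5 s and 29.5 s, so the raw heading span covers 29 of the 30 s and
   underestimates the turn by exactly 29/30 on noiseless circles (a 3.3%
   bias at every period). The cumulative turn is therefore scaled by 30/29,
   making `ω = |Δθ|/30` exact on noiseless circles.
2. *Amplitude correction.* Central differencing attenuates a rotation of
   rate ω sampled at Δt by `sin(ωΔt)/(ωΔt)` — 2.2% at ω = 0.37 rad s⁻¹ and
   10% at ω = 0.8 rad s⁻¹ — while leaving any constant drift untouched.
   Air-relative speeds are multiplied by the inverse factor using the fitted
   ω, so airspeed is exact on noiseless circular flight.

**Wind from loop drift.** In a steady horizontal wind the ground velocity of
a circling bird is a constant vector plus a uniformly rotating one:

```
v_E(t) = w_E + a cos(ω t + φ)
v_N(t) = w_N + s a sin(ω t + φ),    s = turn direction (±1)
```

For fixed ω the model is linear in `(w_E, w_N, a cos φ, a sin φ)` and is
solved by QR least squares on the 29 interior velocities; ω is then refined
by golden-section minimisation of the residual sum of squares over ±20% of
the heading-based ω. Only interior (central-difference) velocities enter the
fit: the constant wind passes through central differencing exactly and the
rotating part has a *known* attenuation, whereas the one-sided end
velocities have a different attenuation and a half-sample phase shift —
including them biases noiseless wind recovery by roughly 0.1 m s⁻¹. The
bracket stop is 1e−11 rad s⁻¹; at that resolution noiseless wind recovery is
limited only by floating point and the (sub-µm) projection curvature. A
rank-deficient design or a vanishing heading rate (straight flight) returns
a non-converged estimate rather than an error, and such segments are dropped
with their count recorded.

Airspeed is the mean attenuation-corrected magnitude of the wind-subtracted
interior velocities; it is horizontal only, since a ~1 m s⁻¹ climb
contributes under 0.5% to speed magnitude at soaring speeds. Segments whose
fitted wind speed reaches the airspeed violate the method's small-wind
assumption and are flagged `wind_dominant` (strict inequality: a tie is
already dominant) and excluded from kinematics.

**Which ω feeds the kinematics.** The heading-based estimator `|Δθ|/30` is
retained for `r = v/ω` and everything downstream; the wind fit's refined ω
is reported alongside as a diagnostic. With wind present, the heading span
of the *ground* velocity wobbles by up to `2(w/a)` radians over a window, so
the heading-based ω carries a zero-mean, phase-dependent error of a few
percent per segment; it averages out across segments and keeps the
pipeline's definition of ω independent of the wind model.

**Air density.** Preference order is configurable: a per-fix density column
when present, else the International Standard Atmosphere evaluated at the
segment's mean altitude (`T = 288.15 − 0.0065 h`,
`p = 101325 (T/288.15)^5.25588`, `ρ = p/(287.058 T)`, valid to 11 km).
Pressure/temperature annotations can be converted upstream with
`air_density()`. Segments with no density source are dropped and counted.
GPS altitude is used as recorded, without smoothing or geoid correction.

## The statistical layer

* **Equal-count elevation bins** (default k = 15): segments sorted by
  altitude, ties broken by time order, bin sizes `floor(N/k)` or
  `ceil(N/k)` with the lower bins taking the remainder; counts differ by at
  most one. Per-bin summaries use type-7 (linear interpolation) quantiles;
  the 95% interval is the 2.5–97.5 percentile range.
* **Density tail groups** (default fraction 5%): the `round(0.05 N)`
  segments at highest density form the low-flying group and the same number
  at lowest density the high-flying group; rounding is half-up (so N = 30
  gives 2 per group), and overlapping groups are an error. Contrasts are
  `(ρ_l/ρ_h − 1)`, `(r_h/r_l − 1)`, `(v_h/v_l − 1)`, and the
  lift-coefficient difference `(C_L,low − C_L,high)/C_L,low` — the
  low-flying value is the denominator convention throughout. `C_L` is
  computed per segment and then averaged per group; since `C_L` is nonlinear
  in `(v, r, ρ)`, this averaging order is part of the definition.
* **Speed–density regression:** unweighted OLS with intercept of `v²` on
  `1/ρ` across all accepted segments. At constant `C_L` the theoretical
  slope is `2 g (m/S)/C_L` (with `l = g`); `theoretical_speed_density_slope()`
  exposes it. A single pre-specified model is fitted, so the slope's
  two-sided t-test p-value is reported without any multiplicity machinery.
* **Radius–altitude trend:** a constant percentage change per km *is* a
  log-linear model, so the trend is OLS of `log r` on altitude in km,
  reported as `(exp(slope) − 1)·100` percent per 1000 m; it requires at
  least 1 km of altitude span.

Tunable parameters, all arguments of `thermal_flight()` /
`run_config()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `wing_loading` | 10.54 | kg m⁻² | population mean of the study species; individual masses vary with feeding, so a fixed population value is used for every segment |
| `k_bins` | 15 | – | elevation bins with equal counts |
| `tail_fraction` | 0.05 | – | density tail groups |
| `min_speed` | 0.5 | m s⁻¹ | heading-validity gate, far below soaring speeds |
| `density_source` | column, then ISA | – | measured density preferred; ISA is a deterministic fallback |

## What the simulator emulates — and what it does not

`simulate_thermalling_track()` generates the planar path
`p(t) = w t + r (cos(sωt + φ₀), sin(sωt + φ₀))` at 1 Hz (a burst of B
seconds holds B + 1 fixes), climbs at a constant rate, adds independent
Gaussian noise per horizontal coordinate, and inverse-projects onto the
globe. Defaults mirror the observed flight regime: 10-minute bursts,
airspeeds 8–16 m s⁻¹, radii 20–60 m, winds of a few m s⁻¹, ~1 m s⁻¹ climb,
0.5 m GPS noise, ISA densities spanning roughly 1.1 down to 0.65 kg m⁻³
across the altitude band. Every 30 s window's true wind, airspeed, ω, r, θ,
l, ρ and `C_L` are recorded so each pipeline stage can be checked against
ground truth. A seed is mandatory; identical seed and configuration give
identical output.

`simulate_population()` encodes the behavioural hypothesis itself: every
bird holds `C_L` constant (default 1.787, the value implied by wing loading
10.54 and a regression slope of 115.7), so true airspeed per flight level is
`v = sqrt(2 g (m/S)/(ρ C_L))` and radius scales as `v²` to hold bank angle
constant (default 22°, near the observed low-altitude value). The default
grid spans ISA densities 1.099 to 0.646 kg m⁻³ in 12 levels, 3 birds per
level, with per-track random wind (≤ 3 m s⁻¹), turn direction and phase.

Deliberately *not* simulated: thermal updraft structure (climb is
prescribed, not driven by an updraft field), time-varying or sheared wind
within a track, autocorrelated GPS error, flapping flight, and any
energy-budget behaviour. Passing the recovery tests therefore shows the
*estimators* are correct under the model's assumptions — constant wind per
loop, balanced circular turns, white position noise — not that real
vulture tracks satisfy those assumptions. On field data the wind-fit RMS
residual and the `wind_dominant` / non-convergence counts in the run report
are the diagnostics for assumption violations.

## Numerical choices and degenerate inputs

* Windows are exactly 31 fixes / 30 s; anything else is a contract error at
  projection time. Burst membership guarantees 1 Hz spacing.
* The full-circle criterion is `|Δθ| ≥ 2π` exactly (a window holding
  exactly one period passes after the turn-span correction); magnitude is
  used so clockwise and counterclockwise turns are symmetric, with the sign
  kept for the wind fit.
* Golden-section search: bracket ±20% of the initial ω, stop when the
  bracket is below 1e−11 rad s⁻¹ (or the RSS is stationary to 1e−10
  relative); ~55 RSS evaluations, each a 58×4 least-squares solve.
* Initial ω below 1e−3 rad s⁻¹ (no discernible rotation) short-circuits to
  a non-converged estimate.
* Zero accepted segments is a valid, non-error outcome everywhere; the
  statistics that need more segments than available (bins, groups,
  regressions) are simply absent from the fit object.
* Tail-group rounding is half-up; equal-count binning gives the remainder
  to the lower bins; quantiles are type 7. These conventions are asserted
  in the test suite so they cannot drift silently.

## Validation scale

The test suite and acceptance script validate at desk scale: recovery grids
over v ∈ {8, 11, 16} m s⁻¹ × r ∈ {20, 40, 60} m × wind ∈ {0, 3, 6} m s⁻¹ ×
both turn directions (combinations whose circle period exceeds 30 s never
produce a loop segment and are exercised directly at the estimator level);
200-loop Monte Carlo at 0.5 m GPS noise; populations of 720 segments
(3 birds × 12 levels × 20 windows) for the end-to-end constant-`C_L`
recovery; 400–8595-point fixtures for the statistical layer. These sizes
give the regression and Monte Carlo checks standard errors comfortably
inside their asserted tolerances while keeping the whole suite fast.

## Known limitations

* The wind is assumed constant within each 30 s loop and the turn balanced;
  gusts, shear and accelerating flight violate the model and surface as
  inflated RMS residuals rather than biased estimates being flagged.
* The heading-based ω (and hence r and `C_L`) carries a few-percent
  per-segment wobble in windy conditions; analyses should average over many
  segments, as the statistical layer does.
* Airspeed is horizontal; in strong climbs (> 2 m s⁻¹ at 10 m s⁻¹
  airspeed) the neglected vertical component approaches 2%.
* The ISA fallback is a climatological reference, not weather; where real
  density annotations exist they should be supplied as the `air-density`
  column.
* Wing loading is a population constant; per-individual `C_L` levels are
  confounded with individual mass deviations by construction.
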