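---
title: "Methods: evaluating ICU continuous glucose monitoring with cgmeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating ICU continuous glucose monitoring with cgmeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmeval)
```

`cgmeval` quantifies how well a per-minute subcutaneous glucose sensor
tracks intermittent blood-gas reference measurements in intensive-care
patients, and whether its real-time display is reliable enough to steer
insulin therapy. This vignette explains the models and conventions behind
each stage, the choices we made where the methodology is genuinely open,
and what the synthetic cohort generator does and does not emulate.

## Pairing model

A comparative pair joins a reference blood glucose value R drawn at time t
with the latest displayed sensor value S at or before t. Decisions:

- **Staleness window, 5 min (configurable).** "The latest value
  immediately before" is unquantified in common usage; at a 1/min display
  cadence a 5-min window bounds the staleness while tolerating short
  display hiccups. References inside longer gaps are counted as
  *unpairable* rather than matched to stale data.
- **Same-minute ties.** Timestamps are floored to the minute (the device
  cadence); a sensor value in the same minute as the draw is used.
- **Calibration exclusions.** The device requires a blood entry at start,
  +1 h and +2 h, and after display gaps longer than 15 min. Those entries
  are circular as accuracy evidence (the gain is re-anchored to them), so
  they are excluded. The three initial entries are identified by order
  within the session. Routine 8-hourly calibration values are kept as
  pairs but flagged (`is_calibration`), so either convention is one filter
  away.
- **Inclusion rule.** A patient enters the accuracy analysis with ≥ 48 h
  of monitoring *or* ≥ 12 comparative readings.

## Point accuracy

ARD = |R − S| / R × 100; MARD is the arithmetic mean. The 95 % CI uses the
normal approximation MARD ± 1.96·sd(ARD)/√n by default; a seeded
percentile bootstrap is available (`mard(..., ci = "bootstrap")`). The
consensus criteria for ICU CGM are evaluated with *inclusive* bands
("within 12.5 %" means ≤ 12.5 %), and the ± 10 mg/dl absolute alternative
applies whenever R < 100 mg/dl. Bland–Altman uses differences R − S, bias
= mean, limits of agreement bias ± 1.96 × sample SD (n − 1).

The Clarke error grid uses the canonical piecewise-linear 1987 zone
geometry; every boundary inequality is written out in `clarke_zone()`'s
documentation and the classifier is checked against an independently
written per-point oracle over a 600 × 600 grid at half-integer
coordinates (avoiding ties exactly on boundaries). Boundary conventions:
zone A takes deviations ≤ 20 % and the strict hypoglycemic corner
(R < 70 and S < 70); overlapping regions resolve in the order A, E, C, D,
with B as the remainder — the order the canonical definition implies.

The surveillance-style risk surface is **synthetic**: the published
Surveillance Error Grid distributes its full-resolution surface only as
external software, so `cgmeval` builds a coarse anchor grid from a
documented clinical-action score (a monotone piecewise-linear map from
glucose to the direction/intensity of the treatment response it would
trigger; risk = capped absolute score difference, scale 0–4 with color
zones at 0.5/1.5/2.5/3.5). The grid is parameterised over
(reference, error) rather than (reference, sensor) so that bilinear
interpolation is *exactly* zero on the identity diagonal and
non-decreasing as the estimate moves away from the reference. Scores from
this surface are comparable within analyses that use it, but are not
numerically interchangeable with published SEG risk values.

## Reliability

A display gap is a maximal run of missing minutes between initialization
and removal; a leading run before the first displayed value also counts.
Early removal is *not* a gap — removal reasons are tabulated separately
from gap causes. Duration categories: very brief < 15, brief 15–30,
prolonged 31–120, very prolonged > 120 min. The printed convention
"15–30 / > 30 / > 2 h" leaves the 30- and 120-min edges ambiguous; we
close each edge downward (30 is brief, 120 is prolonged) and state it
here. Cause codes 1–7 are input annotations (1–3 device-related); when a
gap spans several annotated episodes the majority cause is kept. The
consensus display criterion (display > 95 %, device-related gaps
< 30 min) is evaluated against actual monitoring time by default,
configurable to the expected 72 h — both denominators appear in the
per-sensor table. Cohort medians are computed per sensor and then
aggregated, never over pooled minutes.

## Glycemic metrics

Bands use the standard ICU integer edges: severe hypoglycemia ≤ 40,
moderate hypoglycemia 41–70, euglycemia 71–149, moderate hyperglycemia
150–179, severe hyperglycemia > 179 mg/dl; the insulin-therapy target
(80–149) is carried as a separate labelled range and never mixed with the
71–149 analysis band. Event counting is transition-based ("newly
developed"): one event per entry into the band, one for a series starting
inside — so a per-minute series is not over-counted relative to a sparse
one traversing the same path.

Time in range interpolates linearly between consecutive samples and
computes exact band-edge crossing times; segments resting exactly on an
edge count toward the target (edges inclusive). For sparse 2–4-h
reference data the alternative readings-share estimate is one argument
away (`method = "readings"`); we default to interpolation because it
treats rises and falls symmetrically, and report both where the
distinction matters. The glycemic lability index is
GLI = Σ ΔG²/Δt(h), accumulated in 24-h windows anchored at the first
sample, each increment assigned to the window containing its interval
start; partial windows are scaled up to 24 h. Units are (mg/dl)²/h per
24 h throughout — note that the older per-week, mmol-based convention
produces numbers roughly two orders of magnitude smaller, so GLI values
are only comparable within one convention.

## Confounders and lag

MARD is stratified by reference glucose range (< 80, 80–179,
≥ 180 mg/dl; Kruskal–Wallis) and by each pair's deviation from the
patient's *daily* reference mean: within one daily SD versus beyond it
(rank-sum). Daily windows are 24-h blocks anchored at the first monitored
minute; days with fewer than two reference values leave their pairs
unassigned (reported, untested). Covariates are matched to pairs by
nearest timestamp within ± 4 h (blood-gas cadence); continuous covariates
get Spearman correlations against ARD, binary ones rank-sum group tests;
p-values are reported raw, with no multiplicity correction, as is usual
in exploratory confounder screens.

The time-shift analysis pairs each reference at t with the sensor value
at t + k (sensor later; the physiological direction of interstitial lag),
k = 0…30 by default, negative k available. Shift 0 reproduces the
unshifted MARD exactly; the argmin of MARD(k) estimates the effective
sensor delay.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
with defaults calibrated to a realistic 20-patient medical-surgical ICU
cohort: ~31 sensors (second sensor after a premature first removal),
premature-removal probability 0.677, gap onsets 0.12/h with category mix
43.9/22.6/17.4/16.1 %, blood-gas draws every 2–4 h (≈ 28 comparative
readings per patient), calibrations at start/+1 h/+2 h then 8-hourly plus
post-gap entries, per-patient mean glucose 134 mg/dl with SD 25.

**Blood glucose dynamics.** An exactly discretized Ornstein–Uhlenbeck
process (mean reversion 2 h) passed through a two-stage exponential
smoother (stage constant 30 min), with the innovation variance rescaled
via the exact discrete-time Lyapunov solution so the stationary SD equals
`bg_sd`. The smoothing is deliberate: a raw 1-min OU path has independent
minute-to-minute increments, a roughness real glucose does not have, and
one with a sharp statistical consequence — for a random-walk-like signal
the MARD-minimizing time shift of a first-order lag is the lag kernel's
*median* (≈ 0.69 τ), not τ, which would make the lag analysis
systematically "recover" the wrong delay. Two smoothing stages give the
path a continuous velocity, i.e. the momentum of meal- and insulin-driven
excursions. Transient dysglycemia episodes (half-sine bumps, default
0.5/day, 55 ± 20 mg/dl, 80 % hyperglycemic) are superimposed; the path is
floored at 20 mg/dl.

**Interstitial lag.** dI/dt = (G − I)/τ, discretized with the exact
exponential update so a step reaches 1 − e⁻¹ = 63.2 % after τ minutes;
τ = 0 is the identity.

**Sensor.** Displayed value = gain(t) · I(t) + Gaussian noise. The gain
random-walks multiplicatively (0.01/√h) and re-anchors at every
calibration so the *subsequent* display matches the entered blood value;
the displayed value at the calibration minute itself still carries the
old gain, since that is the value the entry is compared against.
Calibrating mid-excursion therefore bakes the momentary blood–interstitial
gap into the gain — reproducing, as a testable scenario, the way blood
calibration can amplify rather than remove error.

**What it does not emulate.** The sensor noise is white at 1 min. Real
devices smooth internally, so Δ-based statistics computed *on the dense
sensor series* (GLI, event counts at band edges) come out far larger here
than on a device trace of equal point accuracy; comparisons of those
metrics between the intermittent and continuous series are therefore
qualitative in this generator. There is no meal/insulin input model, no
trend-accuracy ground truth, and covariates are uninformative
autocorrelated series unless `covariate_coupling > 0` deliberately ties
SOFA to sensor noise.

## The lag-recovery experiment

Recovering τ from `time_shift_mard()` is only well-posed under conditions
a validation experiment would deliberately create, and two default
mechanisms must be switched off to see the lag at all:

1. **Blood-anchored recalibration partially cancels lag.** At a
   calibration the gain absorbs the momentary blood–interstitial gap, so
   for the following trend-persistence time the display effectively leads
   the interstitial signal. Under the routine 8-hourly schedule this
   halves the apparent delay — consistent with published ICU evaluations
   that found no clear fixed shift. The experiment calibrates only at
   session start.
2. **Curvature biases the optimum low.** A first-order filter equals a
   pure τ-delay only for locally linear input. Transient episode bumps
   and fast mean reversion curve the path over the kernel span (~3 τ) and
   pull the MARD-optimal shift 1–2 min below τ at τ = 20. The experiment
   uses slow reversion (4 h), stronger smoothing (stage 90 min), and no
   episodes.

With full 72-h sessions, dense reference draws (0.5–1 h), sensor noise
1 mg/dl and no drift, the per-patient argmin median over 20 patients
recovers τ ∈ {5, 10, 20} within ± 2 min across seeds. The default cohort
settings are *not* changed by any of this; the experiment is a controlled
configuration of the same generator.

## Numerical conventions and degenerate inputs

Percentages print to one decimal, half-up. Timestamps are floored to the
minute with a warning. Sessions longer than 72 h (+ 60 min scheduling
tolerance) are validation errors, as are non-positive glucose values,
duplicate sensor minutes and unknown reference sources. Empty pair sets
raise errors in estimators that need data (`mard`, `bland_altman`,
`rank_correlation`) but yield empty *reports* where the study design
allows absence (no qualifying patient in the parallel comparison, empty
covariate tables). Constant series make rank correlations undefined
(error) and lag profiles flat (reported as such). Risk-surface queries
outside 20–600 mg/dl are clamped with a warning.

Test problem sizes: unit tests run 4-patient cohorts with shortened
pre/post windows; the golden smoke, noise-monotonicity and lag-recovery
checks use the full 20-patient design described above. The whole suite
completes in under a minute on one CPU.

## Limitations

Point accuracy only: trend (rate-of-change) agreement is out of scope.
The risk surface is a documented approximation, not the published SEG
software. The generator's defaults are calibration targets for cohort
*structure* (counts, rates, moments), not a physiological glucose model;
conclusions about real devices require real paired data, which the
pipeline accepts through `read_cgm_dataset()`.
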