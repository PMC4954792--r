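# cgmeval

Evaluation of continuous glucose monitoring (CGM) devices against
intermittent blood-gas reference measurements in critically ill patients.

## The problem

Subcutaneous CGM sensors report interstitial glucose once per minute, but
ICU insulin therapy is steered by intermittent arterial/venous blood-gas
analyses taken every 2–4 hours. Before a CGM device can guide therapy, its
point accuracy and reliability must be quantified against that reference
standard. `cgmeval` implements the full evaluation pipeline used in ICU
device studies:

- **Comparative-pair extraction** — each reference value is matched to the
  latest displayed sensor value at or before the draw (5-min staleness
  window); reference values that served as initial calibrations (start,
  +1 h, +2 h) or as calibrations after display gaps > 15 min are excluded.
  Patients qualify with ≥ 48 h monitoring or ≥ 12 comparative readings.
- **Point accuracy** — for pairs (R, S) the absolute relative difference is
  ARD = |R − S| / R × 100, and MARD is its mean, with a normal-approximation
  (or bootstrap) 95 % CI. The 2013 consensus criteria for ICU CGM are
  checked: ≥ 98 % of readings within 12.5 % (or ± 10 mg/dl when R < 100),
  the remainder within 20 %, MARD < 14 % (> 18 % flags poor accuracy).
  Bland–Altman bias with limits of agreement `bias ± 1.96·sd(R − S)`,
  Spearman rank correlation, the Clarke error grid (canonical 1987 zone
  geometry), and a surveillance-style clinical risk surface (synthetic
  anchor grid, bilinear interpolation, zero on the identity diagonal).
- **Reliability** — display gaps (maximal runs of missing minutes) in four
  duration categories (< 15, 15–30, 31–120, > 120 min), cause attribution
  (codes 1–3 device-related), per-sensor display percentages against both
  the expected 72 h and the actual monitoring time, premature-removal
  tabulation, and the consensus display criterion (> 95 % display,
  device-related gaps < 30 min).
- **Glycemic metrics** — dysglycemia bands (≤ 40 / 41–70 / 71–149 /
  150–179 / > 179 mg/dl), newly developed hypo-/hyperglycemia events,
  interpolated time in range with exact band-edge crossings, SD, and the
  glycemic lability index GLI = Σ ΔG² / Δt(h) per 24-h window.
- **Confounders and lag** — MARD stratified by glucose range and by
  deviation from the patient's daily mean (within vs beyond 1 SD),
  covariate screening (Spearman / rank-sum), and the time-shift analysis:
  MARD recomputed with the reference paired to the sensor value k minutes
  later, k = 1…30, whose argmin estimates the interstitial delay τ.
- **Longitudinal and parallel comparison** — glycemic control in 72-h
  windows before/during/after monitoring (Friedman + Wilcoxon), and
  intermittent-vs-continuous metrics in patients where the device read
  accurately (MARD < 14 %).

Because ICU CGM trial data are rarely shareable, the package ships a fully
seeded **synthetic cohort generator**: smoothed mean-reverting (Ornstein–
Uhlenbeck) blood-glucose dynamics with transient dysglycemia episodes, a
first-order interstitial lag dI/dt = (G − I)/τ, a per-minute sensor with
calibration-anchored multiplicative gain drift and additive noise, display
gaps, premature removals, blood-gas sampling, and the standard calibration
schedule. Every pipeline stage is tested against this generator's ground
truth.

## Worked example

```r
library(cgmeval)

cohort <- simulate_cohort(sim_config(seed = 42))   # 20 synthetic ICU patients
pairs  <- extract_pairs(cohort$dataset)
pairs
#> <cgm_pairs> 620 comparative readings (20 patients)
#>   of 1804 references: 620 paired, 176 calibration-excluded, 47 unpairable, 961 outside sessions
#>   MARD 5.5 %

accuracy_report(pairs)
#> <cgm_accuracy> 620 comparative readings
#>   MARD 5.5 % (95 % CI 5.1-5.8 %)
#>   within 12.5 % (or 10 mg/dl < 100): 92.6 %; within 20 %: 99.4 %
#>   consensus criteria: c1 FALSE, c2 FALSE, c3 TRUE -> FAIL
#>   Bland-Altman bias -0.00 mg/dl, LoA +17.6 / -17.6 mg/dl
#>   Spearman rho 0.929 (p <2e-16), r^2 0.864
#>   Clarke zones (%): A 99.4, B 0.5, C 0.0, D 0.2, E 0.0
#>   Risk surface: mean risk 0.10; zones (%): none 99.4, slight 0.6, moderate 0.0, great 0.0, extreme 0.0

reliability_summary(cohort$dataset)
#> <cgm_reliability> 31 sensors, 20 patients
#>   actual monitoring time   55.8 [38.2/72.0] h
#>   real-time data display   50.1 [32.1/62.5] h
#>   display / expected 72 h  69.6 [44.6/86.9] %
#>   display / actual time    91.6 [88.1/94.5] %
#>   gaps: 154 (very_brief 63, brief 35, prolonged 25, very_prolonged 31)
#>   premature removals: 22 of 31 sensors (71.0 %)
#>   consensus display criterion (>95 % of actual time, device gaps <30 min): FAIL

time_shift_mard(cohort$dataset)
#> <lag_profile> 31 shifts evaluated
#>   MARD minimized at shift 9 min (MARD 4.97 %)
#>   unshifted MARD 5.46 %
```

Reading the numbers: 1804 blood-gas values were logged over the patients'
stays; 620 fall inside a sensor session, outside the calibration exclusions
and within the pairing window, and form the accuracy dataset. The device
here is *precise but not consensus-accurate*: MARD 5.5 % is well under
14 %, yet only 92.6 % of readings sit inside the 12.5 % band, so the first
consensus criterion fails. The Bland–Altman bias near zero with ± 17.6
mg/dl limits shows random rather than systematic error. Reliability fails
the consensus display criterion because device-related gaps exceed 30 min.
The lag profile locates the accuracy optimum at a +9-min shift —
consistent with the configured 10-min interstitial lag, partially masked
by blood-anchored recalibration (see the methods vignette).

Hand-collected CSV data load through `read_cgm_dataset()` (column layouts
in its help page); `evaluate_cgm()` runs the whole standard evaluation in
one call, and `longitudinal_compare()` / `parallel_compare()` produce the
before/during/after and intermittent-vs-continuous comparisons.

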