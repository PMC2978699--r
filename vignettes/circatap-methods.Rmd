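---
title: "Assessing circadian function from wrist temperature, activity and body position"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing circadian function from wrist temperature, activity and body position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circatap)
```

## The problem

Ambulatory assessment of the human circadian system relies on overt rhythms
recorded under free-living conditions. Each single marker is masked by
behaviour: wrist skin temperature rises during rest through distal
vasodilation but also responds to ambient exposure and showers; motor
activity and body position respond to volition as much as to the clock.
`circatap` implements an integrated variable, **TAP**, that fuses the three
simultaneous recordings — wrist **T**emperature, motor **A**ctivity and body
**P**osition — so that uncorrelated masking artifacts partially cancel, and a
single-number summary of circadian robustness, the **Circadian Function
Index (CFI)**.

## Signal derivation and preprocessing

The upper-arm logger records three-axis accelerations every 30 s with its
X-axis along the humerus. Two variables are derived:

* **Body position** `P = asin(|x| / ||(x,y,z)||)`, in degrees: 0 when the arm
  is horizontal (lying), 90 when vertical (upright). The unsigned `|x|`
  makes arm-up and arm-down both read as vertical, which is what a 0–90
  degree tilt scale requires. Static gravity is assumed to dominate each
  reading; no separation of linear acceleration is attempted.
* **Motor activity** is the angular displacement between consecutive
  orientation vectors (`arccos` of their normalized dot product, degrees per
  30 s). Summing these over 10-minute epochs gives the total angular path
  length, and dividing by 10 expresses it as degrees of position change per
  minute.

Temperature is sampled every 10 minutes; activity is *summed* and position
*averaged* onto that grid (half-open windows anchored at the first common
epoch). Artifact screening replaces temperature samples outside 25–40 °C, or
jumping by more than 2 °C per step from an unflagged sample, with missing
values — removal of the sensor exposes it to ambient temperature, which is
exactly this signature. The thresholds are package defaults, stated here
because the choice is otherwise open; they are parameters of
`artifact_rule()`.

Each signal is normalized per subject by its 5th and 95th percentiles over
the whole recording (linear interpolation between order statistics), clipped
to [0, 1]; temperature is inverted so that high values mean arousal in all
three channels. TAP is the equal-weight epoch mean of the three normalized
signals. Epochs with any missing component are missing by default, because a
two-of-three mean is a different variable; averaging the available
components is available as an option. Weights are configurable for
sensitivity analyses only.

## Non-parametric statistics and the CFI

With $p$ bins per day, $n$ used bins, bin-across-days means $\bar x_h$ and
grand mean $\bar x$:

$$IS = \frac{n \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2},
\qquad
IV = \frac{n \sum_{i\ge2} (x_i - x_{i-1})^2}{(n-1)\sum_i (x_i - \bar x)^2}.$$

IS is 0 for noise and 1 for a pattern repeating exactly day after day; IV is
near 0 for a smooth sinusoid (analytically $2(1-\cos(2\pi/p))$) and near 2
for white noise. Both are computed on hourly bins by default; the bin width
is exposed because it shifts third-decimal values. Missing bins are excluded
with the counts adjusted, and days with more than 30% missing bins are
dropped from the IS day means.

The mean 24-h waveform (bins anchored at midnight, day-level means averaged
across days with their SEM) is scanned circularly for the five consecutive
hours with the lowest values (L5, VL5) and the ten with the highest (M10,
VM10), at the native 10-minute resolution. On flat troughs or plateaus many
windows tie; the scan returns the window at the centre of the longest run of
tying starts. This keeps the timing estimate unbiased on square-wave-like
patterns (a rest phase over 00:00–08:00 yields L5 = 04:00, not the earliest
tying window at 02:30) while remaining fully deterministic. Relative
amplitude is $RA = (VM10 - VL5)/(VM10 + VL5)$, defined as 0 when both terms
are 0.

$$CFI = \tfrac13\left( IS + \mathrm{clip}(1 - IV/2,\,0,\,1) + RA \right)$$

maps 0 to absent rhythmicity and 1 to a robust rhythm. The IV term inverts
and normalizes IV using its two anchor points (2 for noise, 0 for a
sinusoid) and is clipped because IV can exceed 2 on real, alternating data.

## Rest/wake scoring and validation

A normalized signal is thresholded: values above the threshold score awake
(0), values at or below it rest (1). The boundary scores rest so that a
signal at 0 — complete rest by construction — is classified as rest even
with a zero threshold. Thresholds are calibrated by exhaustive scan of
[0, 1] in steps of 0.01, maximizing epoch agreement with the diary per
calibration subject (ties toward the lower threshold within the scan; the
final threshold averages the per-subject optima).

`confusion_stats()` treats rest as the positive class and reports
sensitivity TP/(TP+FN), specificity TN/(TN+FP) and agreement as overall
accuracy (TP+TN)/total. Verbal definitions of these rates in the applied
literature sometimes read as predictive values, so PPV and NPV are reported
alongside rather than silently substituting either convention. Pearson
chi-squared tests (no continuity correction), waveform Pearson correlations
and the Fisher r-to-z two-correlation comparison
$z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/\sqrt{1/(n_1-3)+1/(n_2-3)}$
support comparisons between variables; the correlation $n$ defaults to the
number of waveform bins actually used.

## What the simulator emulates

`sim_config()` fixes the generative conditions used throughout the tests:

* a **square** daily wave with the activity phase covering 66% of the day
  (rest ≈ 8.2 h placed at the start of the day, i.e. nocturnally for a
  midnight start), or a **sinusoid** with its minimum at the rest midpoint;
* **fractal (1/f) noise**, generated by spectral synthesis (amplitudes
  $\propto f^{-1/2}$, seeded uniform phases, inverse FFT, standardized),
  min-max matched to the base wave's peak-to-trough range and mixed in
  convexly at 0–100%, clipping to [0, 1]. The mixing percentage is the
  convex weight — the internal definition used by the original simulation
  software is unpublished, so the gradient is calibrated qualitatively, not
  to reproduce specific published panel values;
* **instability** of the rest-activity ratio: each day's phase boundaries
  jittered independently and uniformly within ±(pct/100)·24 h/2 (±2.4 h at
  20%), clamped against phase inversion. This keeps the mean activity
  fraction at its nominal value;
* 7 days at a 10-minute step, everything bit-reproducible from the seed.

`synth_subject()` turns the binary pattern into a full recording: wrist
temperature mapped to ≈ 31 °C awake / 35 °C at rest and *inverted* relative
to activity; activity scaled to ≈ 40 deg/min awake; position to 0–90°. Each
channel receives its own independent fractal mixture at the configured noise
percentage, plus channel noise representing sensor error *and behavioural
masking*: 1.0 °C on temperature and 15° on position, realized as slow 1/f
noise because masking events (ambient exposure, daytime recumbency) evolve
over tens of minutes, and white Gaussian noise of 8 deg/min on activity,
because movement is bursty. These magnitudes were chosen to reproduce the
well-documented ordering of single-channel reliability — temperature the
weakest rest/wake predictor, activity and position better, the fused TAP
best — which disappears if channel noise is set to bare sensor resolution.
Afternoon naps (probability 0.15/day, onset 15:00 ± 1 h, 40–90 min) enter
the ground truth and the diary alike; the diary reports the truth exactly.
What the generator does **not** emulate: ultradian sleep structure,
thermoregulatory dynamics, diary misreporting, and weekday/weekend
structure. Passing tests therefore demonstrate correctness of the statistics
and the internal consistency of the pipeline on masked, noisy, unstable
rhythms — not clinical performance on real cohorts.

## Numerical choices and degenerate inputs

* Percentile normalization errors on constant series (no span); IS and IV
  error on constant series (zero variance); the L5/M10 scan errors on
  waveforms with missing bins and on windows longer than a day.
* Mean-reduced resampling windows need ≥ 50% of samples; summed windows need
  all samples, since a partial sum is not defined up to scale. Trailing
  incomplete windows are dropped.
* Diary binarization uses the epoch midpoint with closed-left, open-right
  interval membership, an unambiguous boundary rule.
* Equality with the scoring threshold counts as rest.
* All timestamps are taken at face value in UTC; no daylight-saving
  handling.

## Problem sizes

The test-suite simulations use 7-day recordings at the 10-minute step
(1008 epochs), cohorts of up to 20 subjects, 200 days of hourly noise for
the white-noise limit of IS, $10^4$ samples for the IV limit, and
$2^{14}$-sample spectra for the 1/f slope check — sizes at which the
sampling error of every stochastic check is far below its assertion
tolerance, while the whole suite runs in seconds.

```{r example}
cfg <- sim_config(noise_pct = 30, seed = 1)
subject <- synth_subject(cfg)
tap <- build_tap(subject$recording)
npar_summary(tap$series)
```

## Known limitations

Real recordings start mid-day, contain wear gaps and diary omissions; the
alignment and missing-data rules cover these, but the defaults (artifact
thresholds, 30% missing-day rule) are package choices the user should revisit
for unusual populations. CFI weights its three components equally; no claim
is made that equal weights are optimal for any particular clinical contrast.
Parametric rhythm analysis (cosinor, periodogram) is deliberately out of
scope; only the Fisher r-to-z comparison utility is provided for relating
correlations.
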