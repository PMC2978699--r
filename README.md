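# circatap

Assessment of human circadian-system status from week-long ambulatory
recordings of wrist skin temperature, motor activity and body position.

Single overt rhythms are masked by behaviour: wrist temperature reacts to
ambient exposure, activity and position to volition. `circatap` fuses the
three simultaneous signals into the integrated **TAP** variable — the
epoch-wise mean of the per-subject percentile-normalized signals, with
temperature inverted so that 0 means complete rest and 1 high arousal — and
summarizes circadian robustness in one number, the **Circadian Function
Index**.

For a signal binned to *p* bins per day (*n* bins total, bin-across-days
means x̄ₕ, grand mean x̄), the non-parametric statistics are

    IS = n Σₕ (x̄ₕ − x̄)²  /  [ p Σᵢ (xᵢ − x̄)² ]          interdaily stability
    IV = n Σᵢ (xᵢ − xᵢ₋₁)²  /  [ (n−1) Σᵢ (xᵢ − x̄)² ]    intradaily variability
    RA = (VM10 − VL5) / (VM10 + VL5)                      relative amplitude

where VL5/VM10 are the mean levels of the lowest 5 and highest 10
consecutive hours of the mean 24-h waveform (timings L5, M10), and

    CFI = ( IS + clip(1 − IV/2, 0, 1) + RA ) / 3

ranges from 0 (no circadian rhythmicity) to 1 (robust rhythm).

The package covers the full chain: reading logger CSV exports; deriving
activity (inter-sample angular displacement) and position (X-axis elevation)
from raw three-axis 30-s accelerometry; artifact filtering and resampling to
the common 10-minute grid; TAP composition; IS/IV/RA/L5/M10/CFI; mean
waveforms; diary-calibrated rest/wake scoring with sensitivity, specificity,
agreement, chi-squared and correlation-comparison statistics; and a
simulator (square/sinusoidal patterns, 1/f fractal noise, rest-activity
instability, full synthetic subjects with ground truth) used to validate the
whole pipeline.

Intended users: chronobiologists and sleep researchers analysing wearable
temperature/actimetry data, and methodologists testing rest/wake scoring
algorithms against known ground truth.

## Worked example

Simulate one week-long subject (square rest-activity pattern, 30% fractal
noise plus behavioural masking noise), compute TAP and its circadian
summary, then calibrate a rest threshold against the diary and score:

```r
library(circatap)

cfg <- sim_config(noise_pct = 30, seed = 1)
subject <- synth_subject(cfg)
subject$recording
#> <subject_recording> subject S1: 1008 epochs of 10 min (7.0 days), diary with 9 rest intervals

tap <- build_tap(subject$recording)
npar_summary(tap$series)
#> <npar_summary> TAP
#>   IS = 0.936  IV = 0.364  RA = 0.638  CFI = 0.797
#>   L5 = 02:30 (VL5 = 0.168)   M10 = 15:20 (VM10 = 0.761)

fit <- calibrate_threshold(list(S1 = tap$series), list(subject$truth))
confusion_stats(score_rest(tap$series, fit$threshold), subject$truth)
#> <scoring_result> n = 1008 epochs (TP 355, FP 0, TN 652, FN 1)
#>   sensitivity = 0.997  specificity = 1.000  agreement = 0.999
#>   PPV = 1.000  NPV = 0.998
```

Reading the output: IS = 0.936 means the daily pattern repeats closely from
day to day; IV = 0.364 indicates little fragmentation (0 would be a smooth
sinusoid, 2 white noise); RA = 0.638 is the normalized day-night amplitude
of the mean waveform, whose lowest 5 hours centre at 02:30 — inside the
generative nocturnal rest phase — and highest 10 hours at 15:20. The CFI of
0.797 summarizes the three as a robust, mildly degraded rhythm (this
simulation mixes in 30% noise). The calibrated threshold then recovers the
generative rest/wake state with 99.9% epoch agreement.

A thin command-line front end is included for shell use:

```sh
Rscript inst/cli/circatap.R simulate --noise 30 --subjects 8 --seed 1 --out simdir
Rscript inst/cli/circatap.R score --dir simdir --calib-n 6 --seed 1 --out simdir
```

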