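Package: circatap
Title: Circadian Rhythm Assessment from Wrist Temperature, Motor Activity
    and Body Position Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to assess human circadian-system status from ambulatory
    wrist skin temperature, motor activity and body position recordings.
    Derives activity and position from raw three-axis accelerometer
    exports, filters artifacts, resamples to a common 10-minute grid,
    fuses the percentile-normalized signals into the integrated TAP
    variable, computes non-parametric circadian statistics (interdaily
    stability, intradaily variability, relative amplitude, L5/M10) and the
    Circadian Function Index (CFI), calibrates diary-based rest/wake
    scoring thresholds with sensitivity, specificity and agreement
    statistics, and simulates square or sinusoidal rest-activity patterns
    degraded by 1/f fractal noise and phase instability for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
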