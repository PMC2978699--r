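test_that("interdaily stability hits its analytic limits", {
  # perfectly repeating pattern: IS = 1 at any bin width
  set.seed(21)
  pat <- rnorm(24)
  s <- hourly_series(rep(pat, 7))
  expect_equal(interdaily_stability(s), 1)
  pat10 <- rnorm(144)
  expect_equal(interdaily_stability(tenmin_series(rep(pat10, 4)), bin_step = 600), 1)
  # long white noise: IS near 0 (expectation ~ 1/days)
  set.seed(22)
  w <- hourly_series(rnorm(200 * 24))
  expect_lt(interdaily_stability(w), 0.02)
  # affine invariance
  expect_equal(interdaily_stability(hourly_series(3 * rep(pat, 7) - 7)), 1)
  set.seed(23)
  x <- rnorm(7 * 24)
  expect_equal(interdaily_stability(hourly_series(x)),
               interdaily_stability(hourly_series(-2 * x + 5)))
  # degenerate inputs
  expect_error(interdaily_stability(hourly_series(rep(1, 48))), "constant")
  expect_error(interdaily_stability(hourly_series(rnorm(24))), "2 complete days")
})

test_that("signal-plus-noise IS matches the Monte-Carlo expectation", {
  # 7 days of a fixed unit-variance hourly pattern plus iid N(0,1) noise.
  # Frozen expectation 0.56007 (se 3e-4) from a 2e4-replicate brute-force
  # Monte-Carlo evaluation of the defining sums.
  set.seed(99)
  pat <- rnorm(24); pat <- (pat - mean(pat)) / sd(pat)
  vals <- replicate(400, {
    interdaily_stability(hourly_series(rep(pat, 7) + rnorm(168)))
  })
  expect_equal(mean(vals), 0.56007, tolerance = 0.02)
})

test_that("intradaily variability hits its analytic limits", {
  # iid Gaussian noise: IV near 2
  set.seed(31)
  g <- hourly_series(rnorm(1e4))
  expect_equal(intradaily_variability(g, 3600), 2, tolerance = 0.05)
  # smooth sinusoid: IV = 2(1 - cos(2 pi / p)) for p samples per cycle
  p <- 1440
  s1 <- eqseries(cos(2 * pi * (0:(7 * p - 1)) / p), "2024-01-01", 60)
  expect_equal(intradaily_variability(s1, 60), 2 * (1 - cos(2 * pi / p)),
               tolerance = 1e-3)
  sh <- hourly_series(cos(2 * pi * (0:(7 * 24 - 1)) / 24))
  expect_equal(intradaily_variability(sh, 3600), 2 * (1 - cos(2 * pi / 24)),
               tolerance = 0.01)          # closed form is the large-n limit
  # affine invariance and degenerate input
  set.seed(32)
  x <- rnorm(300)
  expect_equal(intradaily_variability(hourly_series(x)),
               intradaily_variability(hourly_series(5 * x - 2)))
  expect_error(intradaily_variability(hourly_series(rep(3, 10))), "constant")
})

test_that("IV of a constant-increment sawtooth matches the brute-force oracle", {
  x <- rep(c(1:12, 11:2), 4)              # 96 points, period 22
  s <- hourly_series(x)
  expect_equal(intradaily_variability(s), oracle_iv(x), tolerance = 1e-14)
})

test_that("mean waveforms average by time of day with across-day SEM", {
  set.seed(41)
  pat <- runif(144)
  s <- tenmin_series(rep(pat, 7))
  wf <- mean_waveform(s)
  expect_equal(wf$values, pat)
  expect_equal(wf$sem, rep(0, 144))
  expect_equal(wf$n_days, 7)
  # one day: the waveform is that day
  wf1 <- mean_waveform(tenmin_series(pat))
  expect_equal(wf1$values, pat)
  # two days at a and a + 2: mean a + 1, SEM 1
  wf2 <- mean_waveform(tenmin_series(c(pat, pat + 2)))
  expect_equal(wf2$values, pat + 1)
  expect_equal(wf2$sem, rep(1, 144))
  # binning within days first: hourly bins of a 10-min series
  wfh <- mean_waveform(s, bin_step = 3600)
  expect_equal(wfh$values, colMeans(matrix(pat, nrow = 6)))
})

test_that("waveforms anchor their bins at midnight clock time", {
  # series starting 06:00: bin 0 must still be 00:00-00:10
  pat <- sin(2 * pi * (0:143) / 144)
  s <- eqseries(rep(pat, 3), "2024-01-01 06:00:00", 600)
  wf <- mean_waveform(s)
  expect_equal(wf$values[37], pat[1])     # 06:00 sample lands in bin 36
  expect_equal(wf$bin_tod[1], 0)
})

test_that("L5/M10 window scans agree with geometry and the brute oracle", {
  # square day: 0 on 00:00-08:00, 1 afterwards
  sq <- c(rep(0, 48), rep(1, 96))
  wf <- mean_waveform(tenmin_series(sq))
  lm <- l5_m10(wf)
  expect_equal(lm$L5_mid, 4 * 3600)       # centre of the flat rest trough
  expect_equal(lm$VL5, 0)
  expect_equal(lm$M10_mid, 16 * 3600)     # centre of the activity plateau
  expect_equal(lm$VM10, 1)
  expect_equal(relative_amplitude(lm$VL5, lm$VM10), 1)
  # constant waveform: VL5 = VM10 = c, RA = 0
  wfc <- mean_waveform(tenmin_series(rep(3.5, 144)))
  lmc <- l5_m10(wfc)
  expect_equal(lmc$VL5, 3.5)
  expect_equal(lmc$VM10, 3.5)
  expect_equal(relative_amplitude(lmc$VL5, lmc$VM10), 0)
  # cosine with minimum at 04:00: symmetric L5 centred there
  tod <- (0:143) * 600 + 300
  cs <- 2 - cos(2 * pi * (tod - 4 * 3600) / 86400)
  lmcos <- l5_m10(mean_waveform(tenmin_series(cs)))
  expect_equal(lmcos$L5_mid, 4 * 3600)
  expect_equal(lmcos$M10_mid, (16 * 3600) %% 86400)
  # shifting the series by whole days leaves the windows unchanged
  s2 <- eqseries(rep(sq, 3), "2024-01-03 00:00:00", 600)
  expect_equal(l5_m10(mean_waveform(s2))$L5_mid, 4 * 3600)
  # window longer than a day is rejected
  expect_error(l5_m10(wf, high_hours = 25), "longer than one day")
})

test_that("relative amplitude follows its defining ratio", {
  expect_equal(relative_amplitude(0.25, 0.75), 0.5)
  expect_equal(relative_amplitude(0.4, 0.4), 0)
  expect_equal(relative_amplitude(0, 1), 1)
  expect_equal(relative_amplitude(0, 0), 0)
  expect_error(relative_amplitude(-0.1, 0.5), "non-negative")
  expect_error(relative_amplitude(0.6, 0.5), "at least")
})

test_that("CFI averages IS, inverted-normalized IV and RA", {
  expect_equal(circadian_function_index(1, 0, 1), 1)
  expect_equal(circadian_function_index(0, 2, 0), 0)
  expect_equal(circadian_function_index(0.6, 0.6, 0.6), (0.6 + 0.7 + 0.6) / 3)
  # IV beyond 2 is clipped, keeping CFI in [0, 1]
  expect_equal(circadian_function_index(0, 2.7, 0), 0)
  expect_error(circadian_function_index(1.2, 1, 0.5), "IS")
  expect_error(circadian_function_index(0.5, -1, 0.5), "IV")
  # monotone: increasing IS or RA raises CFI, increasing IV lowers it
  expect_gt(circadian_function_index(0.8, 1, 0.5),
            circadian_function_index(0.6, 1, 0.5))
  expect_gt(circadian_function_index(0.6, 1, 0.7),
            circadian_function_index(0.6, 1, 0.5))
  expect_lt(circadian_function_index(0.6, 1.5, 0.5),
            circadian_function_index(0.6, 1, 0.5))
})

test_that("the one-call summary reproduces its parts and formats a table", {
  s <- simulate_tap(sim_config(noise_pct = 20, seed = 3))
  np <- npar_summary(s)
  expect_equal(np$IS, interdaily_stability(s))
  expect_equal(np$IV, intradaily_variability(s, 3600))
  lm <- l5_m10(mean_waveform(s))
  expect_equal(np$VL5, lm$VL5)
  expect_equal(np$RA, relative_amplitude(lm$VL5, lm$VM10))
  expect_equal(np$CFI, circadian_function_index(min(np$IS, 1), np$IV, np$RA))
  tab <- npar_table(list(TAP = np))
  expect_named(tab, c("variable", "IS", "IV", "RA", "L5", "M10",
                      "VL5", "VM10", "CFI"))
  expect_match(tab$L5, "^\\d{2}:\\d{2}$")
  expect_equal(tod_hhmm(4 * 3600 + 30 * 60), "04:30")
})

test_that("group waveforms average subject waveforms bin-wise", {
  pat <- runif(144)
  w1 <- mean_waveform(tenmin_series(pat))
  w2 <- mean_waveform(tenmin_series(pat + 2))
  g <- group_waveform(list(w1, w2))
  expect_equal(g$values, pat + 1)
  expect_equal(g$sem, rep(1, 144))
})
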