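test_that("artifact filtering removes ambient-temperature runs and nothing else", {
  # sensor removed for 30 min: ambient 21 degC bracketed by physiological values
  v <- c(33.5, 34.2, 21.0, 21.1, 20.9, 34.8, 35.0)
  s <- tenmin_series(v)
  expect_message(f <- filter_artifacts(s), "3 of 7")
  expect_equal(is.na(es_values(f)), c(F, F, T, T, T, F, F), ignore_attr = TRUE)
  expect_equal(es_values(f)[c(1, 2, 6, 7)], v[c(1, 2, 6, 7)])

  # series fully inside physiological bounds with small jumps is untouched
  ok <- tenmin_series(c(33, 33.5, 34, 34.5, 34))
  expect_identical(es_values(filter_artifacts(ok)), es_values(ok))

  # constant series: nothing flagged
  const <- tenmin_series(rep(34, 10))
  expect_identical(es_values(filter_artifacts(const)), rep(34, 10))

  # everything flagged is an error naming the series
  bad <- tenmin_series(rep(10, 5))
  bad$label <- "subject 7 temperature"
  expect_error(filter_artifacts(bad), "subject 7 temperature")
})

test_that("resampling to 10 minutes sums activity and averages position", {
  t30 <- eqseries(rep(3, 20), "2024-01-01", 30, "activity")
  out <- resample_to_10min(t30, "sum")
  expect_equal(es_values(out), 60)
  expect_equal(out$step, 600)
  expect_equal(es_values(activity_per_minute(out)), 6)

  pos <- eqseries(rep(45, 20), "2024-01-01", 30, "position")
  expect_equal(es_values(resample_to_10min(pos, "mean")), 45)

  alt <- eqseries(rep(c(0, 90), 10), "2024-01-01", 30, "position")
  expect_equal(es_values(resample_to_10min(alt, "mean")), 45)

  # constant series: mean is the constant, sum is k * c per window
  const <- eqseries(rep(2.5, 60), "2024-01-01", 30)
  expect_equal(es_values(resample_to_10min(const, "mean")), rep(2.5, 3))
  expect_equal(es_values(resample_to_10min(const, "sum")), rep(20 * 2.5, 3))

  # non-divisor step is rejected
  expect_error(resample_to_10min(eqseries(1:10, "2024-01-01", 450), "mean"),
               "multiple")
})

test_that("partially missing windows follow the mean/sum missing policy", {
  v <- rep(1, 20)
  v[1:9] <- NA                              # 11/20 present: >= 50%
  expect_equal(es_values(resample_to_10min(eqseries(v, "2024-01-01", 30), "mean")), 1)
  v[1:11] <- NA                             # 9/20 present: < 50%
  expect_true(is.na(es_values(resample_to_10min(eqseries(v, "2024-01-01", 30), "mean"))))
  v <- rep(1, 20); v[3] <- NA               # sums need every sample
  expect_true(is.na(es_values(resample_to_10min(eqseries(v, "2024-01-01", 30), "sum"))))
  # missing propagates through the per-minute division
  expect_true(is.na(es_values(activity_per_minute(tenmin_series(NA_real_)))))
})

test_that("percentile normalization maps [p5, p95] onto [0, 1] with clipping", {
  set.seed(7)
  v <- runif(500, 28, 36)
  s <- tenmin_series(v)
  p <- quantile(v, c(0.05, 0.95), names = FALSE)
  z <- es_values(normalize_percentile(s))
  expect_true(all(z >= 0 & z <= 1))
  i5 <- which.min(abs(v - p[1]))
  expect_equal(z[i5], max((v[i5] - p[1]) / (p[2] - p[1]), 0))
  # exact boundary and midpoint mapping on a series with known percentiles
  w <- tenmin_series(c(p[1], (p[1] + p[2]) / 2, p[2], v))
  zw <- es_values(normalize_percentile(w))
  pw <- quantile(c(p[1], (p[1] + p[2]) / 2, p[2], v), c(0.05, 0.95), names = FALSE)
  expect_equal(zw[1:3], pmin(pmax((c(p[1], (p[1]+p[2])/2, p[2]) - pw[1]) / diff(pw), 0), 1))
  # inversion flips the scale
  zi <- es_values(normalize_percentile(s, invert = TRUE))
  expect_equal(zi, 1 - z)
  # re-normalizing an already clipped series keeps values in [0, 1]
  z2 <- es_values(normalize_percentile(normalize_percentile(s)))
  expect_true(all(z2 >= 0 & z2 <= 1))
  # a constant series has no percentile span
  expect_error(normalize_percentile(tenmin_series(rep(34, 10))), "constant")
})

test_that("diary binarization uses closed-left midpoint membership", {
  grid <- tenmin_series(rep(0, 144))        # one day from midnight
  d <- rest_diary("2024-01-01 00:00:00", "2024-01-01 08:00:00", "S1")
  b <- diary_to_binary(d, grid)
  expect_true(all(es_values(b) %in% c(0, 1)))
  # epoch 03:00-03:10 (midpoint 03:05) rests; 12:00-12:10 does not
  expect_equal(es_values(b)[19], 1)
  expect_equal(es_values(b)[73], 0)
  # midpoint exactly at rest onset counts as rest
  d2 <- rest_diary("2024-01-01 10:05:00", "2024-01-01 11:00:00", "S1")
  b2 <- diary_to_binary(d2, grid)
  expect_equal(es_values(b2)[61], 1)        # epoch 10:00-10:10, midpoint 10:05
  # total rest duration is recovered to within one epoch per boundary
  expect_equal(sum(es_values(b)) * 600, 8 * 3600, tolerance = 600 / (8 * 3600))
  # empty diary warns and returns all-zero
  expect_warning(b0 <- diary_to_binary(rest_diary(c(), c(), "S1"), grid), "empty")
  expect_equal(sum(es_values(b0)), 0)
})

test_that("diary validation and binary round trip hold", {
  expect_error(rest_diary("2024-01-01 08:00", "2024-01-01 07:00"), "after")
  expect_error(rest_diary(c("2024-01-01 00:00", "2024-01-01 05:00"),
                          c("2024-01-01 06:00", "2024-01-01 09:00")), "overlap")
  grid <- tenmin_series(rep(0, 288))
  d <- rest_diary(c("2024-01-01 00:00:00", "2024-01-01 23:00:00"),
                  c("2024-01-01 08:00:00", "2024-01-02 07:00:00"), "S9")
  b <- diary_to_binary(d, grid)
  d2 <- binary_to_diary(b, "S9")
  expect_equal(as.numeric(d2$rest_onset), as.numeric(d$rest_onset))
  expect_equal(as.numeric(d2$rest_offset), as.numeric(d$rest_offset))
})

test_that("subject recordings enforce a shared 600 s grid and value ranges", {
  t <- tenmin_series(rep(34, 10)); a <- tenmin_series(rep(5, 10))
  p <- tenmin_series(rep(45, 10))
  rec <- subject_recording("S1", t, a, p)
  expect_s3_class(rec, "subject_recording")
  expect_error(subject_recording("S1", t, a, tenmin_series(rep(45, 9))), "share")
  expect_error(subject_recording("S1", t, a, tenmin_series(rep(95, 10))), "90")
  expect_error(subject_recording("S1", t, tenmin_series(rep(-2, 10)), p),
               "non-negative")
})
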