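# Independent brute-force oracles: plain-loop evaluations of the defining
# sums and window scans, kept free of any package internals.

oracle_is <- function(x, p) {
  d <- length(x) %/% p
  x <- x[seq_len(d * p)]
  xbar <- mean(x)
  hbar <- vapply(seq_len(p), function(h) mean(x[seq(h, d * p, by = p)]), 1)
  (length(x) * sum((hbar - xbar)^2)) / (p * sum((x - xbar)^2))
}

oracle_iv <- function(x) {
  n <- length(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  (n * num) / ((n - 1) * sum((x - mean(x))^2))
}

# circular window scan over a 24-h profile; returns start index (0-based),
# window mean at the optimum, earliest start on ties
oracle_scan <- function(v, w, maximize) {
  p <- length(v)
  best_s <- 0L
  best_m <- mean(v[((0 + 0:(w - 1)) %% p) + 1])
  for (s in 1:(p - 1)) {
    m <- mean(v[((s + 0:(w - 1)) %% p) + 1])
    if ((maximize && m > best_m + 1e-15) || (!maximize && m < best_m - 1e-15)) {
      best_s <- s
      best_m <- m
    }
  }
  list(start = best_s, mean = best_m)
}

hourly_series <- function(values, start = "2024-01-01 00:00:00") {
  eqseries(values, start, 3600, "test signal")
}

tenmin_series <- function(values, start = "2024-01-01 00:00:00") {
  eqseries(values, start, 600, "test signal")
}

# normalized components + TAP for one synthetic subject
subject_components <- function(sub) {
  r <- sub$recording
  list(T = normalize_percentile(r$temperature, invert = TRUE),
       A = normalize_percentile(r$activity),
       P = normalize_percentile(r$position),
       TAP = build_tap(r)$series)
}
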