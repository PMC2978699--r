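## Non-parametric circadian statistics. IS and IV follow the standard
## rest-activity analysis sums; the exact bin width is exposed because it
## shifts third-decimal values (hourly bins are the conventional default,
## the native 10-min grid is used for the L5/M10 window scans).

## aggregate onto a coarser grid by window means (>= 50% of samples present)
bin_series <- function(series, bin_step) {
  stopifnot(inherits(series, "eqseries"))
  if (bin_step == series$step) return(series)
  if (bin_step < series$step)
    stop("bin_step must not be finer than the series step")
  resample_to_10min(series, "mean", out_step = bin_step)
}

## day x bin matrix of whole days, dropping a trailing partial day;
## days with > max_missing fraction of missing bins are dropped entirely
day_matrix <- function(x, p, max_missing = 0.3) {
  d <- length(x) %/% p
  if (d < 1L) stop("series shorter than one day")
  m <- matrix(x[seq_len(d * p)], nrow = d, ncol = p, byrow = TRUE)
  keep <- rowMeans(is.na(m)) <= max_missing
  m[keep, , drop = FALSE]
}

#' Interdaily stability (IS)
#'
#' Day-to-day constancy of the 24-h pattern: the variance of the mean daily
#' profile relative to the total variance,
#' \deqn{IS = \frac{n \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2}}
#' with p bins per day, n used samples and \eqn{\bar x_h} the across-day mean
#' of bin h. IS is 0 for Gaussian noise and 1 for a pattern that repeats
#' itself exactly day after day; it is invariant to affine rescaling of the
#' signal. Missing bins are excluded with n adjusted; days with more than 30%
#' missing bins are dropped.
#'
#' @param series an `eqseries` spanning at least 2 days.
#' @param bin_step bin width in seconds (default 3600); must divide 86400 and
#'   be a multiple of the series step.
#' @return IS, unitless in [0, 1] (up to sampling noise).
#' @export
interdaily_stability <- function(series, bin_step = 3600) {
  b <- bin_series(series, bin_step)
  p <- 86400 / bin_step
  if (abs(p - round(p)) > 1e-9) stop("bin_step must divide 86400 s")
  p <- as.integer(round(p))
  m <- day_matrix(b$values, p)
  if (nrow(m) < 2L) stop("interdaily stability needs at least 2 complete days")
  x <- m[!is.na(m)]
  n <- length(x)
  xbar <- mean(x)
  hbar <- colMeans(m, na.rm = TRUE)
  hbar <- hbar[is.finite(hbar)]
  ss_tot <- sum((x - xbar)^2)
  if (ss_tot == 0) stop("constant series: interdaily stability undefined")
  n * sum((hbar - xbar)^2) / (length(hbar) * ss_tot)
}

#' Intradaily variability (IV)
#'
#' Fragmentation of the rhythm: the mean-square successive difference
#' relative to the variance,
#' \deqn{IV = \frac{n \sum_{i \ge 2} (x_i - x_{i-1})^2}{(n - 1) \sum_i (x_i - \bar x)^2}.}
#' IV is near 0 for a smooth sinusoid (analytically \eqn{2(1 - \cos(2\pi/p))}
#' for p samples per cycle) and near 2 for Gaussian white noise; values above
#' 2 occur for alternating signals. Pairs with a missing member are excluded
#' with the counts adjusted.
#'
#' @param series an `eqseries`.
#' @param bin_step bin width in seconds; defaults to the native step
#'   (no binning). Hourly binning (`3600`) is the conventional choice.
#' @return IV, unitless, >= 0.
#' @export
intradaily_variability <- function(series, bin_step = NULL) {
  if (is.null(bin_step)) bin_step <- series$step
  b <- bin_series(series, bin_step)
  x <- b$values
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2L) stop("intradaily variability needs at least 2 bins")
  xbar <- mean(x[ok])
  ss_tot <- sum((x[ok] - xbar)^2)
  if (ss_tot == 0) stop("constant series: intradaily variability undefined")
  d <- diff(x)
  d <- d[!is.na(d)]
  n * sum(d^2) / ((n - 1) * ss_tot)
}

#' Mean 24-h waveform
#'
#' Averages the signal by time of day: samples are assigned to bins anchored
#' at midnight, averaged within each day, then averaged across days; the SEM
#' across days is kept per bin.
#'
#' @param series an `eqseries` spanning at least 1 day.
#' @param bin_step bin width in seconds; defaults to the native step.
#' @return An object of class `mean_waveform`: list with `values` and `sem`
#'   (one per bin), `bin_step`, `n_days` and `bin_tod` (bin start, seconds
#'   after midnight).
#' @export
mean_waveform <- function(series, bin_step = NULL) {
  stopifnot(inherits(series, "eqseries"))
  if (is.null(bin_step)) bin_step <- series$step
  p <- 86400 / bin_step
  if (abs(p - round(p)) > 1e-9) stop("bin_step must divide 86400 s")
  p <- as.integer(round(p))
  t <- as.numeric(es_times(series))
  bin <- floor((t %% 86400) / bin_step)          # 0-based time-of-day bin
  day <- floor(t / 86400)
  day <- day - min(day)
  v <- series$values
  # day-level bin means, then statistics across days
  day_means <- tapply(v, list(day = day, bin = bin), mean, na.rm = TRUE)
  vals <- sem <- rep(NA_real_, p)
  have <- as.integer(colnames(day_means))
  for (j in seq_along(have)) {
    col <- day_means[, j]
    col <- col[is.finite(col)]
    if (length(col)) {
      vals[have[j] + 1L] <- mean(col)
      sem[have[j] + 1L] <- if (length(col) > 1L)
        stats::sd(col) / sqrt(length(col)) else 0
    }
  }
  structure(list(values = vals, sem = sem, bin_step = bin_step,
                 n_days = length(unique(day)), bin_tod = (0:(p - 1L)) * bin_step,
                 label = series$label),
            class = "mean_waveform")
}

#' Average several waveforms (group-level waveform)
#'
#' Bin-wise mean across subjects' waveforms with the SEM across subjects.
#'
#' @param waveforms list of `mean_waveform` objects on a common bin grid.
#' @return A `mean_waveform` with `n_days` set to the number of subjects.
#' @export
group_waveform <- function(waveforms) {
  stopifnot(length(waveforms) >= 1L,
            all(vapply(waveforms, inherits, TRUE, "mean_waveform")))
  bs <- vapply(waveforms, function(w) w$bin_step, 1)
  if (length(unique(bs)) != 1L) stop("waveforms are on different bin grids")
  m <- do.call(rbind, lapply(waveforms, function(w) w$values))
  nsub <- colSums(!is.na(m))
  structure(list(values = colMeans(m, na.rm = TRUE),
                 sem = apply(m, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(nsub, 1)),
                 bin_step = bs[1L], n_days = length(waveforms),
                 bin_tod = waveforms[[1L]]$bin_tod, label = "group"),
            class = "mean_waveform")
}

#' @export
print.mean_waveform <- function(x, ...) {
  cat(sprintf("<mean_waveform> %s: %d bins of %gs over %d days\n",
              x$label, length(x$values), x$bin_step, x$n_days))
  invisible(x)
}

#' L5 and M10: extreme windows of the mean waveform
#'
#' Scans every circular window of `low_hours` (default 5) consecutive hours
#' for the lowest mean value (VL5, midpoint time L5) and of `high_hours`
#' (default 10) hours for the highest (VM10, M10), wrapping across midnight.
#' When several windows tie (a flat trough or plateau), the window at the
#' centre of the longest run of tying starts wins: on a square day with rest
#' over 00:00-08:00 this places L5 at 04:00 instead of biasing it early.
#'
#' @param waveform a [mean_waveform()] covering 24 h with no missing bins.
#' @param low_hours,high_hours window lengths in hours.
#' @return List with `L5_mid` and `M10_mid` (seconds after midnight of the
#'   window midpoint), `VL5`, `VM10` (window means in series units).
#' @export
l5_m10 <- function(waveform, low_hours = 5, high_hours = 10) {
  stopifnot(inherits(waveform, "mean_waveform"))
  v <- waveform$values
  if (anyNA(v)) stop("waveform has missing bins; L5/M10 scan undefined")
  p <- length(v)
  win <- function(hours) {
    w <- hours * 3600 / waveform$bin_step
    if (abs(w - round(w)) > 1e-9) stop("window is not a whole number of bins")
    w <- as.integer(round(w))
    if (w > p) stop("window longer than one day")
    means <- vapply(0:(p - 1L), function(s) {
      mean(v[((s + 0:(w - 1L)) %% p) + 1L])
    }, 1)
    list(means = means, w = w)
  }
  # centre of the longest circular run of window starts tying the optimum
  pick <- function(means, maximize) {
    opt <- if (maximize) max(means) else min(means)
    tie <- abs(means - opt) <= 1e-12 * max(1, abs(opt))
    if (sum(tie) == 1L) return(which(tie) - 1L)
    if (all(tie)) return(as.integer(floor(p / 2)))
    ext <- rep(tie, 2L)                   # unwrap the circle
    r <- rle(ext)
    ends <- cumsum(r$lengths)
    runs <- which(r$values & r$lengths <= p)
    best <- runs[which.max(r$lengths[runs])]
    mid_idx <- ends[best] - (r$lengths[best] - 1L) %/% 2L - 1L  # 0-based
    mid_idx %% p
  }
  lo <- win(low_hours); hi <- win(high_hours)
  s_lo <- pick(lo$means, FALSE)
  s_hi <- pick(hi$means, TRUE)
  mid <- function(s, w) ((s * waveform$bin_step) + w * waveform$bin_step / 2) %% 86400
  list(L5_mid = mid(s_lo, lo$w), VL5 = lo$means[s_lo + 1L],
       M10_mid = mid(s_hi, hi$w), VM10 = hi$means[s_hi + 1L])
}

#' Relative amplitude (RA)
#'
#' `(VM10 - VL5) / (VM10 + VL5)`: the normalized amplitude of the mean 24-h
#' waveform, 0 when the extreme windows coincide and 1 when the lowest 5 h
#' average exactly 0. Defined as 0 when both inputs are 0.
#'
#' @param VL5,VM10 window means from [l5_m10()], non-negative with
#'   `VM10 >= VL5`.
#' @return RA, unitless in [0, 1].
#' @export
relative_amplitude <- function(VL5, VM10) {
  if (VL5 < 0 || VM10 < 0) stop("VL5 and VM10 must be non-negative")
  if (VM10 < VL5) stop("VM10 must be at least VL5")
  if (VM10 + VL5 == 0) return(0)
  (VM10 - VL5) / (VM10 + VL5)
}

#' Circadian Function Index (CFI)
#'
#' The average of interdaily stability, inverted-normalized intradaily
#' variability and relative amplitude:
#' `CFI = (IS + clip(1 - IV/2, 0, 1) + RA) / 3`. The IV term maps 2 (noise)
#' to 0 and 0 (perfect sinusoid) to 1, clipped because IV can exceed 2 on
#' real data. CFI is 0 for absent circadian rhythmicity and 1 for a robust
#' rhythm.
#'
#' @param IS interdaily stability in [0, 1].
#' @param IV intradaily variability, >= 0.
#' @param RA relative amplitude in [0, 1].
#' @return CFI, unitless in [0, 1].
#' @export
circadian_function_index <- function(IS, IV, RA) {
  tol <- 1e-9
  if (IS < -tol || IS > 1 + tol) stop("IS must lie in [0, 1]")
  if (RA < -tol || RA > 1 + tol) stop("RA must lie in [0, 1]")
  if (IV < 0) stop("IV must be non-negative")
  (min(max(IS, 0), 1) + min(max(1 - IV / 2, 0), 1) + min(max(RA, 0), 1)) / 3
}

#' Non-parametric circadian summary of one series
#'
#' Computes IS and IV (hourly bins by default), the mean waveform at the
#' native step, the L5/M10 window scan, RA and CFI in one call.
#'
#' @param series an `eqseries` spanning at least 2 days.
#' @param is_iv_bin_step bin width for IS/IV in seconds (default 3600).
#' @param waveform_bin_step bin width for the waveform and L5/M10 scan;
#'   defaults to the native step.
#' @return An object of class `npar_summary` with fields `IS`, `IV`, `RA`,
#'   `L5_mid`, `VL5`, `M10_mid`, `VM10`, `CFI` and the `waveform`.
#' @export
npar_summary <- function(series, is_iv_bin_step = 3600,
                         waveform_bin_step = NULL) {
  IS <- interdaily_stability(series, is_iv_bin_step)
  IV <- intradaily_variability(series, is_iv_bin_step)
  wf <- mean_waveform(series, waveform_bin_step)
  lm <- l5_m10(wf)
  RA <- relative_amplitude(lm$VL5, lm$VM10)
  structure(list(IS = IS, IV = IV, RA = RA,
                 L5_mid = lm$L5_mid, VL5 = lm$VL5,
                 M10_mid = lm$M10_mid, VM10 = lm$VM10,
                 CFI = circadian_function_index(min(IS, 1), IV, RA),
                 waveform = wf, label = series$label),
            class = "npar_summary")
}

#' Format seconds after midnight as hh:mm
#' @param tod seconds after midnight.
#' @return character vector like `"04:30"`.
#' @export
tod_hhmm <- function(tod) {
  tod <- round(tod) %% 86400
  sprintf("%02d:%02d", tod %/% 3600, (tod %% 3600) %/% 60)
}

#' @export
print.npar_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<npar_summary> %s\n", x$label))
  cat(sprintf("  IS = %.*f  IV = %.*f  RA = %.*f  CFI = %.*f\n",
              digits, x$IS, digits, x$IV, digits, x$RA, digits, x$CFI))
  cat(sprintf("  L5 = %s (VL5 = %.*f)   M10 = %s (VM10 = %.*f)\n",
              tod_hhmm(x$L5_mid), digits, x$VL5,
              tod_hhmm(x$M10_mid), digits, x$VM10))
  invisible(x)
}

#' Tabulate non-parametric summaries
#'
#' One row per summary, in the conventional reporting layout
#' (`variable, IS, IV, RA, L5, M10, VL5, VM10, CFI`, clock times as hh:mm).
#'
#' @param summaries a named list of `npar_summary` objects.
#' @param path optional file path; when given the table is written as TSV.
#' @return The data frame, invisibly when written.
#' @export
npar_table <- function(summaries, path = NULL) {
  if (inherits(summaries, "npar_summary")) summaries <- list(summaries)
  nm <- names(summaries)
  if (is.null(nm)) nm <- vapply(summaries, function(s) s$label, "")
  d <- data.frame(variable = nm,
                  IS = vapply(summaries, function(s) s$IS, 1),
                  IV = vapply(summaries, function(s) s$IV, 1),
                  RA = vapply(summaries, function(s) s$RA, 1),
                  L5 = tod_hhmm(vapply(summaries, function(s) s$L5_mid, 1)),
                  M10 = tod_hhmm(vapply(summaries, function(s) s$M10_mid, 1)),
                  VL5 = vapply(summaries, function(s) s$VL5, 1),
                  VM10 = vapply(summaries, function(s) s$VM10, 1),
                  CFI = vapply(summaries, function(s) s$CFI, 1))
  if (!is.null(path)) {
    utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(d))
  }
  d
}
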