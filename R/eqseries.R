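#' Equispaced time series
#'
#' Lightweight container for a regularly sampled scalar signal: a numeric
#' vector plus a start time and a constant step. Missing samples are `NA`,
#' never dropped, so index arithmetic (and hence alignment across sensors)
#' stays valid. All timestamps are taken at face value in UTC; no daylight
#' saving adjustment is performed.
#'
#' @param values numeric vector, length >= 1; `NA` marks missing samples.
#' @param start_time timestamp of the first sample (coerced to POSIXct, UTC).
#' @param step sampling interval in seconds (> 0).
#' @param label free-text description, e.g. `"wrist temperature (degC)"`.
#' @return An object of class `eqseries`.
#' @examples
#' x <- eqseries(rnorm(144), "2024-01-01 00:00:00", 600, "demo")
#' length(x)
#' @export
eqseries <- function(values, start_time, step, label = "") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector")
  step <- as.numeric(step)
  if (!is.finite(step) || step <= 0) stop("'step' must be a positive number of seconds")
  start_time <- as.POSIXct(start_time, tz = "UTC")
  if (is.na(start_time)) stop("'start_time' could not be parsed")
  structure(list(values = as.numeric(values),
                 start_time = start_time,
                 step = step,
                 label = as.character(label)[1L]),
            class = "eqseries")
}

#' @export
length.eqseries <- function(x) length(x$values)

#' Sample values of an equispaced series
#' @param x an `eqseries` object.
#' @return numeric vector of sample values (`NA` = missing).
#' @export
es_values <- function(x) {
  stopifnot(inherits(x, "eqseries"))
  x$values
}

#' Timestamps of an equispaced series
#' @param x an `eqseries` object.
#' @return POSIXct vector `start_time + (i - 1) * step`.
#' @export
es_times <- function(x) {
  stopifnot(inherits(x, "eqseries"))
  x$start_time + (seq_along(x$values) - 1) * x$step
}

## seconds since midnight (UTC) for each sample
es_tod <- function(x) as.numeric(es_times(x)) %% 86400

#' @export
print.eqseries <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eqseries> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  n = %d, step = %gs, start = %s UTC\n", length(v), x$step,
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  cat(sprintf("  range = [%g, %g], missing = %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

## grids are equal when start, step and length all match (to the second)
same_grid <- function(a, b) {
  inherits(a, "eqseries") && inherits(b, "eqseries") &&
    abs(as.numeric(a$start_time) - as.numeric(b$start_time)) < 1e-6 &&
    a$step == b$step && length(a$values) == length(b$values)
}

#' Rest diary
#'
#' Declared rest intervals for one subject: chronologically ordered,
#' non-overlapping `[onset, offset)` pairs.
#'
#' @param onset,offset POSIXct (or parseable) vectors of equal length;
#'   each `offset` must exceed its `onset`.
#' @param subject_id subject identifier.
#' @return An object of class `rest_diary` (a data frame with columns
#'   `rest_onset`, `rest_offset` and attribute `subject_id`).
#' @export
rest_diary <- function(onset, offset, subject_id = "") {
  onset <- as.POSIXct(onset, tz = "UTC")
  offset <- as.POSIXct(offset, tz = "UTC")
  if (length(onset) != length(offset)) stop("onset/offset length mismatch")
  if (length(onset)) {
    if (any(offset <= onset)) stop("every rest_offset must be after its rest_onset")
    o <- order(onset)
    onset <- onset[o]; offset <- offset[o]
    if (length(onset) > 1L && any(onset[-1L] < offset[-length(offset)]))
      stop("rest intervals overlap")
  }
  structure(data.frame(rest_onset = onset, rest_offset = offset),
            subject_id = as.character(subject_id)[1L],
            class = c("rest_diary", "data.frame"))
}

#' Aligned multi-sensor recording for one subject
#'
#' Bundles the three 10-minute series (temperature in degC, motor activity in
#' degrees/min, body position in degrees in [0, 90]) and an optional rest
#' diary. The three series must share start time, step (600 s) and length.
#'
#' @param subject_id subject identifier.
#' @param temperature,activity,position `eqseries` on a common 600 s grid.
#' @param diary optional `rest_diary`.
#' @return An object of class `subject_recording`.
#' @export
subject_recording <- function(subject_id, temperature, activity, position,
                              diary = NULL) {
  stopifnot(inherits(temperature, "eqseries"), inherits(activity, "eqseries"),
            inherits(position, "eqseries"))
  if (temperature$step != 600) stop("recording series must be on a 600 s grid")
  if (!same_grid(temperature, activity) || !same_grid(temperature, position))
    stop("temperature, activity and position must share start time, step and length")
  pv <- position$values
  if (any(pv < -1e-9 | pv > 90 + 1e-9, na.rm = TRUE))
    stop("position values must lie in [0, 90] degrees")
  if (any(activity$values < -1e-9, na.rm = TRUE))
    stop("activity values must be non-negative")
  if (!is.null(diary) && !inherits(diary, "rest_diary"))
    stop("'diary' must be a rest_diary or NULL")
  structure(list(subject_id = as.character(subject_id)[1L],
                 temperature = temperature, activity = activity,
                 position = position, diary = diary),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> subject %s: %d epochs of 10 min (%.1f days)%s\n",
              x$subject_id, length(x$temperature),
              length(x$temperature) * 600 / 86400,
              if (is.null(x$diary)) ", no diary"
              else sprintf(", diary with %d rest intervals", nrow(x$diary))))
  invisible(x)
}

#' Artifact-detection rule
#'
#' Flags physiologically impossible samples. The default temperature rule
#' marks samples outside [25, 40] degC and samples whose absolute change from
#' the previous sample exceeds 2 degC per step: removing the sensor exposes it
#' to ambient temperature, which shows up as an out-of-range run entered and
#' left by a large jump.
#'
#' @param lower,upper admissible physical bounds (inclusive); `NA` disables.
#' @param max_jump largest admissible absolute first difference; `NA` disables.
#' @return An object of class `artifact_rule`.
#' @export
artifact_rule <- function(lower = 25, upper = 40, max_jump = 2) {
  structure(list(lower = lower, upper = upper, max_jump = max_jump),
            class = "artifact_rule")
}

#' Replace artifact samples by missing values
#'
#' Screens a series with an [artifact_rule()] and replaces flagged samples by
#' `NA`, keeping the grid intact. The number of flagged samples is reported
#' with `message()`.
#'
#' @param series an `eqseries`.
#' @param rule an [artifact_rule()].
#' @return The series with flagged samples set to `NA`.
#' @export
filter_artifacts <- function(series, rule = artifact_rule()) {
  stopifnot(inherits(series, "eqseries"), inherits(rule, "artifact_rule"))
  v <- series$values
  flag <- rep(FALSE, length(v))
  if (!is.na(rule$lower)) flag <- flag | (!is.na(v) & v < rule$lower)
  if (!is.na(rule$upper)) flag <- flag | (!is.na(v) & v > rule$upper)
  if (!is.na(rule$max_jump) && length(v) > 1L) {
    d <- abs(diff(v))
    # the sample that jumped away is the suspect; a jump back from an already
    # flagged sample is recovery, not a new artifact
    jump <- !is.na(d) & d > rule$max_jump & !flag[-length(v)]
    flag[-1L][jump] <- TRUE
  }
  if (all(flag | is.na(v)))
    stop(sprintf("all samples of series '%s' flagged as artifacts", series$label))
  if (any(flag))
    message(sprintf("filter_artifacts: %d of %d samples flagged in '%s'",
                    sum(flag), length(v), series$label))
  v[flag] <- NA_real_
  out <- series
  out$values <- v
  out
}

#' Aggregate a series onto the common 10-minute grid
#'
#' Reduces consecutive windows of source samples to one value per 10 minutes,
#' the sampling rate of the temperature logger. Motor activity is summed
#' (total angular displacement per epoch); body position is averaged. Windows
#' are half-open `[t, t + 600)`, anchored at the series start; a trailing
#' incomplete window is dropped. A mean-reduced window with at least 50% of
#' its samples present uses the available samples; a sum-reduced window
#' requires all samples (a partial sum is not defined up to scale).
#'
#' @param series an `eqseries` whose step divides 600 s.
#' @param reducer `"mean"` or `"sum"`.
#' @param out_step output step in seconds (default 600).
#' @return An `eqseries` with `step = out_step`.
#' @export
resample_to_10min <- function(series, reducer = c("mean", "sum"),
                              out_step = 600) {
  stopifnot(inherits(series, "eqseries"))
  reducer <- match.arg(reducer)
  k <- out_step / series$step
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop(sprintf("output step %gs is not an integer multiple of series step %gs",
                 out_step, series$step))
  k <- as.integer(round(k))
  n_out <- length(series$values) %/% k
  if (n_out < 1L) stop("series shorter than one output window")
  m <- matrix(series$values[seq_len(n_out * k)], nrow = k)
  n_ok <- colSums(!is.na(m))
  out <- if (reducer == "sum") {
    ifelse(n_ok == k, colSums(m, na.rm = TRUE), NA_real_)
  } else {
    ifelse(n_ok >= k / 2, colMeans(m, na.rm = TRUE), NA_real_)
  }
  eqseries(out, series$start_time, out_step, series$label)
}

#' Express summed activity as degrees of position change per minute
#'
#' Divides each 10-minute angular-displacement sum by 10.
#'
#' @param summed an `eqseries` of per-10-min summed activity (degrees).
#' @return An `eqseries` in degrees/min.
#' @export
activity_per_minute <- function(summed) {
  stopifnot(inherits(summed, "eqseries"))
  out <- summed
  out$values <- summed$values / 10
  out$label <- "motor activity (deg/min)"
  out
}

#' Percentile normalization of a signal
#'
#' Maps a series onto [0, 1] using the subject's own 5th and 95th percentiles
#' computed over the whole recording (linear interpolation between order
#' statistics), clipping values beyond the percentiles so downstream fusion
#' stays on [0, 1]. Wrist temperature is high during rest, opposite to
#' activity and position, so it is inverted (`invert = TRUE`) before fusion.
#'
#' @param series an `eqseries` with at least two distinct non-missing values.
#' @param low_pct,high_pct percentile bounds (defaults 5 and 95).
#' @param invert if `TRUE` return `1 - normalized(x)`.
#' @return An `eqseries` with values in [0, 1].
#' @export
normalize_percentile <- function(series, low_pct = 5, high_pct = 95,
                                 invert = FALSE) {
  stopifnot(inherits(series, "eqseries"))
  v <- series$values
  if (sum(!is.na(v)) < 2L) stop("need at least two non-missing values")
  p <- stats::quantile(v, c(low_pct, high_pct) / 100, na.rm = TRUE,
                       names = FALSE, type = 7)
  if (p[2L] <= p[1L])
    stop(sprintf("series '%s' is constant between the %g and %g percentiles",
                 series$label, low_pct, high_pct))
  z <- pmin(pmax((v - p[1L]) / (p[2L] - p[1L]), 0), 1)
  if (invert) z <- 1 - z
  out <- series
  out$values <- z
  out$label <- paste0(series$label, if (invert) " (normalized, inverted)"
                      else " (normalized)")
  out
}

#' Binarize a rest diary onto a sampling grid
#'
#' One value per grid epoch: 1 when the epoch midpoint falls inside a declared
#' rest interval (closed-left, open-right: `onset <= midpoint < offset`),
#' else 0.
#'
#' @param diary a [rest_diary()].
#' @param grid an `eqseries` supplying the epoch grid.
#' @return An `eqseries` of 0/1 values on the same grid.
#' @export
diary_to_binary <- function(diary, grid) {
  stopifnot(inherits(diary, "rest_diary"), inherits(grid, "eqseries"))
  mid <- as.numeric(es_times(grid)) + grid$step / 2
  out <- numeric(length(mid))
  if (nrow(diary) == 0L) {
    warning("empty diary: returning an all-zero rest series")
  } else {
    for (i in seq_len(nrow(diary))) {
      out[mid >= as.numeric(diary$rest_onset[i]) &
            mid < as.numeric(diary$rest_offset[i])] <- 1
    }
  }
  eqseries(out, grid$start_time, grid$step,
           paste0("diary rest (", attr(diary, "subject_id"), ")"))
}

#' Recover rest intervals from a binary series
#'
#' Inverse of [diary_to_binary()]: maximal runs of 1 become intervals
#' `[epoch_start, last_epoch_start + step)`.
#'
#' @param binary an `eqseries` of 0/1 values (`NA` treated as 0).
#' @param subject_id subject identifier for the resulting diary.
#' @return A [rest_diary()].
#' @export
binary_to_diary <- function(binary, subject_id = "") {
  stopifnot(inherits(binary, "eqseries"))
  v <- ifelse(is.na(binary$values), 0, binary$values)
  r <- rle(v == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  t0 <- as.numeric(binary$start_time)
  rest_diary(onset = as.POSIXct(t0 + (starts[keep] - 1L) * binary$step,
                                tz = "UTC", origin = "1970-01-01"),
             offset = as.POSIXct(t0 + ends[keep] * binary$step,
                                 tz = "UTC", origin = "1970-01-01"),
             subject_id = subject_id)
}
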