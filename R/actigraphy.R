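## Derivation of motor activity (A) and body position (P) from the 30-s
## three-axis logger samples. The logger is worn on the upper arm with its
## X-axis parallel to the humerus, so static gravity on each reading gives the
## arm's tilt: P is the unsigned elevation of the device X-axis over the
## horizontal plane (0 deg lying flat, 90 deg upright), and A is the angular
## displacement of the orientation vector between consecutive readings.

deg <- function(rad) rad * 180 / pi

#' Angle between two orientation vectors
#'
#' The inter-sample angular displacement in degrees: the arccosine of the
#' normalized dot product of the (x, y, z) readings 30 s apart. Symmetric in
#' its arguments and invariant to rescaling either vector. Zero-magnitude
#' vectors yield `NA` (a physically impossible reading).
#'
#' @param prev,curr numeric length-3 vectors (x, y, z in g).
#' @return Angle in degrees, in [0, 180], or `NA`.
#' @export
motor_activity <- function(prev, curr) {
  np <- sqrt(sum(prev^2)); nc <- sqrt(sum(curr^2))
  if (!is.finite(np) || !is.finite(nc) || np == 0 || nc == 0) return(NA_real_)
  cosang <- pmin(pmax(sum(prev * curr) / (np * nc), -1), 1)
  if (cosang > 1 - 1e-12) return(0)      # below numerical angle resolution
  deg(acos(cosang))
}

#' Body position angle from one accelerometer reading
#'
#' The unsigned elevation of the device X-axis over the horizontal plane,
#' `asin(|x| / ||(x,y,z)||)` in degrees: 0 for maximum horizontality, 90 for
#' maximum verticality. Arm-down and arm-up both read as vertical, matching
#' the 0-90 degree definition. Invariant to rotation about the X-axis and to
#' rescaling.
#'
#' @param sample numeric length-3 vector (x, y, z in g).
#' @return Angle in degrees, in [0, 90], or `NA` for a zero vector.
#' @export
body_position <- function(sample) {
  nv <- sqrt(sum(sample^2))
  if (!is.finite(nv) || nv == 0) return(NA_real_)
  deg(asin(pmin(abs(sample[1L]) / nv, 1)))
}

#' Derive activity and position series from raw accelerometer samples
#'
#' Applies [motor_activity()] between consecutive samples (the first sample,
#' having no predecessor, is missing) and [body_position()] to every sample.
#' For a `"degrees"` export the tilt angle is used directly as position and
#' its absolute first difference as activity.
#'
#' @param accel an `accel_frame` from [read_accel_csv()].
#' @return List with `activity` and `position` `eqseries` at the native
#'   (30 s) step: activity in degrees per step, position in degrees.
#' @export
derive_actigraphy <- function(accel) {
  stopifnot(inherits(accel, "accel_frame"))
  step <- attr(accel, "step")
  t0 <- accel$timestamp[1L]
  if (attr(accel, "kind") == "degrees") {
    ang <- as.numeric(accel$angle)
    if (any(ang < -1e-9 | ang > 90 + 1e-9, na.rm = TRUE))
      stop("tilt angles must lie in [0, 90] degrees")
    act <- c(NA_real_, abs(diff(ang)))
    pos <- ang
  } else {
    m <- cbind(accel$x, accel$y, accel$z)
    nv <- sqrt(rowSums(m^2))
    bad <- !is.finite(nv) | nv == 0
    pos <- deg(asin(pmin(abs(m[, 1L]) / nv, 1)))
    pos[bad] <- NA_real_
    # vectorized inter-sample angle
    n <- nrow(m)
    act <- rep(NA_real_, n)
    if (n > 1L) {
      dot <- rowSums(m[-n, , drop = FALSE] * m[-1L, , drop = FALSE])
      cosang <- pmin(pmax(dot / (nv[-n] * nv[-1L]), -1), 1)
      cosang[cosang > 1 - 1e-12] <- 1    # below numerical angle resolution
      a <- deg(acos(cosang))
      a[bad[-n] | bad[-1L]] <- NA_real_
      act[-1L] <- a
    }
  }
  list(activity = eqseries(act, t0, step, "motor activity (deg/step)"),
       position = eqseries(pos, t0, step, "body position (deg)"))
}

#' Build an aligned 10-minute subject recording from raw exports
#'
#' Full preprocessing chain: artifact-filter the temperature, derive activity
#' and position from the accelerometer, sum/average them into 10-minute
#' epochs, express activity in degrees/min, and align the three series to
#' their first common epoch. The first accelerometer sample has no activity
#' value, so the leading epoch is dropped from all three series to keep them
#' complete and aligned.
#'
#' @param subject_id subject identifier.
#' @param temperature an `eqseries` at 600 s (degC).
#' @param accel an `accel_frame` of raw 30 s samples.
#' @param diary optional [rest_diary()].
#' @param temp_rule [artifact_rule()] applied to temperature.
#' @return A [subject_recording()].
#' @export
derive_recording <- function(subject_id, temperature, accel, diary = NULL,
                             temp_rule = artifact_rule()) {
  stopifnot(inherits(temperature, "eqseries"))
  tf <- filter_artifacts(temperature, temp_rule)
  ap <- derive_actigraphy(accel)
  a10 <- activity_per_minute(resample_to_10min(ap$activity, "sum"))
  p10 <- resample_to_10min(ap$position, "mean")
  # align to the common span on the shared 600 s grid
  start <- max(as.numeric(tf$start_time), as.numeric(a10$start_time))
  start <- ceiling(start / 600) * 600
  series <- lapply(list(tf, a10, p10), function(s) {
    off <- round((start - as.numeric(s$start_time)) / 600)
    v <- s$values[(off + 1L):length(s$values)]
    eqseries(v, as.POSIXct(start, tz = "UTC", origin = "1970-01-01"), 600, s$label)
  })
  n <- min(vapply(series, length, 1L))
  series <- lapply(series, function(s) { s$values <- s$values[seq_len(n)]; s })
  # drop the leading epoch: its activity sum is undefined (no first derivative)
  if (is.na(series[[2L]]$values[1L]) && n > 1L) {
    series <- lapply(series, function(s) {
      eqseries(s$values[-1L], s$start_time + 600, 600, s$label)
    })
  }
  subject_recording(subject_id, series[[1L]], series[[2L]], series[[3L]], diary)
}
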