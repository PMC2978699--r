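#' Fuse normalized temperature, activity and position into TAP
#'
#' TAP is the epoch-wise weighted mean (equal weights by default) of the
#' three normalized signals: inverted wrist temperature, motor activity and
#' body position, all on [0, 1]. A TAP of 0 corresponds to complete rest and
#' sleep, 1 to high arousal and movement. By default an epoch with any
#' missing component is missing, because averaging two of three silently
#' changes the meaning of the variable; `na_policy = "available"` averages
#' the components that are present instead.
#'
#' @param t_norm_inverted,a_norm,p_norm `eqseries` on a shared grid with
#'   values in [0, 1] (see [normalize_percentile()]).
#' @param weights length-3 positive weights, normalized to sum to 1.
#' @param na_policy `"propagate"` (default) or `"available"`.
#' @return An object of class `tap_series`: list with the fused `series` and
#'   the three `components` kept for audit.
#' @export
compose_tap <- function(t_norm_inverted, a_norm, p_norm,
                        weights = c(1, 1, 1) / 3,
                        na_policy = c("propagate", "available")) {
  na_policy <- match.arg(na_policy)
  if (!same_grid(t_norm_inverted, a_norm) || !same_grid(t_norm_inverted, p_norm))
    stop("the three component series must share start time, step and length")
  if (length(weights) != 3L || any(weights <= 0))
    stop("'weights' must be three positive numbers")
  weights <- weights / sum(weights)
  m <- cbind(t_norm_inverted$values, a_norm$values, p_norm$values)
  if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE))
    stop("component values must lie in [0, 1]")
  if (na_policy == "propagate") {
    tap <- as.vector(m %*% weights)
  } else {
    w <- matrix(weights, nrow(m), 3L, byrow = TRUE)
    w[is.na(m)] <- 0
    wsum <- rowSums(w)
    tap <- ifelse(wsum > 0, rowSums(m * w, na.rm = TRUE) / wsum, NA_real_)
  }
  structure(list(series = eqseries(tap, t_norm_inverted$start_time,
                                   t_norm_inverted$step, "TAP"),
                 components = list(temperature = t_norm_inverted,
                                   activity = a_norm, position = p_norm),
                 weights = weights),
            class = "tap_series")
}

#' @export
print.tap_series <- function(x, ...) {
  print(x$series)
  cat(sprintf("  weights (T,A,P) = %s\n",
              paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

#' Compute TAP from an aligned subject recording
#'
#' Normalizes the three aligned 10-minute series by the subject's 5th/95th
#' percentiles (temperature inverted, so high values mean arousal in all
#' three) and fuses them with [compose_tap()].
#'
#' @param recording a [subject_recording()].
#' @param ... passed to [compose_tap()] (weights, na_policy).
#' @return A `tap_series`.
#' @export
build_tap <- function(recording, ...) {
  stopifnot(inherits(recording, "subject_recording"))
  compose_tap(normalize_percentile(recording$temperature, invert = TRUE),
              normalize_percentile(recording$activity),
              normalize_percentile(recording$position), ...)
}
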