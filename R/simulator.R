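## Synthetic rest-activity signals for validating TAP and CFI: a square (or
## sinusoidal) daily pattern with a 66% activity phase, degraded by 1/f
## fractal noise mixed in at 0-100% and, for the square wave, by day-to-day
## instability of the rest-activity phase boundaries. Also generates full
## synthetic subject recordings (temperature, activity, position, diary)
## with known epoch-level ground truth.

## run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Fixes the generative conditions for one simulated series: daily waveform,
#' activity fraction (0.66, i.e. a rest phase of about 8.2 h), noise kind and
#' percentage, rest-activity instability percentage, length and sampling
#' step. The same configuration and seed always reproduce the same output
#' bit for bit.
#'
#' @param waveform `"square"` or `"sine"`.
#' @param activity_fraction fraction of each 24 h spent in the activity
#'   phase, in (0, 1); default 0.66.
#' @param noise_pct percentage of noise mixed into the pattern, in [0, 100].
#' @param instability_pct day-to-day jitter of the phase boundaries as a
#'   percentage of the 24-h period (square wave only), in [0, 100].
#' @param days number of simulated days (default 7).
#' @param step sampling step in seconds (default 600).
#' @param seed integer RNG seed.
#' @param noise_kind `"fractal"` (1/f, default) or `"gaussian"` (white).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(waveform = c("square", "sine"), activity_fraction = 0.66,
                       noise_pct = 0, instability_pct = 0, days = 7,
                       step = 600, seed = 1,
                       noise_kind = c("fractal", "gaussian")) {
  waveform <- match.arg(waveform)
  noise_kind <- match.arg(noise_kind)
  stopifnot(activity_fraction > 0, activity_fraction < 1,
            noise_pct >= 0, noise_pct <= 100,
            instability_pct >= 0, instability_pct <= 100,
            days >= 1, step > 0, 86400 %% step == 0)
  if (waveform == "sine" && instability_pct > 0)
    stop("instability is defined on the square waveform only")
  structure(list(waveform = waveform, activity_fraction = activity_fraction,
                 noise_pct = noise_pct, instability_pct = instability_pct,
                 days = as.integer(days), step = step, seed = as.integer(seed),
                 noise_kind = noise_kind),
            class = "sim_config")
}

## continuous activity/rest boundary times over the whole run, with optional
## per-boundary uniform jitter; returns the vector b of segment edges where
## segments alternate rest, activity, rest, activity, ...
phase_boundaries <- function(config, seed = config$seed) {
  per_day <- 86400 / config$step
  rest_len <- (per_day - round(config$activity_fraction * per_day)) * config$step
  d <- 0:(config$days - 1L)
  b <- as.vector(rbind(d * 86400, d * 86400 + rest_len))  # rest onset, activity onset
  b <- c(b, config$days * 86400)
  if (config$instability_pct > 0) {
    w <- config$instability_pct / 100 * 86400 / 2
    jit <- with_seed(seed, stats::runif(length(b) - 2L, -w, w))
    b[2:(length(b) - 1L)] <- b[2:(length(b) - 1L)] + jit
    # clamp so phases never invert
    for (k in 2:length(b)) {
      if (b[k] < b[k - 1L]) {
        warning("instability jitter clamped to avoid phase inversion")
        b[k] <- b[k - 1L]
      }
    }
  }
  b
}

## 0/1 activity indicator per epoch (midpoint membership) from boundaries
square_from_boundaries <- function(b, config, start_time) {
  n <- config$days * 86400 / config$step
  mid <- (seq_len(n) - 0.5) * config$step
  seg <- findInterval(mid, b)          # odd segment index = rest, even = activity
  eqseries(as.numeric(seg %% 2 == 0), start_time, config$step, "base wave")
}

#' Daily base pattern of a simulation
#'
#' The noiseless pattern: a square wave at 1 during the activity phase and 0
#' during rest (rest placed at the start of each day, i.e. nocturnally for a
#' midnight start), or a sinusoid `0.5 - 0.5 cos(...)` phased so its minimum
#' falls at the rest-phase midpoint. For the square wave a non-zero
#' `instability_pct` jitters each day's phase boundaries independently by a
#' uniform offset within +/- `instability_pct`/100 * 24 h / 2.
#'
#' @param config a [sim_config()].
#' @param start_time timestamp of the first epoch (default midnight
#'   2024-01-01 UTC, so rest is nocturnal).
#' @return An `eqseries` with values in [0, 1].
#' @export
base_wave <- function(config, start_time = "2024-01-01 00:00:00") {
  stopifnot(inherits(config, "sim_config"))
  start_time <- as.POSIXct(start_time, tz = "UTC")
  if (config$waveform == "square") {
    square_from_boundaries(phase_boundaries(config), config, start_time)
  } else {
    per_day <- 86400 / config$step
    rest_len <- (per_day - round(config$activity_fraction * per_day)) * config$step
    n <- config$days * per_day
    mid <- (seq_len(n) - 0.5) * config$step
    v <- 0.5 - 0.5 * cos(2 * pi * (mid - rest_len / 2) / 86400)
    eqseries(v, start_time, config$step, "base wave")
  }
}

#' Jittered square wave (rest-activity instability)
#'
#' The square base pattern with each day's activity-phase onset and offset
#' independently displaced by a uniform offset in
#' +/- (`instability_pct`/100) * 24 h / 2, clamped so phases never invert.
#' At 20% instability each boundary moves by up to 2.4 h.
#'
#' @param config a [sim_config()] with `waveform = "square"`.
#' @param instability_pct overrides `config$instability_pct` when given.
#' @param seed overrides `config$seed` when given.
#' @param start_time timestamp of the first epoch.
#' @return An `eqseries` of 0/1 values.
#' @export
apply_instability <- function(config, instability_pct = NULL, seed = NULL,
                              start_time = "2024-01-01 00:00:00") {
  stopifnot(inherits(config, "sim_config"))
  if (config$waveform != "square")
    stop("instability is defined on the square waveform only")
  cfg <- config
  if (!is.null(instability_pct)) cfg$instability_pct <- instability_pct
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  start_time <- as.POSIXct(start_time, tz = "UTC")
  square_from_boundaries(phase_boundaries(cfg), cfg, start_time)
}

#' 1/f (pink) fractal noise
#'
#' Zero-mean, unit-variance noise whose spectral power density falls off as
#' 1/f, the canonical fractal noise of biological signals. Generated by
#' spectral synthesis: Fourier amplitudes proportional to `f^(-exponent/2)`
#' (power proportional to `f^-exponent`), phases drawn uniformly from a
#' seeded RNG, inverse transform, then standardization.
#'
#' @param n number of samples (>= 2).
#' @param seed integer RNG seed.
#' @param exponent spectral exponent (1 = pink noise, the default).
#' @return Numeric vector of length `n` with mean 0 and variance 1.
#' @export
fractal_noise <- function(n, seed, exponent = 1) {
  stopifnot(n >= 2)
  n <- as.integer(n)
  half <- n %/% 2L
  phases <- with_seed(seed, stats::runif(half, 0, 2 * pi))
  freq <- (1:half) / n
  amp <- freq^(-exponent / 2)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[(1:half) + 1L] <- spec
  full[n + 1L - (1:half)] <- Conj(spec)
  if (n %% 2L == 0L)                       # Nyquist bin must be real
    full[half + 1L] <- complex(real = amp[half])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  as.vector(scale(x))
}

#' Mix noise into a base pattern
#'
#' Convex mixture `out = (1 - a) base + a noise'` with `a = noise_pct / 100`,
#' where the noise is first min-max rescaled to the base wave's
#' peak-to-trough range; the result is clipped to [0, 1]. At 0% the base is
#' returned unchanged; at 100% the output is pure (rescaled) noise.
#'
#' @param base an `eqseries` (or numeric vector) with values in [0, 1].
#' @param noise numeric vector (or `eqseries`) of the same length.
#' @param noise_pct mixing percentage in [0, 100].
#' @return Same type as `base`, clipped to [0, 1].
#' @export
mix_noise <- function(base, noise, noise_pct) {
  stopifnot(noise_pct >= 0, noise_pct <= 100)
  bv <- if (inherits(base, "eqseries")) base$values else base
  nv <- if (inherits(noise, "eqseries")) noise$values else noise
  if (length(bv) != length(nv)) stop("base and noise lengths differ")
  alpha <- noise_pct / 100
  if (alpha > 0) {
    rng_b <- range(bv, na.rm = TRUE)
    rng_n <- range(nv, na.rm = TRUE)
    if (diff(rng_n) == 0) stop("constant noise cannot be rescaled")
    nv <- (nv - rng_n[1L]) / diff(rng_n) * diff(rng_b) + rng_b[1L]
    out <- (1 - alpha) * bv + alpha * nv
  } else out <- bv
  out <- pmin(pmax(out, 0), 1)
  if (inherits(base, "eqseries")) {
    base$values <- out
    base
  } else out
}

#' Simulate a TAP-like series
#'
#' One call from configuration to degraded series: base pattern (with
#' instability for the square wave), plus fractal or Gaussian noise mixed in
#' at `noise_pct`.
#'
#' @param config a [sim_config()].
#' @param start_time timestamp of the first epoch.
#' @return An `eqseries` with values in [0, 1].
#' @export
simulate_tap <- function(config, start_time = "2024-01-01 00:00:00") {
  stopifnot(inherits(config, "sim_config"))
  b <- base_wave(config, start_time)
  if (config$noise_pct == 0) return(b)
  n <- length(b$values)
  nz <- if (config$noise_kind == "fractal") fractal_noise(n, config$seed + 1L)
        else with_seed(config$seed + 1L, stats::rnorm(n))
  out <- mix_noise(b, nz, config$noise_pct)
  out$label <- sprintf("simulated TAP (%s, %g%% %s noise, %g%% instability)",
                       config$waveform, config$noise_pct, config$noise_kind,
                       config$instability_pct)
  out
}

#' Physiological profile of a synthetic subject
#'
#' Levels and sensor-noise scales used to turn the binary rest-activity
#' pattern into realistic signals: wrist temperature around 31 degC awake
#' rising to about 35 degC during rest, wake motor activity of about
#' 40 deg/min, position spanning 0 (lying) to 90 (upright) degrees,
#' channel-specific noise covering both the sensor and behavioural masking,
#' and an optional afternoon nap. Masking on temperature (ambient exposure,
#' showers) and position (daytime recumbency) is slow, so it is realized as
#' 1/f fractal noise scaled to the stated standard deviation; activity noise
#' is bursty and stays white Gaussian.
#'
#' @param t_rest,t_wake wrist temperature during rest / wake (degC).
#' @param a_wake mean motor activity while awake (deg/min).
#' @param t_sd,a_sd,p_sd noise standard deviations per channel
#'   (degC, deg/min, degrees), sized for masking, not bare sensor noise.
#' @param nap_prob per-day probability of an afternoon nap.
#' @param nap_tod mean nap onset (seconds after midnight, default 15:00).
#' @param nap_tod_jitter uniform jitter on nap onset (seconds).
#' @param nap_duration range (seconds) of nap durations.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(t_rest = 35, t_wake = 31, a_wake = 40,
                            t_sd = 1.0, a_sd = 8, p_sd = 15,
                            nap_prob = 0.15, nap_tod = 15 * 3600,
                            nap_tod_jitter = 3600,
                            nap_duration = c(2400, 5400)) {
  stopifnot(t_rest > t_wake, a_wake > 0, nap_prob >= 0, nap_prob <= 1)
  structure(list(t_rest = t_rest, t_wake = t_wake, a_wake = a_wake,
                 t_sd = t_sd, a_sd = a_sd, p_sd = p_sd,
                 nap_prob = nap_prob, nap_tod = nap_tod,
                 nap_tod_jitter = nap_tod_jitter, nap_duration = nap_duration),
            class = "subject_profile")
}

#' Generate one synthetic subject recording
#'
#' Builds a week-long recording with known ground truth: a square
#' rest-activity pattern (nocturnal rest of about 8 h, optional afternoon
#' naps, optional day-to-day instability) drives the three channels, each
#' degraded by its own independent fractal-noise mixture at
#' `config$noise_pct` plus channel noise from the profile. Temperature follows the
#' inverted pattern (high during rest), activity and position follow it
#' directly. The diary is derived from the truth (exact reporting).
#'
#' @param config a [sim_config()] with `waveform = "square"`.
#' @param profile a [subject_profile()].
#' @param subject_id subject identifier.
#' @param start_time timestamp of the first epoch (midnight for nocturnal
#'   rest).
#' @return An object of class `synthetic_subject`: list with `recording`
#'   (a [subject_recording()] including the diary), `truth` (0/1 rest
#'   `eqseries`) and the `config` and `profile` used.
#' @export
synth_subject <- function(config, profile = subject_profile(),
                          subject_id = "S1",
                          start_time = "2024-01-01 00:00:00") {
  stopifnot(inherits(config, "sim_config"), inherits(profile, "subject_profile"))
  if (config$waveform != "square")
    stop("synthetic subjects are generated from the square waveform")
  start_time <- as.POSIXct(start_time, tz = "UTC")
  act <- apply_instability(config, start_time = start_time)  # 1 = active
  n <- length(act$values)
  mid <- (seq_len(n) - 0.5) * config$step

  # optional afternoon naps become extra rest in the truth
  nap <- with_seed(config$seed + 8L, {
    napday <- stats::runif(config$days) < profile$nap_prob
    ons <- profile$nap_tod + stats::runif(config$days, -1, 1) * profile$nap_tod_jitter
    dur <- stats::runif(config$days, profile$nap_duration[1L], profile$nap_duration[2L])
    list(day = which(napday), onset = ons, dur = dur)
  })
  for (d in nap$day) {
    t0 <- (d - 1L) * 86400 + nap$onset[d]
    act$values[mid >= t0 & mid < t0 + nap$dur[d]] <- 0
  }
  truth <- eqseries(1 - act$values, start_time, config$step, "true rest state")

  channel <- function(seed_off) {
    if (config$noise_pct == 0) return(act$values)
    nz <- if (config$noise_kind == "fractal") fractal_noise(n, config$seed + seed_off)
          else with_seed(config$seed + seed_off, stats::rnorm(n))
    mix_noise(act$values, nz, config$noise_pct)
  }
  sig_t <- channel(2L); sig_a <- channel(3L); sig_p <- channel(4L)
  # channel noise: slow 1/f masking on temperature and position (ambient
  # exposure, daytime recumbency), bursty white noise on activity
  tv <- profile$t_wake + (profile$t_rest - profile$t_wake) * (1 - sig_t) +
    fractal_noise(n, config$seed + 5L) * profile$t_sd
  av <- pmax(sig_a * profile$a_wake +
               with_seed(config$seed + 6L, stats::rnorm(n, 0, profile$a_sd)), 0)
  pv <- pmin(pmax(sig_p * 90 + fractal_noise(n, config$seed + 7L) * profile$p_sd,
                  0), 90)

  diary <- binary_to_diary(truth, subject_id)
  rec <- subject_recording(
    subject_id,
    temperature = eqseries(tv, start_time, config$step, "wrist temperature (degC)"),
    activity = eqseries(av, start_time, config$step, "motor activity (deg/min)"),
    position = eqseries(pv, start_time, config$step, "body position (deg)"),
    diary = diary)
  structure(list(recording = rec, truth = truth, config = config,
                 profile = profile),
            class = "synthetic_subject")
}

#' Generate a synthetic cohort
#'
#' Independent subjects under a shared configuration and profile; subject i
#' uses seed `config$seed + (i - 1) * 20` so channels never share noise.
#'
#' @param n_subjects number of subjects.
#' @param config a [sim_config()].
#' @param profile a [subject_profile()].
#' @param start_time timestamp of the first epoch.
#' @return Named list of `synthetic_subject` objects (`S01`, `S02`, ...).
#' @export
synth_cohort <- function(n_subjects, config, profile = subject_profile(),
                         start_time = "2024-01-01 00:00:00") {
  stopifnot(n_subjects >= 1)
  out <- lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 20L
    synth_subject(cfg, profile, sprintf("S%02d", i), start_time)
  })
  names(out) <- vapply(out, function(s) s$recording$subject_id, "")
  out
}

#' Generate raw logger exports for one synthetic subject
#'
#' Emulates the sensors upstream of the 10-minute pipeline: a 10-minute
#' temperature series and a 30-second three-axis accelerometer frame whose
#' orientation follows the rest-activity pattern (arm near-horizontal and
#' almost still during rest, tilted and mobile during activity), plus the
#' diary. Intended for exercising the derivation and I/O chain end to end.
#'
#' @param config a [sim_config()] with `waveform = "square"`.
#' @param profile a [subject_profile()].
#' @param subject_id subject identifier.
#' @param start_time timestamp of the first sample.
#' @return List with `temperature` (`eqseries`, 600 s), `accel`
#'   (`accel_frame`, 30 s), `diary` ([rest_diary()]) and `truth`
#'   (0/1 rest `eqseries` at 600 s).
#' @export
synth_raw_logger <- function(config, profile = subject_profile(),
                             subject_id = "S1",
                             start_time = "2024-01-01 00:00:00") {
  stopifnot(inherits(config, "sim_config"))
  if (config$waveform != "square")
    stop("raw logger synthesis uses the square waveform")
  start_time <- as.POSIXct(start_time, tz = "UTC")
  cfg30 <- config; cfg30$step <- 30
  act30 <- apply_instability(cfg30, start_time = start_time)$values
  n30 <- length(act30)
  samp <- with_seed(config$seed + 11L, {
    theta <- ifelse(act30 == 1,
                    60 + stats::rnorm(n30, 0, 8),
                    8 + stats::rnorm(n30, 0, 2))
    theta <- pmin(pmax(theta, 0), 90) * pi / 180
    phi_step <- ifelse(act30 == 1, stats::rnorm(n30, 0, 25),
                       stats::rnorm(n30, 0, 1)) * pi / 180
    phi <- cumsum(phi_step)
    cbind(x = sin(theta), y = cos(theta) * cos(phi), z = cos(theta) * sin(phi))
  })
  accel <- structure(
    data.frame(timestamp = start_time + (seq_len(n30) - 1L) * 30,
               x = samp[, "x"], y = samp[, "y"], z = samp[, "z"]),
    step = 30, kind = "g", class = c("accel_frame", "data.frame"))

  act600 <- apply_instability(config, start_time = start_time)
  truth <- eqseries(1 - act600$values, start_time, config$step, "true rest state")
  n <- length(truth$values)
  tv <- profile$t_wake + (profile$t_rest - profile$t_wake) * truth$values +
    fractal_noise(n, config$seed + 12L) * profile$t_sd
  list(temperature = eqseries(tv, start_time, 600, "wrist temperature (degC)"),
       accel = accel,
       diary = binary_to_diary(truth, subject_id),
       truth = truth)
}
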