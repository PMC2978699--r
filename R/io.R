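## CSV dialects for the three logger exports. Header lines starting with "#"
## are ignored on read; timestamps are ISO-8601 taken at face value (UTC).
## Numeric columns are written with 17 significant digits so that
## read(write(x)) reproduces the values bit-exactly.

iso_parse <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable ISO-8601 timestamp in input")
  out
}

iso_format <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

num_format <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

infer_step <- function(times) {
  d <- diff(as.numeric(times))
  if (length(d) == 0L) stop("need at least two rows to infer the sampling step")
  if (max(abs(d - d[1L])) > 1e-6)
    stop("timestamps are not equispaced")
  d[1L]
}

#' Read a temperature-logger CSV export
#'
#' Expects columns `timestamp,temp_c` (ISO-8601, degrees Celsius) at a
#' constant step; lines beginning `#` are ignored.
#'
#' @param path file path.
#' @return An `eqseries` labelled as wrist temperature.
#' @export
read_temperature_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(d)))
    stop("temperature CSV must have columns timestamp,temp_c")
  t <- iso_parse(d$timestamp)
  eqseries(as.numeric(d$temp_c), t[1L], infer_step(t),
           "wrist temperature (degC)")
}

#' Write a temperature series in the logger CSV dialect
#' @param series an `eqseries` of temperatures.
#' @param path file path.
#' @export
write_temperature_csv <- function(series, path) {
  stopifnot(inherits(series, "eqseries"))
  d <- data.frame(timestamp = iso_format(es_times(series)),
                  temp_c = num_format(series$values))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an accelerometer-logger CSV export
#'
#' With `kind = "g"` (the raw export) expects columns `timestamp,x,y,z` in
#' units of g at a 30 s step. Some loggers export a tilt angle directly;
#' `kind = "degrees"` accepts columns `timestamp,angle` instead.
#'
#' @param path file path.
#' @param kind `"g"` (three axes) or `"degrees"` (pre-computed tilt).
#' @return A data frame with POSIXct `timestamp` plus `x`,`y`,`z` or `angle`,
#'   with attribute `step` (seconds) and class `accel_frame`.
#' @export
read_accel_csv <- function(path, kind = c("g", "degrees")) {
  kind <- match.arg(kind)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- if (kind == "g") c("timestamp", "x", "y", "z") else c("timestamp", "angle")
  if (!all(cols %in% names(d)))
    stop(sprintf("accelerometer CSV must have columns %s",
                 paste(cols, collapse = ",")))
  d <- d[cols]
  d$timestamp <- iso_parse(d$timestamp)
  step <- infer_step(d$timestamp)
  structure(d, step = step, kind = kind, class = c("accel_frame", "data.frame"))
}

#' Write accelerometer samples in the logger CSV dialect
#' @param accel an `accel_frame` (see [read_accel_csv()]).
#' @param path file path.
#' @export
write_accel_csv <- function(accel, path) {
  d <- as.data.frame(accel)
  out <- data.frame(timestamp = iso_format(d$timestamp))
  for (col in setdiff(names(d), "timestamp")) out[[col]] <- num_format(d[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rest-diary CSV
#'
#' Expects columns `subject_id,rest_onset,rest_offset` (ISO-8601). A file may
#' hold several subjects; one [rest_diary()] per subject is returned.
#'
#' @param path file path.
#' @return A named list of `rest_diary` objects, one per subject.
#' @export
read_diary_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!all(c("subject_id", "rest_onset", "rest_offset") %in% names(d)))
    stop("diary CSV must have columns subject_id,rest_onset,rest_offset")
  ids <- unique(d$subject_id)
  out <- lapply(ids, function(id) {
    s <- d[d$subject_id == id, ]
    rest_diary(iso_parse(s$rest_onset), iso_parse(s$rest_offset), id)
  })
  names(out) <- ids
  out
}

#' Write one or more rest diaries as CSV
#' @param diaries a `rest_diary` or a list of them.
#' @param path file path.
#' @export
write_diary_csv <- function(diaries, path) {
  if (inherits(diaries, "rest_diary")) diaries <- list(diaries)
  rows <- do.call(rbind, lapply(diaries, function(d) {
    data.frame(subject_id = attr(d, "subject_id"),
               rest_onset = iso_format(d$rest_onset),
               rest_offset = iso_format(d$rest_offset))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a TAP series with its normalized components as TSV
#'
#' Columns: `timestamp, t_norm_inv, a_norm, p_norm, tap`.
#'
#' @param tap a `tap_series` (see [compose_tap()]).
#' @param path file path.
#' @export
write_tap_tsv <- function(tap, path) {
  stopifnot(inherits(tap, "tap_series"))
  d <- data.frame(timestamp = iso_format(es_times(tap$series)),
                  t_norm_inv = num_format(tap$components$temperature$values),
                  a_norm = num_format(tap$components$activity$values),
                  p_norm = num_format(tap$components$position$values),
                  tap = num_format(tap$series$values))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
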