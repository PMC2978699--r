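## Diary-calibrated rest/wake scoring. A normalized signal is thresholded:
## values above the threshold score 0 (awake), values at or below it score 1
## (resting). Thresholds are calibrated per subject by exhaustively scanning
## [0, 1] for the value maximizing agreement with the diary, then averaged
## over the calibration subjects.

#' Threshold a normalized series into rest/wake epochs
#'
#' Scores 0 (awake) where the value exceeds the threshold and 1 (resting)
#' where it is below; a value exactly at the threshold scores rest, so a
#' signal at 0 (complete rest) scored against threshold 0 reads as rest.
#' Missing values stay missing.
#'
#' @param series an `eqseries` with values in [0, 1].
#' @param threshold scalar in [0, 1].
#' @return An `eqseries` of 0/1 predictions on the same grid.
#' @export
score_rest <- function(series, threshold) {
  stopifnot(inherits(series, "eqseries"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  v <- series$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v <= threshold))
  eqseries(out, series$start_time, series$step,
           paste0(series$label, " [rest prediction]"))
}

agreement_rate <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) return(NA_real_)
  mean(pred[ok] == truth[ok])
}

#' Calibrate a rest/wake threshold against diaries
#'
#' For each calibration subject the threshold grid `seq(0, 1, grid_step)` is
#' scanned exhaustively for the value maximizing epoch agreement between
#' [score_rest()] predictions and the diary-derived binary truth; ties are
#' broken toward the lower threshold. The final threshold is the mean of the
#' per-subject optima.
#'
#' @param series_by_subject named list of normalized `eqseries`, one per
#'   calibration subject.
#' @param truth_by_subject matching list of binary truth: `rest_diary`
#'   objects (binarized onto each subject's grid) or 0/1 `eqseries`.
#' @param grid_step threshold scan resolution (default 0.01).
#' @return An object of class `threshold_fit`: list with `threshold` (the
#'   average), `per_subject` (named vector of optima), `agreement`
#'   (per-subject agreement at the optimum) and `grid_step`.
#' @export
calibrate_threshold <- function(series_by_subject, truth_by_subject,
                                grid_step = 0.01) {
  if (length(series_by_subject) == 0L)
    stop("no calibration subjects supplied")
  if (length(series_by_subject) != length(truth_by_subject))
    stop("series and truth lists differ in length")
  ids <- names(series_by_subject)
  if (is.null(ids)) ids <- as.character(seq_along(series_by_subject))
  grid <- seq(0, 1, by = grid_step)
  best <- agr <- rep(NA_real_, length(series_by_subject))
  for (i in seq_along(series_by_subject)) {
    s <- series_by_subject[[i]]
    tr <- truth_by_subject[[i]]
    if (inherits(tr, "rest_diary")) tr <- diary_to_binary(tr, s)
    if (is.null(tr)) {
      warning(sprintf("subject %s has no diary; excluded from calibration", ids[i]))
      next
    }
    stopifnot(inherits(tr, "eqseries"))
    ok <- !is.na(s$values) & !is.na(tr$values)
    v <- s$values[ok]; y <- tr$values[ok]
    if (!length(v)) stop(sprintf("subject %s: no overlapping epochs", ids[i]))
    a <- vapply(grid, function(th) mean((v <= th) == (y == 1)), 1)
    j <- which.max(a)                      # first maximum = lowest threshold
    best[i] <- grid[j]
    agr[i] <- a[j]
  }
  used <- !is.na(best)
  if (!any(used)) stop("no calibration subject had a usable diary")
  structure(list(threshold = mean(best[used]),
                 per_subject = stats::setNames(best[used], ids[used]),
                 agreement = stats::setNames(agr[used], ids[used]),
                 grid_step = grid_step),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> threshold = %.3f (mean of %d subjects, grid %.3g)\n",
              x$threshold, length(x$per_subject), x$grid_step))
  invisible(x)
}

#' Confusion-matrix statistics for rest/wake predictions
#'
#' Rest (1) is the positive class. Reports sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and agreement as overall accuracy
#' `(TP+TN)/total`, together with the predictive values PPV `TP/(TP+FP)`
#' and NPV `TN/(TN+FN)` so users can choose either reading of the rates.
#' Epochs missing in either input are excluded.
#'
#' @param pred,truth 0/1 `eqseries` on the same grid (or plain 0/1 vectors
#'   of equal length).
#' @return An object of class `scoring_result` with the four counts and the
#'   five rates.
#' @export
confusion_stats <- function(pred, truth) {
  if (inherits(pred, "eqseries") && inherits(truth, "eqseries")) {
    if (!same_grid(pred, truth)) stop("pred and truth are on different grids")
    pred <- pred$values; truth <- truth$values
  }
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) stop("no overlapping scored epochs")
  p <- pred[ok] == 1; y <- truth[ok] == 1
  TP <- sum(p & y); FN <- sum(!p & y); TN <- sum(!p & !y); FP <- sum(p & !y)
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = rate(TP, FN), specificity = rate(TN, FP),
                 agreement = (TP + TN) / (TP + TN + FP + FN),
                 ppv = rate(TP, FP), npv = rate(TN, FN),
                 n = TP + TN + FP + FN),
            class = "scoring_result")
}

#' @export
print.scoring_result <- function(x, digits = 3, ...) {
  cat(sprintf("<scoring_result> n = %d epochs (TP %d, FP %d, TN %d, FN %d)\n",
              x$n, x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  sensitivity = %.*f  specificity = %.*f  agreement = %.*f\n",
              digits, x$sensitivity, digits, x$specificity, digits, x$agreement))
  cat(sprintf("  PPV = %.*f  NPV = %.*f\n", digits, x$ppv, digits, x$npv))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Classical Pearson chi-squared statistic with `(rows-1)(cols-1)` degrees of
#' freedom and upper-tail p-value, without continuity correction, for
#' comparing classification outcomes between variables.
#'
#' @param table matrix of non-negative integer counts.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(abs(table - round(table)) > 1e-9))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total: chi-squared undefined")
  ct <- stats::chisq.test(table, correct = FALSE)
  if (any(ct$expected <= 0)) stop("all expected counts must be positive")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Correlate a variable's waveform with the rest-probability waveform
#'
#' Pearson correlation across time-of-day bins between a signal's mean
#' waveform and the mean diary waveform (per-bin rest probability), with the
#' two-sided p-value. Strong negative values mean the signal falls when
#' subjects report rest.
#'
#' @param var_waveform,rest_waveform [mean_waveform()] objects on the same
#'   bin grid.
#' @return List with `r`, `p_value` and `n` (bins used).
#' @export
waveform_correlation <- function(var_waveform, rest_waveform) {
  stopifnot(inherits(var_waveform, "mean_waveform"),
            inherits(rest_waveform, "mean_waveform"))
  if (var_waveform$bin_step != rest_waveform$bin_step ||
      length(var_waveform$values) != length(rest_waveform$values))
    stop("waveforms are on different bin grids")
  x <- var_waveform$values; y <- rest_waveform$values
  ok <- !is.na(x) & !is.na(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("constant waveform: correlation undefined")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Compare two Pearson correlations (Fisher r-to-z)
#'
#' Two-sided test of equality of two independent correlations:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to the
#' standard normal.
#'
#' @param r1,r2 sample correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, each > 3.
#' @return List with `z` and `p_value`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must be strictly inside (-1, 1)")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
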