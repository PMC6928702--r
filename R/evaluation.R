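# Scoring detected bouts against interval activity labels as sample-wise
# binary classification with a temporal tolerance around reference
# transitions (absorbing manual video/sensor synchronization error).

#' Default free-text activity to category map
#'
#' Maps common label texts to the three evaluation categories
#' `straight_walking`, `other_walking`, `non_walking`. Unmapped activities are
#' treated as `non_walking` (with a warning) by [read_labels()].
#'
#' @return named character vector.
#' @export
default_category_map <- function() {
  c(
    "walking" = "straight_walking",
    "straight walking" = "straight_walking",
    "walking on grass" = "other_walking",
    "walking on stones" = "other_walking",
    "walking uphill" = "other_walking",
    "curved walking" = "other_walking",
    "slow walking" = "other_walking",
    "fast walking" = "other_walking",
    "lying" = "non_walking",
    "sitting" = "non_walking",
    "standing" = "non_walking",
    "playing on swings" = "non_walking",
    "climbing stairs" = "non_walking",
    "descending stairs" = "non_walking",
    "running" = "non_walking",
    "jumping" = "non_walking"
  )
}

#' Read interval activity labels from CSV
#'
#' Expects video-annotation style exports: one row per labeled interval with
#' an activity name and either start/end times or start/duration. Labels are
#' validated (sorted, non-overlapping under the half-open convention) and
#' mapped to evaluation categories.
#'
#' @param path CSV file path.
#' @param category_map named character vector mapping activity text to
#'   `straight_walking` / `other_walking` / `non_walking`.
#' @param dialect list naming the columns: `activity`, `start`, and either
#'   `end` or `duration`; `time_unit` scales times to seconds (default 1).
#' @return data.frame of class `activity_labels` with columns `activity`,
#'   `start`, `end`, `category`.
#' @export
read_labels <- function(path, category_map = default_category_map(),
                        dialect = list(activity = "activity", start = "start",
                                       end = "end", duration = NULL,
                                       time_unit = 1, sep = ",")) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, sep = dialect$sep %||% ",", check.names = FALSE)
  need <- c(dialect$activity, dialect$start)
  if (is.null(dialect$duration)) need <- c(need, dialect$end)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_format(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  unit <- dialect$time_unit %||% 1
  start <- as.numeric(df[[dialect$start]]) * unit
  end <- if (is.null(dialect$duration)) {
    as.numeric(df[[dialect$end]]) * unit
  } else {
    start + as.numeric(df[[dialect$duration]]) * unit
  }
  if (any(!(start < end))) stop_data("label intervals must have start < end")
  ord <- order(start)
  out <- data.frame(activity = as.character(df[[dialect$activity]])[ord],
                    start = start[ord], end = end[ord],
                    stringsAsFactors = FALSE)
  ov <- which(out$start[-1] < out$end[-nrow(out)])
  if (length(ov)) {
    stop_data(sprintf("overlapping label intervals at rows: %s",
                      paste(ov, collapse = ", ")))
  }
  known <- out$activity %in% names(category_map)
  if (any(!known)) {
    warn_gb("gaitbouts_unmapped_activity",
            sprintf("unmapped activities treated as non_walking: %s",
                    paste(unique(out$activity[!known]), collapse = ", ")))
  }
  out$category <- ifelse(known, unname(category_map[out$activity]),
                         "non_walking")
  class(out) <- c("activity_labels", class(out))
  out
}

#' Rasterize intervals to a binary sample mask
#'
#' Sample `i` (at time `(i-1)/rate`) is `TRUE` iff it falls in some interval
#' under the half-open `[start, end)` convention.
#'
#' @param intervals data.frame (or matrix) with columns `start` and `end`
#'   in seconds.
#' @param duration total duration in seconds.
#' @param rate sampling rate of the mask in Hz.
#' @return logical vector of length `round(duration * rate)`.
#' @export
rasterize <- function(intervals, duration, rate) {
  if (rate <= 0) stop_param("rate must be > 0")
  n <- round(duration * rate)
  tms <- (seq_len(n) - 1L) / rate
  mask <- logical(n)
  intervals <- as.data.frame(intervals)
  for (k in seq_len(nrow(intervals))) {
    s <- intervals$start[k]
    e <- intervals$end[k]
    if (e > duration) {
      warn_gb("gaitbouts_clipped_interval",
              sprintf("interval [%g, %g) clipped to duration %g", s, e, duration))
      e <- duration
    }
    mask[tms >= s & tms < e] <- TRUE
  }
  mask
}

detection_metrics <- function(tp, tn, fp, fn) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         sensitivity = safe_div(tp, tp + fn),
         specificity = safe_div(tn, tn + fp),
         accuracy = safe_div(tp + tn, tp + tn + fp + fn),
         precision = safe_div(tp, tp + fp)),
    class = "detection_metrics"
  )
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics> sens=%.3f spec=%.3f acc=%.3f prec=%.3f (tp=%d tn=%d fp=%d fn=%d)\n",
    x$sensitivity, x$specificity, x$accuracy, x$precision,
    x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Sample-wise confusion with a transition tolerance
#'
#' Samples within `tolerance` seconds of any reference transition are excluded
#' from counting (symmetric exclusion zones); the remaining samples are
#' tallied into true/false positives/negatives with walking as the positive
#' class. A transition's time is the time of the first sample carrying the
#' new value. Metrics with a zero denominator are reported as `NA`.
#'
#' @param pred,ref logical (or 0/1) masks of equal length on the same grid.
#' @param rate sampling rate of the masks in Hz.
#' @param tolerance exclusion half-width in seconds (default 2).
#' @return a `detection_metrics` object.
#' @export
confusion_with_tolerance <- function(pred, ref, rate, tolerance = 2) {
  if (length(pred) != length(ref)) stop_data("mask lengths differ")
  pred <- as.logical(pred)
  ref <- as.logical(ref)
  n <- length(ref)
  tms <- (seq_len(n) - 1L) / rate
  excl <- logical(n)
  if (n > 1 && tolerance > 0) {
    ch <- which(ref[-1] != ref[-n])
    for (c0 in ch) {
      tt <- c0 / rate
      excl <- excl | (abs(tms - tt) <= tolerance)
    }
  }
  keep <- !excl
  detection_metrics(
    tp = sum(pred & ref & keep),
    tn = sum(!pred & !ref & keep),
    fp = sum(pred & !ref & keep),
    fn = sum(!pred & ref & keep)
  )
}

#' Convert bouts / labels to masks on a common grid
#'
#' @param bouts list of `walking_bout` objects.
#' @param duration,rate grid definition (seconds, Hz).
#' @return logical mask.
#' @export
bouts_to_mask <- function(bouts, duration, rate) {
  iv <- data.frame(
    start = pmax(0, vapply(bouts, `[[`, numeric(1), "start")),
    end = vapply(bouts, `[[`, numeric(1), "end")
  )
  iv$end <- pmin(iv$end, duration)
  if (nrow(iv)) iv <- iv[iv$end > iv$start, , drop = FALSE]
  rasterize(iv, duration, rate)
}

#' @rdname bouts_to_mask
#' @param labels an `activity_labels` data.frame.
#' @param positive categories counted as walking.
#' @export
labels_to_mask <- function(labels, duration, rate,
                           positive = c("straight_walking", "other_walking")) {
  iv <- labels[labels$category %in% positive, c("start", "end"), drop = FALSE]
  rasterize(iv, duration, rate)
}

#' Evaluate detected bouts against reference labels
#'
#' Rasterizes both at `rate`, then applies [confusion_with_tolerance()].
#'
#' @param bouts list of `walking_bout` objects.
#' @param labels an `activity_labels` data.frame.
#' @param duration recording duration in seconds.
#' @param rate evaluation rate in Hz (default 10).
#' @param tolerance transition tolerance in seconds (default 2).
#' @return a `detection_metrics` object.
#' @export
evaluate_detection <- function(bouts, labels, duration, rate = 10,
                               tolerance = 2) {
  pred <- bouts_to_mask(bouts, duration, rate)
  ref <- labels_to_mask(labels, duration, rate)
  confusion_with_tolerance(pred, ref, rate, tolerance)
}
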