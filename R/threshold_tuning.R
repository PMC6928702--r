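# Threshold customization from supervised laboratory gait trials: per-subject
# per-side feature extraction, group-extreme (pop) thresholds, and
# individual-level (indiv) thresholds with amplitude renormalization.

lab_gait_features <- function(subject_id, side, ms_amplitudes,
                              same_side_intervals, inter_side_intervals,
                              signal_max) {
  if (!length(ms_amplitudes) || !length(same_side_intervals) ||
      !length(inter_side_intervals)) {
    stop_tuning(sprintf("subject %s side %s: empty feature lists", subject_id, side))
  }
  if (any(same_side_intervals <= 0) || any(inter_side_intervals <= 0)) {
    stop_data("intervals must be positive")
  }
  if (min(ms_amplitudes) > signal_max) {
    stop_data("minimum midswing amplitude exceeds the recorded signal maximum")
  }
  structure(
    list(subject_id = subject_id, side = side,
         ms_amplitudes = as.numeric(ms_amplitudes),
         same_side_intervals = as.numeric(same_side_intervals),
         inter_side_intervals = as.numeric(inter_side_intervals),
         signal_max = signal_max),
    class = "lab_gait_features"
  )
}

#' Extract per-side gait features from laboratory trials
#'
#' For each straight-walking trial, midswing peaks are detected per side with
#' a prominence criterion (no fixed amplitude threshold: lab trials are
#' supervised, so every prominent positive peak is a true midswing). Peak
#' amplitudes, same-side intervals and successive opposite-side intervals are
#' pooled across trials; `signal_max` is the maximum of the positive part of
#' the signal over all trials.
#'
#' @param trials list of trials, each a list with elements `left` and `right`
#'   ([pitch_signal()]s).
#' @param subject_id free-text subject identifier.
#' @param peak_prominence minimum peak prominence in deg/s; default is 20% of
#'   each trial's 95th percentile of the positive signal part.
#' @return list with elements `left` and `right`, each of class
#'   `lab_gait_features`.
#' @export
extract_lab_features <- function(trials, subject_id = "",
                                 peak_prominence = NULL) {
  if (!length(trials)) stop_tuning("no laboratory trials supplied")
  acc <- list(
    left = list(amp = numeric(0), ss = numeric(0), smax = -Inf),
    right = list(amp = numeric(0), ss = numeric(0), smax = -Inf)
  )
  inter <- numeric(0)
  for (tr in trials) {
    times_by_side <- list()
    for (s in c("left", "right")) {
      sig <- tr[[s]]
      v <- sig$values
      prom <- peak_prominence %||% (0.2 * positive_p95(v))
      idx <- if (is.na(prom)) integer(0) else find_peaks(v, prom)
      idx <- idx[v[idx] > 0]
      tms <- signal_times(sig)[idx]
      times_by_side[[s]] <- tms
      acc[[s]]$amp <- c(acc[[s]]$amp, v[idx])
      if (length(tms) > 1L) acc[[s]]$ss <- c(acc[[s]]$ss, diff(tms))
      acc[[s]]$smax <- max(acc[[s]]$smax, if (any(v > 0)) max(v) else -Inf)
    }
    merged <- rbind(
      data.frame(time = times_by_side$left,
                 side = rep("left", length(times_by_side$left))),
      data.frame(time = times_by_side$right,
                 side = rep("right", length(times_by_side$right)))
    )
    if (nrow(merged) > 1L) {
      merged <- merged[order(merged$time), ]
      gaps <- diff(merged$time)
      alt <- merged$side[-1] != merged$side[-nrow(merged)]
      inter <- c(inter, gaps[alt])
    }
  }
  out <- list()
  for (s in c("left", "right")) {
    if (!length(acc[[s]]$amp)) {
      stop_tuning(sprintf(
        "no midswing peaks found in any trial for subject %s, side %s",
        subject_id, s))
    }
    out[[s]] <- lab_gait_features(
      subject_id = subject_id, side = s,
      ms_amplitudes = acc[[s]]$amp,
      same_side_intervals = acc[[s]]$ss,
      inter_side_intervals = inter,
      signal_max = acc[[s]]$smax
    )
  }
  out
}

# Accept a flat list of lab_gait_features or a list of left/right pairs.
flatten_features <- function(members) {
  out <- list()
  for (m in members) {
    if (inherits(m, "lab_gait_features")) {
      out[[length(out) + 1L]] <- m
    } else if (is.list(m)) {
      for (el in m) {
        if (inherits(el, "lab_gait_features")) out[[length(out) + 1L]] <- el
      }
    }
  }
  if (!length(out)) stop_tuning("no laboratory features in group")
  out
}

#' Group-extreme (population) thresholds
#'
#' To be as inclusive as possible, the group extremes of the supervised lab
#' features become the thresholds: `th1` is the group minimum of the minimal
#' midswing amplitudes, `th2`/`th3` the group minimum/maximum of the same-side
#' intervals, `th4` the group maximum of the opposite-side intervals.
#'
#' @param members list of `lab_gait_features` (or of left/right pairs as
#'   returned by [extract_lab_features()]).
#' @param group_id free-text group label (e.g. a diagnostic group).
#' @return a [threshold_set()] with `mode = "pop"`.
#' @export
pop_thresholds <- function(members, group_id = "") {
  feats <- flatten_features(members)
  th1 <- min(vapply(feats, function(f) min(f$ms_amplitudes), numeric(1)))
  th2 <- min(vapply(feats, function(f) min(f$same_side_intervals), numeric(1)))
  th3 <- max(vapply(feats, function(f) max(f$same_side_intervals), numeric(1)))
  th4 <- max(vapply(feats, function(f) max(f$inter_side_intervals), numeric(1)))
  threshold_set(th1_left = th1, th1_right = th1, th2 = th2, th3 = th3,
                th4 = th4, mode = "pop",
                metadata = list(group_id = group_id, n_members = length(feats)))
}

#' Individual-level (personalized) thresholds
#'
#' Per side `s`, the amplitude threshold is renormalized to the out-of-lab
#' signal scale:
#' `th1_s = (min lab MS amplitude_s / max lab signal_s) x P95(positive out-lab signal_s)`,
#' since absolute amplitudes may differ between laboratory and daily-life
#' gait. Timing thresholds are the per-side lab extremes (`th2` minimum,
#' `th3` maximum of same-side intervals); `th4` is the maximum opposite-side
#' interval. The shared fields store the permissive envelope of the two
#' sides; exact per-side values are kept in `metadata$per_side` and applied
#' during detection.
#'
#' @param features_left,features_right `lab_gait_features` per side.
#' @param out_lab_left,out_lab_right out-of-laboratory [pitch_signal()]s.
#' @return a [threshold_set()] with `mode = "indiv"`.
#' @export
indiv_thresholds <- function(features_left, features_right,
                             out_lab_left, out_lab_right) {
  stopifnot(inherits(features_left, "lab_gait_features"),
            inherits(features_right, "lab_gait_features"))
  p95 <- function(sig) {
    q <- positive_p95(sig$values)
    if (is.na(q) || q <= 0) {
      stop_tuning("degenerate out-of-lab signal (95th percentile <= 0)")
    }
    q
  }
  side_th <- function(f, out_sig) {
    list(th1 = min(f$ms_amplitudes) / f$signal_max * p95(out_sig),
         th2 = min(f$same_side_intervals),
         th3 = max(f$same_side_intervals))
  }
  l <- side_th(features_left, out_lab_left)
  r <- side_th(features_right, out_lab_right)
  th4 <- max(c(features_left$inter_side_intervals,
               features_right$inter_side_intervals))
  threshold_set(
    th1_left = l$th1, th1_right = r$th1,
    th2 = min(l$th2, r$th2), th3 = max(l$th3, r$th3), th4 = th4,
    mode = "indiv",
    metadata = list(subject_id = features_left$subject_id,
                    per_side = list(left = l, right = r))
  )
}

#' Export lab features as a one-row data.frame
#'
#' @param features a `lab_gait_features` object.
#' @return data.frame of the feature extremes used for tuning.
#' @export
features_to_df <- function(features) {
  data.frame(
    subject_id = features$subject_id,
    side = features$side,
    min_ms_amplitude = min(features$ms_amplitudes),
    min_same_side_interval = min(features$same_side_intervals),
    max_same_side_interval = max(features$same_side_intervals),
    max_inter_side_interval = max(features$inter_side_intervals),
    signal_max = features$signal_max,
    stringsAsFactors = FALSE
  )
}
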