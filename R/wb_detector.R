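# The fixed-threshold midswing/alternation walking-bout detector. Thresholds
# are injectable so the same machinery runs in init (literature defaults),
# pop (group extremes) and indiv (per-individual, per-side) modes.

#' Construct a detection threshold set
#'
#' The four thresholds governing midswing-based bout detection:
#' * `th1` (deg/s): minimal midswing amplitude, one value per side;
#' * `th2` (s): minimal time between midswings of the same side;
#' * `th3` (s): maximal time between midswings of the same side;
#' * `th4` (s): maximal time between opposite-side midswings, used for the
#'   first pair of a bout and adapted afterwards (see [adaptive_th4()]).
#'
#' No ordering between `th3` and `th4` is required (group-extreme sets can
#' have `th4 < th3`).
#'
#' @param th1_left,th1_right amplitude thresholds in deg/s.
#' @param th2,th3,th4 timing thresholds in seconds.
#' @param mode `"init"`, `"pop"` or `"indiv"`.
#' @param metadata optional list; `metadata$per_side$left/right` may carry
#'   per-side `th1`, `th2`, `th3` for individual-level detection.
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(th1_left = 50, th1_right = th1_left, th2 = 0.5,
                          th3 = 1.5, th4 = 3.5,
                          mode = c("init", "pop", "indiv"), metadata = list()) {
  mode <- match.arg(mode)
  vals <- c(th1_left = th1_left, th1_right = th1_right, th2 = th2,
            th3 = th3, th4 = th4)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_param("all thresholds must be finite and positive")
  }
  if (!(th2 < th3)) stop_param("th2 must be smaller than th3")
  structure(
    list(th1_left = th1_left, th1_right = th1_right, th2 = th2, th3 = th3,
         th4 = th4, mode = mode, metadata = metadata),
    class = "threshold_set"
  )
}

#' Default thresholds of the initial fixed-threshold algorithm
#'
#' 50 deg/s minimal midswing amplitude, 0.5 s and 1.5 s minimal/maximal
#' same-side spacing, 3.5 s maximal opposite-side spacing.
#'
#' @return a [threshold_set()] with `mode = "init"`.
#' @export
init_thresholds <- function() threshold_set()

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set mode=%s> th1 L/R = %.4g/%.4g deg/s, th2 = %.4g s, th3 = %.4g s, th4 = %.4g s\n",
    x$mode, x$th1_left, x$th1_right, x$th2, x$th3, x$th4))
  invisible(x)
}

per_side_th <- function(thresholds, side, name) {
  ps <- thresholds$metadata$per_side
  if (!is.null(ps) && !is.null(ps[[side]]) && !is.null(ps[[side]][[name]])) {
    return(ps[[side]][[name]])
  }
  thresholds[[name]]
}

th1_for <- function(thresholds, side) {
  if (side == "left") thresholds$th1_left else thresholds$th1_right
}

midswing_events <- function(time = numeric(0), amplitude = numeric(0),
                            side = character(0)) {
  data.frame(time = as.numeric(time), amplitude = as.numeric(amplitude),
             side = as.character(side), stringsAsFactors = FALSE)
}

#' Detect midswing candidate peaks
#'
#' All strict local maxima of the pitch angular velocity with amplitude
#' strictly above `th1`, tagged with the signal's side. Event times are the
#' sample times of the maxima.
#'
#' @param signal a [pitch_signal()]; warns (does not fail) if unfiltered.
#' @param th1 amplitude threshold in deg/s.
#' @return data.frame with columns `time`, `amplitude`, `side`.
#' @export
find_midswing_candidates <- function(signal, th1) {
  stopifnot(inherits(signal, "pitch_signal"))
  if (!isTRUE(signal$filtered)) {
    warn_gb("gaitbouts_unfiltered_signal",
            "signal is not high-pass filtered; drift may bias peak detection")
  }
  v <- signal$values
  idx <- local_maxima(v)
  idx <- idx[v[idx] > th1]
  midswing_events(time = signal$t0 + (idx - 1L) / signal$sampling_rate,
                  amplitude = v[idx], side = rep(signal$side, length(idx)))
}

#' Collapse peaks closer than th2
#'
#' Same-side candidate peaks are grouped into clusters by chaining successive
#' gaps smaller than `th2`; within each cluster only the highest-amplitude
#' event survives (ties keep the earlier event). Surviving events are thus
#' never closer than `th2`.
#'
#' @param events time-sorted single-side event data.frame.
#' @param th2 minimal allowed spacing in seconds.
#' @return the deduplicated event data.frame.
#' @export
deduplicate_within_th2 <- function(events, th2) {
  n <- nrow(events)
  if (n <= 1L) return(events)
  if (is.unsorted(events$time)) stop_data("events must be time-sorted")
  grp <- cumsum(c(TRUE, diff(events$time) >= th2))
  keep <- vapply(split(seq_len(n), grp), function(ix) {
    ix[which.max(events$amplitude[ix])] # which.max: first (earliest) on ties
  }, integer(1))
  out <- events[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adaptive opposite-side spacing threshold
#'
#' For the first pair of a candidate bout the fixed `th4_initial` applies
#' (3.5 s by default); once step intervals have accumulated, the bound
#' becomes `1.5 s + mean(step intervals so far detected in the bout)`.
#'
#' @param step_intervals_so_far numeric vector of step intervals (s) already
#'   accepted in the current bout.
#' @param th4_initial initial threshold in seconds.
#' @return the applicable threshold in seconds.
#' @export
adaptive_th4 <- function(step_intervals_so_far, th4_initial = 3.5) {
  if (length(step_intervals_so_far) && any(step_intervals_so_far < 0)) {
    stop_data("step intervals must be non-negative")
  }
  if (!length(step_intervals_so_far)) return(th4_initial)
  1.5 + mean(step_intervals_so_far)
}

make_bout <- function(events) {
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  ints <- diff(events$time)
  n_left <- sum(events$side == "left")
  n_right <- sum(events$side == "right")
  structure(
    list(events = events,
         start = events$time[1] - ints[1] / 2,
         end = events$time[nrow(events)] + ints[length(ints)] / 2,
         n_steps = nrow(events),
         n_cycles = min(n_left, n_right)),
    class = "walking_bout"
  )
}

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf("<walking_bout> [%.2f, %.2f] s, %d steps (%d cycles)\n",
              x$start, x$end, x$n_steps, x$n_cycles))
  invisible(x)
}

#' Group midswing events into walking bouts
#'
#' Merges the two deduplicated per-side event streams into one time-ordered
#' stream and emits maximal runs satisfying (a) strict left/right alternation,
#' (b) same-side consecutive gaps no larger than `th3` (per-side values when
#' present in the threshold metadata), and (c) adjacent opposite-side gaps no
#' larger than the adaptive th4 at that point. A violating event ends the
#' current bout and seeds the next candidate. Runs with fewer than 2 events
#' are discarded.
#'
#' @param ms_left,ms_right deduplicated, time-sorted event data.frames.
#' @param thresholds a [threshold_set()].
#' @return list of `walking_bout` objects.
#' @export
segment_bouts <- function(ms_left, ms_right, thresholds) {
  ev <- rbind(ms_left, ms_right)
  if (!nrow(ev)) return(list())
  ev <- ev[order(ev$time, ev$side), , drop = FALSE] # ties: left first
  rownames(ev) <- NULL
  n <- nrow(ev)
  th3l <- per_side_th(thresholds, "left", "th3")
  th3r <- per_side_th(thresholds, "right", "th3")
  bouts <- list()
  i <- 1L
  while (i <= n) {
    last_side_time <- c(left = NA_real_, right = NA_real_)
    last_side_time[[ev$side[i]]] <- ev$time[i]
    intervals <- numeric(0)
    j <- i + 1L
    while (j <= n) {
      sj <- ev$side[j]
      tj <- ev$time[j]
      gap <- tj - ev$time[j - 1L]
      ok <- sj != ev$side[j - 1L]
      if (ok && !is.na(last_side_time[[sj]])) {
        th3s <- if (sj == "left") th3l else th3r
        ok <- (tj - last_side_time[[sj]]) <= th3s
      }
      if (ok) ok <- gap <= adaptive_th4(intervals, thresholds$th4)
      if (!ok) break
      intervals <- c(intervals, gap)
      last_side_time[[sj]] <- tj
      j <- j + 1L
    }
    if (j - i >= 2L) {
      bouts[[length(bouts) + 1L]] <- make_bout(ev[i:(j - 1L), , drop = FALSE])
    }
    i <- j
  }
  bouts
}

#' Full walking-bout detection pipeline
#'
#' Midswing candidates per side (per-side `th1`), deduplication within `th2`
#' (per-side values when present), then alternation-based bout segmentation.
#'
#' @param left,right filtered [pitch_signal()]s sharing sampling rate and
#'   time base.
#' @param thresholds a [threshold_set()].
#' @return list of `walking_bout` objects.
#' @export
detect_walking_bouts <- function(left, right, thresholds = init_thresholds()) {
  stopifnot(inherits(left, "pitch_signal"), inherits(right, "pitch_signal"))
  if (left$sampling_rate != right$sampling_rate) {
    stop_data("left and right signals must share the sampling rate")
  }
  if (left$side != "left" || right$side != "right") {
    stop_data("pass the left signal first and the right signal second")
  }
  msl <- find_midswing_candidates(left, th1_for(thresholds, "left"))
  msr <- find_midswing_candidates(right, th1_for(thresholds, "right"))
  msl <- deduplicate_within_th2(msl, per_side_th(thresholds, "left", "th2"))
  msr <- deduplicate_within_th2(msr, per_side_th(thresholds, "right", "th2"))
  segment_bouts(msl, msr, thresholds)
}

#' Keep bouts with a minimum number of steps
#'
#' The walking-speed stage only analyses bouts of at least 4 steps; detection
#' itself emits bouts from 2 events up.
#'
#' @param bouts list of `walking_bout` objects.
#' @param min_steps minimum step count, inclusive (default 4).
#' @return filtered list.
#' @export
filter_min_steps <- function(bouts, min_steps = 4) {
  Filter(function(b) b$n_steps >= min_steps, bouts)
}

#' Validate the structural invariants of a walking bout
#'
#' Checks strict time ordering, strict side alternation, same-side gaps within
#' `[th2, th3]`, and opposite-side gaps within the adaptive th4. Used heavily
#' by the test-suite.
#'
#' @param bout a `walking_bout`.
#' @param thresholds the [threshold_set()] used for detection.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_bout <- function(bout, thresholds) {
  ev <- bout$events
  if (nrow(ev) < 2L) stop_data("bout has fewer than 2 events")
  if (any(diff(ev$time) <= 0)) stop_data("event times not strictly increasing")
  if (any(ev$side[-1] == ev$side[-nrow(ev)])) stop_data("sides do not alternate")
  for (s in c("left", "right")) {
    t_s <- ev$time[ev$side == s]
    amp_s <- ev$amplitude[ev$side == s]
    if (any(amp_s <= th1_for(thresholds, s))) {
      stop_data("amplitude at or below the applicable th1")
    }
    if (length(t_s) > 1L) {
      g <- diff(t_s)
      if (any(g < per_side_th(thresholds, s, "th2"))) {
        stop_data("same-side gap below th2")
      }
      if (any(g > per_side_th(thresholds, s, "th3"))) {
        stop_data("same-side gap above th3")
      }
    }
  }
  ints <- diff(ev$time)
  for (k in seq_along(ints)) {
    if (ints[k] > adaptive_th4(ints[seq_len(k - 1L)], thresholds$th4)) {
      stop_data("opposite-side gap above the adaptive th4")
    }
  }
  invisible(TRUE)
}

#' Flatten bouts to a summary data.frame
#'
#' @param bouts list of `walking_bout` objects.
#' @return data.frame with one row per bout (`bout_id`, `start_s`, `end_s`,
#'   `n_steps`, `n_cycles`, `first_side`).
#' @export
bouts_to_df <- function(bouts) {
  if (!length(bouts)) {
    return(data.frame(bout_id = integer(0), start_s = numeric(0),
                      end_s = numeric(0), n_steps = integer(0),
                      n_cycles = integer(0), first_side = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    bout_id = seq_along(bouts),
    start_s = vapply(bouts, `[[`, numeric(1), "start"),
    end_s = vapply(bouts, `[[`, numeric(1), "end"),
    n_steps = vapply(bouts, `[[`, integer(1), "n_steps"),
    n_cycles = vapply(bouts, function(b) as.integer(b$n_cycles), integer(1)),
    first_side = vapply(bouts, function(b) b$events$side[1], character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a threshold set as JSON
#'
#' @param thresholds a [threshold_set()].
#' @param path file path.
#' @return `write_thresholds` returns `path` invisibly; `read_thresholds`
#'   returns a [threshold_set()].
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("thresholds file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(th1_left = x$th1_left, th1_right = x$th1_right, th2 = x$th2,
                th3 = x$th3, th4 = x$th4, mode = x$mode,
                metadata = x$metadata %||% list())
}
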