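# Independent brute-force oracles and tiny fixture builders shared across the
# suite. The oracles deliberately re-derive the semantics from scratch
# (connectivity search, window re-validation, per-sample loops) rather than
# reusing any package internals.

# Deduplication oracle: clusters are connected components of the graph with
# an edge between any two events closer than th2; each component keeps its
# highest-amplitude event (earlier on ties).
oracle_dedup <- function(events, th2) {
  n <- nrow(events)
  if (n <= 1) return(events)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(events$time[i] - events$time[j]) < th2 &&
            comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- vapply(unique(comp), function(cc) {
    ix <- which(comp == cc)
    best <- ix[events$amplitude[ix] == max(events$amplitude[ix])]
    min(best)
  }, integer(1))
  out <- events[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Bout-segmentation oracle: re-validates every candidate window from scratch
# and emits the maximal valid run starting at each restart position.
oracle_valid_window <- function(ev, i, j, th) {
  sides <- ev$side[i:j]
  times <- ev$time[i:j]
  m <- length(sides)
  if (m >= 2 && any(sides[-1] == sides[-m])) return(FALSE)
  for (s in c("left", "right")) {
    ts <- times[sides == s]
    if (length(ts) > 1 && any(diff(ts) > th$th3)) return(FALSE)
  }
  gaps <- diff(times)
  for (k in seq_along(gaps)) {
    lim <- if (k == 1) th$th4 else 1.5 + mean(gaps[seq_len(k - 1)])
    if (gaps[k] > lim) return(FALSE)
  }
  TRUE
}

oracle_segment <- function(ms_left, ms_right, th) {
  ev <- rbind(ms_left, ms_right)
  if (!nrow(ev)) return(list())
  ev <- ev[order(ev$time, ev$side), , drop = FALSE]
  rownames(ev) <- NULL
  n <- nrow(ev)
  res <- list()
  p <- 1L
  while (p <= n) {
    j <- p
    while (j + 1L <= n && oracle_valid_window(ev, p, j + 1L, th)) j <- j + 1L
    if (j - p + 1L >= 2L) {
      run <- ev[p:j, , drop = FALSE]
      rownames(run) <- NULL
      res[[length(res) + 1L]] <- run
    }
    p <- j + 1L
  }
  res
}

# Confusion oracle: per-sample loop, each sample checked against every
# reference transition.
oracle_confusion <- function(pred, ref, rate, tolerance) {
  n <- length(ref)
  trans <- c()
  for (i in seq_len(n - 1)) if (ref[i] != ref[i + 1]) trans <- c(trans, i / rate)
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(n)) {
    ti <- (i - 1) / rate
    skip <- FALSE
    if (tolerance > 0) {
      for (tt in trans) if (abs(ti - tt) <= tolerance) skip <- TRUE
    }
    if (skip) next
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (!pred[i] && !ref[i]) tn <- tn + 1L
    else if (pred[i] && !ref[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

random_event_stream <- function(n, span = 6, sides = c("left", "right")) {
  data.frame(time = sort(runif(n, 0, span)),
             amplitude = runif(n, 55, 300),
             side = sample(sides, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

bout_events_equal <- function(bouts, oracle_runs) {
  if (length(bouts) != length(oracle_runs)) return(FALSE)
  for (k in seq_along(bouts)) {
    a <- bouts[[k]]$events
    b <- oracle_runs[[k]]
    if (nrow(a) != nrow(b)) return(FALSE)
    if (!isTRUE(all.equal(a$time, b$time)) || !identical(a$side, b$side)) {
      return(FALSE)
    }
  }
  TRUE
}

# A pitch signal made of Gaussian bumps at known times (clean, marked
# filtered so the detector does not warn).
bump_signal <- function(times, amps, duration, fs = 100, sigma = 0.05,
                        side = "left") {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  v <- numeric(n)
  for (k in seq_along(times)) {
    v <- v + amps[k] * exp(-0.5 * ((t - times[k]) / sigma)^2)
  }
  pitch_signal(v, fs, side, filtered = TRUE)
}

write_temp_csv <- function(df, sep = ",") {
  p <- tempfile(fileext = ".csv")
  utils::write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE)
  p
}

# The stated-world scenario used by the method-ordering experiments:
# a subject with known gait parameters performing walks interleaved with a
# swing (high amplitude, slow bilateral periodicity) and a stairs confounder
# (low amplitude, gait-like alternation).
ordering_subject <- function() {
  walk_params(cadence = 105, amp_left = 230, amp_right = 210,
              amp_cv = 0.06, step_cv = 0.04)
}

ordering_scenario <- function(seed) {
  gait_scenario(list(
    list(activity = "lie", duration = 10),
    list(activity = "walk", duration = 45, params = ordering_subject()),
    list(activity = "swing", duration = 45),
    list(activity = "walk", duration = 45, params = ordering_subject()),
    list(activity = "stairs", duration = 45),
    list(activity = "sit", duration = 30)
  ), seed = seed)
}

# Full tune -> detect -> evaluate comparison of the three threshold modes on
# one seeded protocol; returns named sensitivities/specificities.
ordering_metrics <- function(seed) {
  sim <- simulate_protocol(ordering_scenario(seed))
  sl <- highpass_filter(pca_align(sim$left))
  sr <- highpass_filter(pca_align(sim$right))
  dur <- sim$truth$duration

  lab_a <- simulate_lab_trials(ordering_subject(), n_trials = 2,
                               seed = seed * 1000 + 1)
  fe_a <- extract_lab_features(lab_a$trials, "A")
  th_indiv <- indiv_thresholds(fe_a$left, fe_a$right, sl, sr)

  lab_b <- simulate_lab_trials(
    walk_params(cadence = 100, amp_left = 115, amp_right = 110,
                amp_cv = 0.06, step_cv = 0.04),
    n_trials = 2, seed = seed * 1000 + 2)
  lab_c <- simulate_lab_trials(
    walk_params(cadence = 80, amp_left = 250, amp_right = 250,
                amp_cv = 0.06, step_cv = 0.04),
    n_trials = 2, seed = seed * 1000 + 3)
  th_pop <- pop_thresholds(list(fe_a,
                                extract_lab_features(lab_b$trials, "B"),
                                extract_lab_features(lab_c$trials, "C")),
                           group_id = "G")

  out <- lapply(list(init = init_thresholds(), pop = th_pop,
                     indiv = th_indiv), function(th) {
    evaluate_detection(detect_walking_bouts(sl, sr, th),
                       sim$truth$labels, dur)
  })
  c(sens_init = out$init$sensitivity, sens_pop = out$pop$sensitivity,
    sens_indiv = out$indiv$sensitivity, spec_init = out$init$specificity,
    spec_pop = out$pop$specificity, spec_indiv = out$indiv$specificity)
}
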