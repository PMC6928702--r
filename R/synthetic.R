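# Ground-truthed synthetic gait generator: laboratory trials and
# daily-life-like activity protocols with the statistical structure the
# detector relies on (alternating positive midswing peaks on the shank pitch
# angular velocity, variable cadence/amplitude/asymmetry, drift, noise, and
# confounding periodic non-gait activities).

#' Walking parameters for the simulator
#'
#' @param cadence steps per minute (left + right steps; default 109, i.e. a
#'   gait cycle of about 1.1 s).
#' @param amp_left,amp_right mean midswing peak amplitude per side in deg/s.
#' @param amp_cv coefficient of variation of per-step peak amplitudes.
#' @param step_cv coefficient of variation of step times (jitter of midswing
#'   times, as a fraction of the step period).
#' @param asymmetry multiplier on the right-side amplitude (1 = symmetric).
#' @param speed,speed_cv true walking speed per gait cycle, mean (m/s) and CV.
#' @param peak_width optional midswing peak width (Gaussian sigma, s);
#'   default is 5% of the gait-cycle period.
#' @return parameter list for [simulate_walk_segment()].
#' @export
walk_params <- function(cadence = 109, amp_left = 200, amp_right = 200,
                        amp_cv = 0.08, step_cv = 0.04, asymmetry = 1,
                        speed = 1.2, speed_cv = 0.05, peak_width = NULL) {
  list(cadence = cadence, amp_left = amp_left, amp_right = amp_right,
       amp_cv = amp_cv, step_cv = step_cv, asymmetry = asymmetry,
       speed = speed, speed_cv = speed_cv, peak_width = peak_width)
}

#' Parameter preset emulating an impaired, attenuated gait pattern
#'
#' Lower peak amplitudes, higher amplitude/timing variability and left/right
#' asymmetry; a parameter preset, not a clinical claim.
#'
#' @return parameter list for [simulate_walk_segment()].
#' @export
cp_walk_params <- function() {
  walk_params(cadence = 95, amp_left = 160, amp_right = 120, amp_cv = 0.15,
              step_cv = 0.08, asymmetry = 1, speed = 0.9, speed_cv = 0.1)
}

# Sum Gaussian bumps at `times` with amplitudes `amps` onto an n-sample grid.
add_bumps <- function(v, fs, times, amps, sigma) {
  n <- length(v)
  for (k in seq_along(times)) {
    lo <- max(1L, floor((times[k] - 4 * sigma) * fs) + 1L)
    hi <- min(n, ceiling((times[k] + 4 * sigma) * fs) + 1L)
    if (lo > hi) next
    tt <- (lo:hi - 1L) / fs
    v[lo:hi] <- v[lo:hi] + amps[k] * exp(-0.5 * ((tt - times[k]) / sigma)^2)
  }
  v
}

# True midswing = sample argmax of the clean signal near each nominal time.
truth_from_clean <- function(clean, fs, times, sigma) {
  n <- length(clean)
  tm <- numeric(length(times))
  am <- numeric(length(times))
  for (k in seq_along(times)) {
    lo <- max(1L, floor((times[k] - 2 * sigma) * fs) + 1L)
    hi <- min(n, ceiling((times[k] + 2 * sigma) * fs) + 1L)
    w <- lo:hi
    i <- w[which.max(clean[w])]
    tm[k] <- (i - 1L) / fs
    am[k] <- clean[i]
  }
  data.frame(time = tm, amplitude = am)
}

#' Simulate one straight-walking segment
#'
#' Per side, a periodic train of positive Gaussian midswing peaks with broad
#' negative stance lobes in between; left and right are offset by half a
#' gait cycle (one step period), midswing times are jittered by `step_cv`,
#' and white noise plus linear drift are added. Ground-truth midswing times
#' and amplitudes are recorded at the clean-signal peak samples.
#'
#' @param params see [walk_params()].
#' @param duration segment duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed, or `NULL` to continue from the current RNG state.
#' @param noise_sd white noise standard deviation in deg/s.
#' @param drift linear drift rate in deg/s per minute.
#' @return list with `left`/`right` ([pitch_signal()]s), `clean` (noise-free
#'   values per side) and `truth` (`ms_left`, `ms_right`, `cycle_speeds`).
#' @export
simulate_walk_segment <- function(params = walk_params(), duration, fs = 100,
                                  seed = NULL, noise_sd = 3, drift = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (params$cadence <= 0) stop_param("cadence must be > 0")
  step_p <- 60 / params$cadence
  cycle <- 2 * step_p
  sigma <- params$peak_width %||% (0.05 * cycle)
  if (step_p < 4 * sigma) {
    stop_param("cadence implies a step period shorter than 2 peak widths")
  }
  margin <- max(cycle / 4, 4 * sigma)
  if (duration < 2 * margin + cycle) stop_param("segment too short for one cycle")
  n <- round(duration * fs)

  nominal <- function(offset) {
    tt <- seq(margin + offset, duration - margin + 1e-9, by = cycle)
    tt + stats::rnorm(length(tt), 0, params$step_cv * step_p)
  }
  tL <- sort(nominal(0))
  tR <- sort(nominal(step_p))
  draw_amp <- function(m, k) m * pmax(0.3, 1 + stats::rnorm(k, 0, params$amp_cv))
  aL <- draw_amp(params$amp_left, length(tL))
  aR <- draw_amp(params$amp_right * params$asymmetry, length(tR))

  side_clean <- function(tt, aa) {
    v <- add_bumps(numeric(n), fs, tt, aa, sigma)
    if (length(tt) > 1L) {
      mids <- (tt[-1] + tt[-length(tt)]) / 2
      st_amp <- -0.35 * (aa[-1] + aa[-length(aa)]) / 2
      v <- add_bumps(v, fs, mids, st_amp, 0.15 * cycle)
    }
    v
  }
  cL <- side_clean(tL, aL)
  cR <- side_clean(tR, aR)
  msL <- truth_from_clean(cL, fs, tL, sigma)
  msR <- truth_from_clean(cR, fs, tR, sigma)

  tgrid <- (seq_len(n) - 1L) / fs
  noisy <- function(cl) {
    cl + stats::rnorm(n, 0, noise_sd) + (drift / 60) * tgrid
  }
  filt <- (drift == 0)
  list(
    left = pitch_signal(noisy(cL), fs, "left", "raw-axis", filtered = filt),
    right = pitch_signal(noisy(cR), fs, "right", "raw-axis", filtered = filt),
    clean = list(left = cL, right = cR),
    truth = list(
      ms_left = msL, ms_right = msR,
      cycle_speeds = params$speed *
        (1 + stats::rnorm(min(length(tL), length(tR)), 0, params$speed_cv))
    )
  )
}

confounder_defaults <- function(activity) {
  switch(activity,
    swing = list(amp = 150, period = 1.4, sync_offset = 0.05, jitter_cv = 0.01,
                 width_frac = 0.1),
    run = list(amp = 260, cycle = 0.7, step_cv = 0.03, width_frac = 0.05),
    stairs = list(amp = 60, cycle = 1.2, step_cv = 0.03, width_frac = 0.06),
    sit = list(noise_sd = 4),
    stop_param(sprintf("unknown confounder activity: %s", activity))
  )
}

#' Simulate a non-walking confounder segment
#'
#' * `swing`: bilateral synchronous high-amplitude peaks (legs swinging
#'   together), same-side period longer than typical gait cycles;
#' * `run`: high-amplitude alternating peaks with short periods;
#' * `stairs`: gait-like alternation but lower amplitude and slower;
#' * `sit`: low-amplitude noise only.
#'
#' All are labeled `non_walking`.
#'
#' @param activity one of `"swing"`, `"run"`, `"stairs"`, `"sit"`.
#' @param duration segment duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed, or `NULL` to continue from the current RNG state.
#' @param params optional overrides of the activity defaults (see
#'   `confounder_defaults`).
#' @param noise_sd white noise standard deviation in deg/s.
#' @return list with `left`/`right` pitch signals, `clean` values, `activity`
#'   and `category = "non_walking"`.
#' @export
simulate_confounder <- function(activity, duration, fs = 100, seed = NULL,
                                params = list(), noise_sd = 3) {
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(confounder_defaults(activity), params)
  n <- round(duration * fs)
  tgrid <- (seq_len(n) - 1L) / fs
  if (activity == "sit") {
    cL <- numeric(n)
    cR <- numeric(n)
    nsd <- p$noise_sd
  } else if (activity == "swing") {
    sigma <- p$width_frac * p$period
    tt <- seq(2 * sigma, duration - 2 * sigma - p$sync_offset, by = p$period)
    tt <- sort(tt + stats::rnorm(length(tt), 0, p$jitter_cv * p$period))
    amps <- p$amp * (1 + stats::rnorm(length(tt), 0, 0.05))
    cL <- add_bumps(numeric(n), fs, tt, amps, sigma)
    cR <- add_bumps(numeric(n), fs, tt + p$sync_offset, amps, sigma)
    nsd <- noise_sd
  } else { # run, stairs: alternating gait-like trains
    sigma <- p$width_frac * p$cycle
    step_p <- p$cycle / 2
    mk <- function(offset) {
      tt <- seq(2 * sigma + offset, duration - 2 * sigma, by = p$cycle)
      sort(tt + stats::rnorm(length(tt), 0, p$step_cv * step_p))
    }
    tL <- mk(0)
    tR <- mk(step_p)
    cL <- add_bumps(numeric(n), fs, tL, p$amp * (1 + stats::rnorm(length(tL), 0, 0.05)), sigma)
    cR <- add_bumps(numeric(n), fs, tR, p$amp * (1 + stats::rnorm(length(tR), 0, 0.05)), sigma)
    nsd <- noise_sd
  }
  list(
    left = pitch_signal(cL + stats::rnorm(n, 0, nsd), fs, "left",
                        filtered = TRUE),
    right = pitch_signal(cR + stats::rnorm(n, 0, nsd), fs, "right",
                         filtered = TRUE),
    clean = list(left = cL, right = cR),
    activity = activity, category = "non_walking"
  )
}

activity_label_text <- function(activity) {
  switch(activity,
    lie = "lying", sit = "sitting", walk = "walking",
    walk_other = "walking on grass", stairs = "climbing stairs",
    run = "running", swing = "playing on swings", activity)
}

#' Define a daily-life-like activity scenario
#'
#' @param segments ordered list of segments, each
#'   `list(activity = , duration = , params = )` with activity one of
#'   `lie`, `sit`, `walk`, `walk_other`, `stairs`, `run`, `swing`. The first
#'   segment must be `lie` (recordings start in a predefined lying posture).
#' @param sampling_rate sampling rate in Hz.
#' @param noise_sd gyro white noise in deg/s.
#' @param drift gyro drift in deg/s per minute.
#' @param seed integer seed.
#' @return an object of class `gait_scenario`.
#' @export
gait_scenario <- function(segments, sampling_rate = 100, noise_sd = 3,
                          drift = 0.5, seed = 1) {
  if (!length(segments)) stop_config("scenario has no segments")
  for (sg in segments) {
    if (is.null(sg$activity) || is.null(sg$duration) || sg$duration <= 0) {
      stop_config("each segment needs an activity and a positive duration")
    }
  }
  if (segments[[1]]$activity != "lie") {
    stop_config("the first scenario segment must be 'lie'")
  }
  structure(
    list(segments = segments, sampling_rate = sampling_rate,
         noise_sd = noise_sd, drift = drift, seed = seed),
    class = "gait_scenario"
  )
}

#' A small default scenario
#'
#' Lying, walking bouts on regular and irregular surfaces, playing on swings
#' and sitting.
#'
#' @param seed integer seed.
#' @return a [gait_scenario()].
#' @export
default_scenario <- function(seed = 1) {
  gait_scenario(list(
    list(activity = "lie", duration = 5),
    list(activity = "walk", duration = 40),
    list(activity = "swing", duration = 20),
    list(activity = "sit", duration = 10),
    list(activity = "walk", duration = 30),
    list(activity = "walk_other", duration = 25)
  ), seed = seed)
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

#' Simulate a full out-of-laboratory protocol
#'
#' Concatenates the scenario segments into continuous left/right recordings:
#' the pitch waveform is embedded into 3-axis gyro channels through a fixed
#' random sensor rotation (so that the PCA alignment step is exercised), a
#' global linear drift is added, and the accelerometer shows a static 1 g
#' norm during the initial lying posture. Ground truth (labels, true midswing
#' events, true bouts, per-cycle speeds) is emitted alongside.
#'
#' @param scenario a [gait_scenario()].
#' @return list with `left`/`right` ([raw_recording()]s) and `truth`: a list
#'   with `labels` (activity intervals with categories), `ms_left`/`ms_right`
#'   (true midswing events), `bouts` (true walking bouts with per-cycle
#'   speeds), `clean` (noise-free pitch values per side) and `duration`.
#' @export
simulate_protocol <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  set.seed(scenario$seed)
  fs <- scenario$sampling_rate
  pL <- numeric(0)
  pR <- numeric(0)
  clL <- numeric(0)
  clR <- numeric(0)
  labels <- data.frame(activity = character(0), start = numeric(0),
                       end = numeric(0), category = character(0),
                       stringsAsFactors = FALSE)
  msL <- midswing_events()
  msR <- midswing_events()
  bouts <- list()
  t_off <- 0
  accel_rows <- list()
  for (sg in scenario$segments) {
    act <- sg$activity
    dur <- sg$duration
    nseg <- round(dur * fs)
    tseg <- (seq_len(nseg) - 1L) / fs
    if (act == "lie") {
      l <- stats::rnorm(nseg, 0, 1)
      r <- stats::rnorm(nseg, 0, 1)
      cl <- numeric(nseg)
      cr <- numeric(nseg)
      cat_ <- "non_walking"
      acc <- cbind(stats::rnorm(nseg, 0, 0.005), stats::rnorm(nseg, 0, 0.005),
                   1 + stats::rnorm(nseg, 0, 0.005))
    } else if (act %in% c("walk", "walk_other")) {
      prm <- sg$params %||% if (act == "walk") walk_params() else {
        utils::modifyList(walk_params(), list(cadence = 98, amp_left = 180,
                                              amp_right = 180, amp_cv = 0.12,
                                              step_cv = 0.06, speed = 1.0))
      }
      seg <- simulate_walk_segment(prm, dur, fs, seed = NULL,
                                   noise_sd = scenario$noise_sd, drift = 0)
      l <- seg$left$values
      r <- seg$right$values
      cl <- seg$clean$left
      cr <- seg$clean$right
      cat_ <- if (act == "walk") "straight_walking" else "other_walking"
      ev_l <- seg$truth$ms_left
      ev_r <- seg$truth$ms_right
      ev_l$time <- ev_l$time + t_off
      ev_r$time <- ev_r$time + t_off
      msL <- rbind(msL, midswing_events(ev_l$time, ev_l$amplitude,
                                        rep("left", nrow(ev_l))))
      msR <- rbind(msR, midswing_events(ev_r$time, ev_r$amplitude,
                                        rep("right", nrow(ev_r))))
      ev <- rbind(
        midswing_events(ev_l$time, ev_l$amplitude, rep("left", nrow(ev_l))),
        midswing_events(ev_r$time, ev_r$amplitude, rep("right", nrow(ev_r)))
      )
      ev <- ev[order(ev$time), ]
      bouts[[length(bouts) + 1L]] <- list(
        events = ev, start = t_off, end = t_off + dur,
        n_steps = nrow(ev), n_cycles = min(nrow(ev_l), nrow(ev_r)),
        cycle_speeds = seg$truth$cycle_speeds
      )
      acc <- moving_accel(nseg, fs)
    } else {
      seg <- simulate_confounder(act, dur, fs, seed = NULL,
                                 noise_sd = scenario$noise_sd)
      l <- seg$left$values
      r <- seg$right$values
      cl <- seg$clean$left
      cr <- seg$clean$right
      cat_ <- "non_walking"
      acc <- moving_accel(nseg, fs)
    }
    labels <- rbind(labels, data.frame(
      activity = activity_label_text(act), start = t_off, end = t_off + dur,
      category = cat_, stringsAsFactors = FALSE))
    pL <- c(pL, l)
    pR <- c(pR, r)
    clL <- c(clL, cl)
    clR <- c(clR, cr)
    accel_rows[[length(accel_rows) + 1L]] <- acc
    t_off <- t_off + dur
  }
  n <- length(pL)
  tgrid <- (seq_len(n) - 1L) / fs
  pL <- pL + (scenario$drift / 60) * tgrid
  pR <- pR + (scenario$drift / 60) * tgrid
  accel <- do.call(rbind, accel_rows)
  embed <- function(p, side) {
    u <- random_rotation()[, 1]
    gyro <- outer(p, u) + matrix(stats::rnorm(3 * n, 0, 1.5), ncol = 3)
    raw_recording(gyro, sampling_rate = fs, side = side,
                  sensor_id = paste0("sim_", side), accel = accel, t0 = 0)
  }
  class(labels) <- c("activity_labels", class(labels))
  list(
    left = embed(pL, "left"),
    right = embed(pR, "right"),
    truth = list(labels = labels, ms_left = msL, ms_right = msR,
                 bouts = bouts, clean = list(left = clL, right = clR),
                 duration = t_off)
  )
}

# Accelerometer during movement: 1 g base plus an oscillation large enough
# that the norm never stays within the lying tolerance for seconds.
moving_accel <- function(nseg, fs) {
  tseg <- (seq_len(nseg) - 1L) / fs
  ph <- stats::runif(1, 0, 2 * pi)
  cbind(0.25 * sin(2 * pi * 0.9 * tseg + ph) + stats::rnorm(nseg, 0, 0.05),
        stats::rnorm(nseg, 0, 0.05),
        1 + 0.2 * sin(2 * pi * 1.3 * tseg + ph) + stats::rnorm(nseg, 0, 0.05))
}

#' Simulate supervised laboratory gait trials
#'
#' Straight-walking trials at three self-selected speeds (slow, spontaneous,
#' fast) with speed-dependent cadence and amplitude scaling, low noise and no
#' drift — the in-clinic data from which thresholds are tuned. Ground-truth
#' feature extremes are returned for parameter-recovery tests.
#'
#' @param params subject parameters, see [walk_params()].
#' @param n_trials trials per speed (default 4, i.e. 12 trials total).
#' @param trial_duration seconds per trial (default 12, a short walkway pass).
#' @param fs sampling rate in Hz.
#' @param noise_sd white noise in deg/s (default 0.5; supervised lab trials
#'   are clean).
#' @param seed integer seed, or `NULL` to continue from the current RNG state.
#' @return list with `trials` (each `list(left, right, speed)`) and `truth`
#'   (per-side `min_amplitude`, `min_interval`, `max_interval`, plus
#'   `max_inter_side`).
#' @export
simulate_lab_trials <- function(params = walk_params(), n_trials = 4,
                                trial_duration = 12, fs = 100, noise_sd = 0.5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_trials < 1) stop_param("n_trials must be >= 1")
  speed_defs <- list(slow = c(cad = 0.9, amp = 0.85),
                     spontaneous = c(cad = 1, amp = 1),
                     fast = c(cad = 1.2, amp = 1.15))
  trials <- list()
  tr_truth <- list(left = list(amp = numeric(0), ss = numeric(0)),
                   right = list(amp = numeric(0), ss = numeric(0)))
  inter <- numeric(0)
  for (sp in names(speed_defs)) {
    f <- speed_defs[[sp]]
    prm <- params
    prm$cadence <- params$cadence * f[["cad"]]
    prm$amp_left <- params$amp_left * f[["amp"]]
    prm$amp_right <- params$amp_right * f[["amp"]]
    for (i in seq_len(n_trials)) {
      seg <- simulate_walk_segment(prm, trial_duration, fs, seed = NULL,
                                   noise_sd = noise_sd, drift = 0)
      trials[[length(trials) + 1L]] <-
        list(left = seg$left, right = seg$right, speed = sp)
      for (s in c("left", "right")) {
        ms <- seg$truth[[paste0("ms_", s)]]
        tr_truth[[s]]$amp <- c(tr_truth[[s]]$amp, ms$amplitude)
        if (nrow(ms) > 1L) tr_truth[[s]]$ss <- c(tr_truth[[s]]$ss, diff(ms$time))
      }
      merged <- rbind(
        data.frame(time = seg$truth$ms_left$time, side = "left"),
        data.frame(time = seg$truth$ms_right$time, side = "right"))
      merged <- merged[order(merged$time), ]
      gaps <- diff(merged$time)
      alt <- merged$side[-1] != merged$side[-nrow(merged)]
      inter <- c(inter, gaps[alt])
    }
  }
  truth <- list(
    left = list(min_amplitude = min(tr_truth$left$amp),
                min_interval = min(tr_truth$left$ss),
                max_interval = max(tr_truth$left$ss)),
    right = list(min_amplitude = min(tr_truth$right$amp),
                 min_interval = min(tr_truth$right$ss),
                 max_interval = max(tr_truth$right$ss)),
    max_inter_side = max(inter)
  )
  list(trials = trials, truth = truth)
}
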