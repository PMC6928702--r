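test_that("threshold_set validates and carries the printed defaults", {
  th <- init_thresholds()
  expect_equal(th$mode, "init")
  expect_error(threshold_set(th2 = 2, th3 = 1),
               class = "gaitbouts_parameter_error")
  expect_error(threshold_set(th1_left = -5),
               class = "gaitbouts_parameter_error")
  # no ordering required between th3 and th4 (group extremes can invert it)
  expect_silent(threshold_set(th1_left = 109, th2 = 0.64, th3 = 3.53,
                              th4 = 1.88, mode = "pop"))
})

test_that("find_midswing_candidates keeps strict local maxima above th1", {
  # two isolated bumps, 60 and 40 deg/s, th1 = 50 -> only the 60 bump
  sig <- bump_signal(c(1, 2.5), c(60, 40), 4)
  ev <- find_midswing_candidates(sig, 50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, 1, tolerance = 0.011)
  expect_equal(ev$side, "left")

  # everywhere below th1 -> empty
  expect_equal(nrow(find_midswing_candidates(sig, 100)), 0)

  # strictly monotone ramp has no interior maxima
  ramp <- pitch_signal(seq(0, 200, length.out = 100), 100, "left",
                       filtered = TRUE)
  expect_equal(nrow(find_midswing_candidates(ramp, 10)), 0)

  # unfiltered signal warns but still returns events
  raw <- pitch_signal(sig$values, 100, "left", filtered = FALSE)
  expect_warning(find_midswing_candidates(raw, 50),
                 class = "gaitbouts_unfiltered_signal")
})

test_that("deduplicate_within_th2 keeps the cluster argmax", {
  ev <- data.frame(time = c(0, 0.3), amplitude = c(80, 100), side = "left")
  out <- deduplicate_within_th2(ev, 0.5)
  expect_equal(out$time, 0.3)

  # spacing above th2 left untouched
  ev2 <- data.frame(time = c(0, 0.6, 1.2), amplitude = c(80, 100, 90),
                    side = "left")
  expect_equal(nrow(deduplicate_within_th2(ev2, 0.5)), 3)

  # amplitude tie within a cluster keeps the earlier event
  ev3 <- data.frame(time = c(0, 0.2), amplitude = c(90, 90), side = "left")
  expect_equal(deduplicate_within_th2(ev3, 0.5)$time, 0)
})

test_that("deduplicate_within_th2 matches the brute-force cluster oracle", {
  set.seed(101)
  for (k in 1:300) {
    n <- sample(0:12, 1)
    ev <- random_event_stream(n, span = 4, sides = "left")
    th2 <- runif(1, 0.2, 1)
    got <- deduplicate_within_th2(ev, th2)
    want <- oracle_dedup(ev, th2)
    expect_equal(got$time, want$time)
    expect_equal(got$amplitude, want$amplitude)
    if (nrow(got) > 1) expect_true(all(diff(got$time) >= th2))
  }
})

test_that("adaptive_th4 follows the printed rule", {
  expect_equal(adaptive_th4(numeric(0)), 3.5)
  expect_equal(adaptive_th4(c(0.5, 0.7)), 2.1)
  expect_equal(adaptive_th4(0), 1.5)
  expect_equal(adaptive_th4(numeric(0), th4_initial = 1.88), 1.88)
  expect_error(adaptive_th4(c(0.5, -0.1)), class = "gaitbouts_data_error")
})

test_that("segment_bouts implements alternation / th3 / adaptive th4", {
  th <- init_thresholds()
  empty <- random_event_stream(0)
  expect_equal(segment_bouts(empty, empty, th), list())

  # perfect alternation every 0.55 s -> one bout of 10 steps
  tl <- seq(0, by = 1.1, length.out = 5)
  tr <- tl + 0.55
  msl <- data.frame(time = tl, amplitude = 100, side = "left")
  msr <- data.frame(time = tr, amplitude = 100, side = "right")
  b <- segment_bouts(msl, msr, th)
  expect_length(b, 1)
  expect_equal(b[[1]]$n_steps, 10)
  expect_equal(b[[1]]$n_cycles, 5)

  # same-side gap of 2.0 s (> th3) splits into two bouts
  tl2 <- c(0, 1.1, 3.1, 4.2)
  tr2 <- tl2 + 0.55
  b2 <- segment_bouts(data.frame(time = tl2, amplitude = 100, side = "left"),
                      data.frame(time = tr2, amplitude = 100, side = "right"),
                      th)
  expect_length(b2, 2)
  expect_equal(b2[[1]]$n_steps, 4)
  expect_equal(b2[[2]]$n_steps, 4)
})

test_that("segment_bouts equals the exhaustive maximal-run oracle", {
  set.seed(202)
  th <- init_thresholds()
  for (k in 1:300) {
    n <- sample(0:12, 1)
    ev <- random_event_stream(n)
    msl <- ev[ev$side == "left", ]
    msr <- ev[ev$side == "right", ]
    got <- segment_bouts(msl, msr, th)
    want <- oracle_segment(msl, msr, th)
    expect_true(bout_events_equal(got, want))
  }
})

test_that("detected bouts satisfy all structural invariants", {
  set.seed(303)
  th <- init_thresholds()
  for (k in 1:50) {
    ev <- random_event_stream(sample(4:12, 1))
    msl <- deduplicate_within_th2(ev[ev$side == "left", ], th$th2)
    msr <- deduplicate_within_th2(ev[ev$side == "right", ], th$th2)
    bouts <- segment_bouts(msl, msr, th)
    for (b in bouts) expect_true(validate_bout(b, th))
    # no event belongs to two bouts; events are a subset of the input
    all_t <- unlist(lapply(bouts, function(b) b$events$time))
    expect_equal(anyDuplicated(all_t), 0)
    expect_true(all(all_t %in% c(msl$time, msr$time)))
  }
})

test_that("segmentation is deterministic and monotone in th1", {
  set.seed(404)
  seg <- simulate_walk_segment(walk_params(), 15, seed = 99)
  b1 <- detect_walking_bouts(seg$left, seg$right)
  b2 <- detect_walking_bouts(seg$left, seg$right)
  expect_identical(b1, b2)

  # lowering th1 never decreases the number of candidate events
  n_lo <- nrow(find_midswing_candidates(seg$left, 30))
  n_hi <- nrow(find_midswing_candidates(seg$left, 120))
  expect_gte(n_lo, n_hi)

  # zero signals -> no bouts
  z <- pitch_signal(numeric(1000), 100, "left", filtered = TRUE)
  zr <- pitch_signal(numeric(1000), 100, "right", filtered = TRUE)
  expect_length(detect_walking_bouts(z, zr), 0)
})

test_that("enlarging th3/th4 only relaxes run validity", {
  # Bout COUNT is not monotone in th3/th4 for the restart semantics (the
  # adaptive th4 depends on the run history, so restart positions shift).
  # What does hold: every window valid under the tighter thresholds stays
  # valid under the wider ones, hence the first maximal run never shrinks.
  set.seed(505)
  for (k in 1:100) {
    ev <- random_event_stream(sample(4:12, 1))
    msl <- ev[ev$side == "left", ]
    msr <- ev[ev$side == "right", ]
    base <- threshold_set(th2 = 0.2, th3 = runif(1, 0.5, 1.5),
                          th4 = runif(1, 0.5, 2))
    wider <- threshold_set(th2 = 0.2, th3 = base$th3 + 1, th4 = base$th4 + 1)
    merged <- rbind(msl, msr)
    merged <- merged[order(merged$time, merged$side), , drop = FALSE]
    rownames(merged) <- NULL
    n <- nrow(merged)
    for (i in seq_len(max(0, n - 1))) {
      for (j in (i + 1):n) {
        if (oracle_valid_window(merged, i, j, base)) {
          expect_true(oracle_valid_window(merged, i, j, wider))
        }
      }
    }
    b1 <- segment_bouts(msl, msr, base)
    b2 <- segment_bouts(msl, msr, wider)
    if (length(b1) && length(b2) &&
        b1[[1]]$events$time[1] == b2[[1]]$events$time[1]) {
      expect_gte(b2[[1]]$n_steps, b1[[1]]$n_steps)
    }
  }
})

test_that("filter_min_steps applies the 4-step rule inclusively", {
  mk <- function(n) {
    tt <- seq(0, by = 0.55, length.out = n)
    sides <- rep(c("left", "right"), length.out = n)
    ev <- data.frame(time = tt, amplitude = 100, side = sides)
    segment_bouts(ev[ev$side == "left", ], ev[ev$side == "right", ],
                  init_thresholds())[[1]]
  }
  bouts <- list(mk(3), mk(4), mk(7))
  kept <- filter_min_steps(bouts)
  expect_length(kept, 2)
  expect_equal(vapply(kept, `[[`, integer(1), "n_steps"), c(4L, 7L))
  expect_length(filter_min_steps(list()), 0)
})

test_that("threshold sets round-trip through JSON", {
  th <- threshold_set(th1_left = 80, th1_right = 75, th2 = 0.7, th3 = 1.9,
                      th4 = 1.2, mode = "indiv",
                      metadata = list(per_side = list(
                        left = list(th1 = 80, th2 = 0.7, th3 = 1.8),
                        right = list(th1 = 75, th2 = 0.72, th3 = 1.9))))
  p <- tempfile(fileext = ".json")
  write_thresholds(th, p)
  back <- read_thresholds(p)
  expect_equal(back$th1_right, 75)
  expect_equal(back$metadata$per_side$right$th3, 1.9)
  expect_equal(back$mode, "indiv")
})
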