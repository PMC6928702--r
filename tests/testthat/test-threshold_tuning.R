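test_that("extract_lab_features recovers simulator feature extremes", {
  lab <- simulate_lab_trials(walk_params(), n_trials = 4, seed = 31)
  fe <- extract_lab_features(lab$trials, "s1")
  for (s in c("left", "right")) {
    tr <- lab$truth[[s]]
    expect_lt(abs(min(fe[[s]]$ms_amplitudes) - tr$min_amplitude) /
                tr$min_amplitude, 0.02)
    expect_lte(abs(min(fe[[s]]$same_side_intervals) - tr$min_interval), 0.02)
    expect_lte(abs(max(fe[[s]]$same_side_intervals) - tr$max_interval), 0.02)
  }
  expect_lte(abs(max(fe$left$inter_side_intervals) - lab$truth$max_inter_side),
             0.02)
})

test_that("extract_lab_features handles regular and degenerate trials", {
  # three evenly spaced identical peaks: all same-side intervals equal
  sig <- bump_signal(c(1, 2.1, 3.2), rep(150, 3), 4.5)
  sigr <- bump_signal(c(1.55, 2.65), rep(150, 2), 4.5, side = "right")
  fe <- extract_lab_features(list(list(left = sig, right = sigr)), "s2")
  expect_equal(min(fe$left$same_side_intervals),
               max(fe$left$same_side_intervals))
  expect_equal(min(fe$left$same_side_intervals), 1.1, tolerance = 0.011)

  # flat signals -> tuning failure naming the subject
  flat <- pitch_signal(numeric(500), 100, "left", filtered = TRUE)
  flatr <- pitch_signal(numeric(500), 100, "right", filtered = TRUE)
  expect_error(
    extract_lab_features(list(list(left = flat, right = flatr)), "s3"),
    class = "gaitbouts_tuning_error")
  expect_error(extract_lab_features(list(), "s4"),
               class = "gaitbouts_tuning_error")
})

make_features <- function(id, side, amps, ss, inter, smax) {
  # build lab features directly from stated numbers via a single-trial signal
  # is overkill here; go through the internal constructor
  gaitbouts:::lab_gait_features(id, side, amps, ss, inter, smax)
}

test_that("pop_thresholds reproduces published group-extreme examples", {
  # group whose pooled extremes equal the reported impaired-group extremes
  m1 <- make_features("a", "left", c(109, 180), c(0.64, 1.0), c(0.8, 1.88), 320)
  m2 <- make_features("b", "left", c(150, 200), c(0.8, 3.53), c(0.7, 1.2), 350)
  th <- pop_thresholds(list(m1, m2), "CP-like")
  expect_equal(th$th1_left, 109)
  expect_equal(th$th2, 0.64)
  expect_equal(th$th3, 3.53)
  expect_equal(th$th4, 1.88)
  expect_equal(th$mode, "pop")

  # typical-development-like extremes
  t1 <- make_features("c", "left", c(193, 260), c(0.67, 1.2), c(0.6, 0.99), 400)
  t2 <- make_features("d", "left", c(240, 300), c(0.7, 1.92), c(0.56, 0.8), 420)
  th2 <- pop_thresholds(list(t1, t2))
  expect_equal(th2$th1_left, 193)
  expect_equal(th2$th2, 0.67)
  expect_equal(th2$th3, 1.92)
  expect_equal(th2$th4, 0.99)

  # a single-member group equals that member's own extremes
  th3 <- pop_thresholds(list(m1))
  expect_equal(th3$th1_left, 109)
  expect_equal(th3$th3, 1.0)
})

test_that("pop_thresholds equals element-wise min/max and only relaxes", {
  set.seed(41)
  rand_feat <- function(id) {
    make_features(id, sample(c("left", "right"), 1),
                  runif(4, 80, 300), sort(runif(3, 0.5, 2)),
                  runif(3, 0.3, 1.5), 400)
  }
  members <- lapply(letters[1:5], rand_feat)
  th <- pop_thresholds(members)
  expect_equal(th$th1_left,
               min(sapply(members, function(f) min(f$ms_amplitudes))))
  expect_equal(th$th2,
               min(sapply(members, function(f) min(f$same_side_intervals))))
  expect_equal(th$th3,
               max(sapply(members, function(f) max(f$same_side_intervals))))
  expect_equal(th$th4,
               max(sapply(members, function(f) max(f$inter_side_intervals))))
  # never stricter than any member's extremes; adding a member only relaxes
  for (f in members) {
    expect_lte(th$th1_left, min(f$ms_amplitudes))
    expect_lte(th$th2, min(f$same_side_intervals))
    expect_gte(th$th3, max(f$same_side_intervals))
    expect_gte(th$th4, max(f$inter_side_intervals))
  }
  th_plus <- pop_thresholds(c(members, list(rand_feat("z"))))
  expect_lte(th_plus$th1_left, th$th1_left)
  expect_lte(th_plus$th2, th$th2)
  expect_gte(th_plus$th3, th$th3)
  expect_gte(th_plus$th4, th$th4)
})

test_that("indiv_thresholds implements the amplitude-renormalized formula", {
  fl <- make_features("s", "left", c(120, 200), c(0.9, 1.2), c(0.5, 0.7), 300)
  fr <- make_features("s", "right", c(130, 210), c(0.95, 1.25), c(0.5, 0.7), 310)

  # out-lab P95 = 200 with lab min 120 / lab max 300 -> th1 = 80
  mk_sig <- function(p95val, side) {
    # constant positive plateau: the 95th percentile of the positive part is
    # the plateau value
    pitch_signal(rep(p95val, 500), 100, side, filtered = TRUE)
  }
  th <- indiv_thresholds(fl, fr, mk_sig(200, "left"), mk_sig(200, "right"))
  expect_equal(th$th1_left, 80)
  expect_equal(th$th1_right, 130 / 310 * 200)
  expect_equal(th$mode, "indiv")
  # shared fields are the permissive envelope; per-side values retained
  expect_equal(th$th2, 0.9)
  expect_equal(th$th3, 1.25)
  expect_equal(th$th4, 0.7)
  expect_equal(th$metadata$per_side$right$th2, 0.95)

  # out-lab P95 equal to the lab max: the ratio cancels exactly
  th2 <- indiv_thresholds(fl, fr, mk_sig(300, "left"), mk_sig(310, "right"))
  expect_equal(th2$th1_left, 120)
  expect_equal(th2$th1_right, 130)

  # th1 scales linearly with the out-of-lab P95
  th3 <- indiv_thresholds(fl, fr, mk_sig(100, "left"), mk_sig(100, "right"))
  expect_equal(th3$th1_left * 2, th$th1_left)

  # degenerate out-lab signal -> tuning failure
  neg <- pitch_signal(rep(-5, 500), 100, "left", filtered = TRUE)
  expect_error(indiv_thresholds(fl, fr, neg, mk_sig(200, "right")),
               class = "gaitbouts_tuning_error")
})

test_that("indiv th1 reflects simulated per-side asymmetry", {
  # low-variability subject so the test probes the ratio propagation itself,
  # not the sampling noise of the min/percentile statistics
  prm <- walk_params(amp_left = 220, amp_right = 150, amp_cv = 0.03,
                     step_cv = 0.03)
  lab <- simulate_lab_trials(prm, n_trials = 3, seed = 77)
  fe <- extract_lab_features(lab$trials, "asym")
  out <- simulate_walk_segment(prm, 90, seed = 78)
  th <- indiv_thresholds(fe$left, fe$right, out$left, out$right)
  # per-side thresholds mirror the generator's amplitude ratio within 5%
  want <- 150 / 220
  expect_lt(abs(th$th1_right / th$th1_left - want) / want, 0.05)
  expect_lt(th$th1_right, th$th1_left)
})

test_that("tuned thresholds admit held-out walking at the same parameters", {
  lab <- simulate_lab_trials(walk_params(), n_trials = 4, seed = 55)
  fe <- extract_lab_features(lab$trials, "s")
  held <- simulate_walk_segment(walk_params(), 30, seed = 56)
  th <- indiv_thresholds(fe$left, fe$right, held$left, held$right)
  bouts <- detect_walking_bouts(held$left, held$right, th)
  det_times <- sort(unlist(lapply(bouts, function(b) b$events$time)))
  truth_times <- sort(c(held$truth$ms_left$time, held$truth$ms_right$time))
  matched <- vapply(truth_times,
                    function(tt) any(abs(det_times - tt) <= 0.05), logical(1))
  expect_true(all(matched))
})
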