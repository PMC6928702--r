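---
title: "Walking-bout detection from shank gyroscopes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking-bout detection from shank gyroscopes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The detection model

A shank-mounted gyroscope measures angular velocity about three axes. During
the swing phase of a step the shank rotates forward about the medio-lateral
axis, so the pitch component `ω_z` shows one sharp positive peak per stride —
the *midswing* (MS) event — followed by a broad, shallower negative excursion
during stance. Walking is a strictly alternating left/right sequence of such
peaks. The detector operationalizes this with four thresholds:

* **Th1** (°/s): candidate peaks must be strict local maxima with amplitude
  above Th1 (default 50 °/s, one value per side).
* **Th2** (s): same-side peaks closer than Th2 (default 0.5 s) are
  duplicates; only the highest survives.
* **Th3** (s): a same-side gap above Th3 (default 1.5 s) ends the bout — a
  gait cycle should not be longer than that.
* **Th4** (s): adjacent opposite-side peaks must be within Th4. For the
  first pair of a bout the fixed value applies (default 3.5 s); afterwards
  the bound adapts to the gait observed so far:
  `Th4_adaptive = 1.5 s + mean(step intervals in the bout)`.

A candidate bout grows event by event through a merged, time-ordered stream
of both sides. Any violated constraint ends the bout at the previous event;
the violating event seeds the next candidate. Runs shorter than two events
are dropped (Th4 is defined on a pair), and only bouts of at least four
steps proceed to the walking-speed stage (`filter_min_steps()`).

### Assumptions

* The sensor's pitch axis can be recovered by projecting the 3-axis gyro
  onto its first principal axis — i.e. most angular-velocity variance during
  movement is sagittal. This weakens for strongly frontal/transverse gait.
* Midswing peaks point *up* after alignment. The sign is fixed so that the
  mean of the largest 10 % of prominent signal excursions is positive. The
  prominence gate (10 % of the absolute maximum) matters: broad stance lobes
  carry many small noise-riding extrema which would otherwise outvote the
  sharp midswing peaks.
* The recording is drift-free after high-pass filtering, and peak *timing*
  is unbiased — hence a zero-phase (forward–backward) filter.

## Threshold customization

Supervised straight-walking trials at slow, spontaneous and fast speeds
provide, per subject and side: midswing amplitudes, same-side intervals,
opposite-side intervals, and the signal maximum. Lab peak extraction uses a
prominence criterion (default 20 % of the trial's 95th percentile of the
positive signal) rather than an amplitude threshold — the trials are
supervised, so every prominent positive peak is a true midswing; this
replaces a manual visual check with simulator-ground-truth tests.

* **Pop**: to be as inclusive as possible, thresholds are the *group
  extremes* — Th1 and Th2 the group minima, Th3 and Th4 the group maxima.
  Adding a member can only relax a Pop threshold set (a tested invariant).
* **Indiv**: per side `s`,
  `Th1_s = (min lab MS amplitude_s / max lab signal_s) × P95(out-of-lab ω_z_s)`,
  because absolute amplitudes differ between a clean lab walkway and daily
  life; the ratio cancels exactly when the out-of-lab P95 equals the lab
  maximum (a tested identity). Timing thresholds are the per-side lab
  extremes. The shared `threshold_set` fields hold the permissive envelope
  of the two sides; exact per-side values ride along in
  `metadata$per_side` and are applied during deduplication and same-side
  validation, which is what lets the detector respect asymmetric gait.

Design choices made where the formulas were open, all documented here
rather than configurable into oblivion:

* `P95` and the lab signal maximum are computed on the **positive part** of
  the filtered pitch signal: midswing peaks are positive, and the negative
  stance lobes would otherwise distort the amplitude scale.
* Features are pooled across all lab speeds and trials; Th4 uses the pooled
  maximum regardless of direction (right→left vs left→right).

## Evaluation

Scoring is sample-wise (default 10 Hz) against interval activity labels,
walking = `straight_walking ∪ other_walking`. Reference transitions carry a
symmetric exclusion zone of ± tolerance (default 2 s, absorbing manual
video–sensor synchronization error); excluded samples are not counted. A
transition's time is the time of the first sample with the new value; with
tolerance 0 the scheme reduces to a plain confusion matrix. Metrics with a
zero denominator are reported as `NA`, never as 0 or 1. Per-sample, the
implementation is verified against a brute-force counting oracle.

## Speed statistics

`summarize_speeds()` reports n, mean, SD, median, min, max, quartiles,
skewness and kurtosis. Numerical conventions, chosen once:

* quantiles: type-7 linear interpolation (R default);
* kurtosis: **raw** (normal ≈ 3), not excess — the descriptor tables this
  mirrors sit near 3 for normal-looking distributions;
* skewness/kurtosis are `NA` for n < 3 or zero variance.

`compare_distributions()` gates on Shapiro–Wilk normality (α = 0.05 per
sample, deterministic thinning above the test's 5000-sample limit): any
departure routes to an unpaired Wilcoxon rank-sum test, otherwise an F-test
chooses between pooled and Welch two-sample t-tests. Type-I error and power
are checked by Monte-Carlo in the acceptance suite.

## The synthetic generator

`simulate_walk_segment()` builds, per side, a train of positive Gaussian
midswing peaks (width σ = 5 % of the gait-cycle period) with broad negative
stance lobes (amplitude −0.35 × peak, σ = 15 % of the cycle) halfway
between same-side peaks, left/right offset by one step period, per-step
amplitude and timing jitter (CVs), white noise and linear drift. Ground
truth records the clean-signal argmax per peak. Defaults describe a typical
spontaneous pediatric gait: cadence 109 steps/min, 200 °/s peaks, 8 %
amplitude CV, 4 % step-time CV; `cp_walk_params()` is a preset with lower
amplitude, higher variability and asymmetry — a parameter preset, not a
clinical claim. Lab trials use noise SD 0.5 °/s (supervised, clean
walkway conditions); out-of-lab protocols default to 3 °/s plus
0.5 °/s·min⁻¹ drift.

Confounders reproduce the failure modes that motivate personalization:

* **swing** — bilateral *synchronous* high-amplitude peaks (150 °/s, period
  1.4 s): passes the fixed Th1/Th3 envelope but violates an individually
  tuned Th3;
* **stairs** — gait-like alternation at 60 °/s: above the fixed Th1 = 50
  but below tuned amplitude thresholds;
* **run** — high amplitude, short periods; **sit** — sub-20 °/s noise.

Protocols embed the pitch trace into 3-axis gyro channels through a fixed
random rotation (exercising PCA alignment), emit a static 1 g accelerometer
norm during the initial lying posture, and label every segment.

**What a green test does and does not establish.** The generator is
waveform-faithful only in the features the detector uses — peak amplitude,
timing, alternation — not biomechanically. Real recordings add
soft-tissue artifacts, turning, shuffling, sensor re-donning, and label
noise; passing the simulator suite shows the algorithms implement their
stated rules and reproduce the *mechanism* of the specificity ordering
(Indiv ≥ Pop ≥ Init under swing/stairs confounders, all sensitivities
≥ 0.95), not that the same metric values would be attained on any
particular clinical cohort.

## Numerical and degenerate-input choices

* **Filter**: the drift remover is an order-4 Butterworth high-pass at
  0.3 Hz (both configurable), applied forward–backward with odd-reflection
  padding — DC and drift are removed while the 0.5–3 Hz gait band and the
  peak timing are untouched. Coefficients are validated against an
  independent reference implementation of the same design.
* **Deduplication semantics**: clusters are *chains* — consecutive
  same-side gaps below Th2 merge — and each cluster keeps its
  highest-amplitude event (earlier on ties). Chain clustering is the only
  reading under which "no two surviving events closer than Th2" is
  guaranteed; clique-based grouping can violate it.
* **Merged-stream ties**: simultaneous left/right events order left-first —
  deterministic, and irrelevant above millisecond resolution.
* **Bout span**: walking physically extends beyond the first/last midswing,
  so bouts are padded by half the adjacent step interval on each end.
* **Bout-count monotonicity does not hold.** Widening Th3/Th4 only relaxes
  window validity (the first maximal run never shrinks — both tested), but
  because the adaptive Th4 depends on run history, restart positions shift
  and the *number* of bouts can increase. The suite tests the provable
  property instead.
* Zero-variance gyro input, flat lab trials, degenerate out-of-lab signals
  (P95 ≤ 0), empty speed samples, and overlapping labels all raise classed
  errors (`gaitbouts_*_error`); a missing lying posture is a classed
  warning with `NA`, letting callers proceed from t = 0.
* Configuration and threshold files are JSON (not YAML) so the package
  needs nothing beyond `jsonlite`.

## Known limitations

* The walking-speed *estimator* (double-pendulum model from shank + thigh
  gyros) is out of scope: speeds come from an external estimator or the
  simulator's ground truth.
* No stance/swing sub-phase segmentation, turning detection, or multi-day
  sensor re-donning handling.
* PCA alignment assumes a dominant sagittal axis; no magnetometer fusion.
* Whether per-cycle or per-bout speeds are pooled for distribution
  comparison is configurable by the caller; the simulator supplies
  per-cycle truth and per-bout means.
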