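# Reading raw shank recordings and producing the calibrated, filtered pitch
# angular velocity (omega_z of the shank) used by the bout detector.

#' Construct a raw sensor recording
#'
#' @param gyro numeric matrix, n x 3, tri-axial angular velocity in deg/s.
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param side `"left"` or `"right"` shank.
#' @param sensor_id free-text sensor identifier.
#' @param accel optional numeric matrix, n x 3, acceleration in g.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(gyro, sampling_rate = 100, side = c("left", "right"),
                          sensor_id = "", accel = NULL, t0 = 0) {
  side <- match.arg(side)
  gyro <- as.matrix(gyro)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_param("sampling_rate must be > 0")
  }
  if (nrow(gyro) == 0L) stop_data("gyro channels are empty")
  if (ncol(gyro) != 3L) stop_format("gyro must have 3 columns")
  if (!all(is.finite(gyro))) stop_data("gyro contains non-finite values")
  if (!is.null(accel)) {
    accel <- as.matrix(accel)
    if (nrow(accel) != nrow(gyro) || ncol(accel) != 3L) {
      stop_data("accel must match gyro dimensions (n x 3)")
    }
  }
  structure(
    list(sensor_id = sensor_id, side = side, sampling_rate = sampling_rate,
         gyro = gyro, accel = accel, t0 = t0),
    class = "raw_recording"
  )
}

#' Construct a pitch angular-velocity signal
#'
#' @param values 1-D angular velocity aligned to the medio-lateral axis (deg/s).
#' @param sampling_rate sampling rate in Hz.
#' @param side `"left"` or `"right"`.
#' @param provenance `"raw-axis"` or `"pca-aligned"`.
#' @param filtered logical; has the drift-removing high-pass been applied?
#' @param t0 time of the first sample in seconds.
#' @return an object of class `pitch_signal`.
#' @export
pitch_signal <- function(values, sampling_rate, side = c("left", "right"),
                         provenance = c("raw-axis", "pca-aligned"),
                         filtered = FALSE, t0 = 0) {
  side <- match.arg(side)
  provenance <- match.arg(provenance)
  structure(
    list(values = as.numeric(values), sampling_rate = sampling_rate,
         side = side, provenance = provenance, filtered = filtered, t0 = t0),
    class = "pitch_signal"
  )
}

#' @export
print.pitch_signal <- function(x, ...) {
  cat(sprintf("<pitch_signal> side=%s n=%d fs=%g Hz %s%s\n",
              x$side, length(x$values), x$sampling_rate, x$provenance,
              if (x$filtered) " (filtered)" else ""))
  invisible(x)
}

signal_times <- function(sig) {
  sig$t0 + (seq_along(sig$values) - 1L) / sig$sampling_rate
}

#' Default column-mapping schema for sensor CSV files
#'
#' @param time,gyro,accel column names; `accel = NULL` if absent.
#' @param side,sampling_rate,sensor_id recording metadata.
#' @param sep field separator (`","` or `"\t"`).
#' @return a schema list understood by [read_recording()].
#' @export
default_schema <- function(time = "time",
                           gyro = c("gyro_x", "gyro_y", "gyro_z"),
                           accel = c("accel_x", "accel_y", "accel_z"),
                           side = "left", sampling_rate = 100,
                           sensor_id = "", sep = ",") {
  list(time = time, gyro = gyro, accel = accel, side = side,
       sampling_rate = sampling_rate, sensor_id = sensor_id, sep = sep)
}

#' Read a raw sensor recording from CSV/TSV
#'
#' Verifies that the declared sampling rate matches the timestamps: the
#' maximum deviation of successive timestamp differences from the nominal
#' sample period must stay below half a period.
#'
#' @param path file path.
#' @param schema column mapping, see [default_schema()].
#' @return a [raw_recording()].
#' @export
read_recording <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, sep = schema$sep %||% ",", check.names = FALSE)
  needed <- c(schema$time, schema$gyro)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_format(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  tm <- as.numeric(df[[schema$time]])
  if (any(diff(tm) <= 0)) stop_data("timestamps are not strictly increasing")
  fs <- schema$sampling_rate
  period <- 1 / fs
  if (length(tm) > 1 && max(abs(diff(tm) - period)) >= period / 2) {
    stop_data(sprintf(
      "timestamp jitter exceeds half a sample period at %g Hz", fs))
  }
  gyro <- as.matrix(df[, schema$gyro, drop = FALSE])
  accel <- NULL
  if (!is.null(schema$accel) && all(schema$accel %in% names(df))) {
    accel <- as.matrix(df[, schema$accel, drop = FALSE])
  }
  raw_recording(gyro, sampling_rate = fs, side = schema$side,
                sensor_id = schema$sensor_id, accel = accel, t0 = tm[1])
}

#' Align the pitch axis by principal component analysis
#'
#' Projects the tri-axial angular velocity onto the first principal axis
#' estimated on `segment` (or the whole recording), so that the output tracks
#' rotation about the medio-lateral axis. The sign is fixed so that the mean
#' of the largest 10% (by magnitude) of local extrema is positive: midswing
#' peaks point up.
#'
#' @param recording a [raw_recording()].
#' @param segment optional `c(start, end)` window in seconds (recording time)
#'   on which the principal axis is estimated; projection is applied to the
#'   whole recording.
#' @return a [pitch_signal()] with `provenance = "pca-aligned"`.
#' @export
pca_align <- function(recording, segment = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  g <- recording$gyro
  fs <- recording$sampling_rate
  rows <- seq_len(nrow(g))
  if (!is.null(segment)) {
    tm <- recording$t0 + (rows - 1L) / fs
    rows <- which(tm >= segment[1] & tm < segment[2])
    if (length(rows) < 3L) stop_param("segment selects fewer than 3 samples")
  }
  sub <- g[rows, , drop = FALSE]
  if (max(apply(sub, 2, stats::var)) <= .Machine$double.eps) {
    stop_degenerate("zero-variance gyro input, cannot estimate principal axis")
  }
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  axis <- pc$rotation[, 1]
  centered <- sweep(g, 2, colMeans(sub))
  proj <- as.numeric(centered %*% axis)
  # Each prominent excursion votes once (prominence gate suppresses the many
  # noise-riding extrema on broad lobes); midswing peaks must point up.
  pk <- find_peaks(abs(proj), min_prominence = 0.1 * max(abs(proj)))
  ext <- proj[pk]
  if (length(ext)) {
    k <- max(1L, ceiling(0.1 * length(ext)))
    top <- ext[order(abs(ext), decreasing = TRUE)[seq_len(k)]]
    if (mean(top) < 0) proj <- -proj
  } else if (proj[which.max(abs(proj))] < 0) {
    proj <- -proj
  }
  pitch_signal(proj, sampling_rate = fs, side = recording$side,
               provenance = "pca-aligned", filtered = FALSE,
               t0 = recording$t0)
}

#' Butterworth high-pass filter coefficients
#'
#' Digital coefficients via the bilinear transform of the analog Butterworth
#' prototype (poles only, unity gain), matching the usual scientific-computing
#' conventions.
#'
#' @param order filter order.
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_highpass <- function(order, cutoff, fs) {
  if (order < 1) stop_param("order must be >= 1")
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    stop_param("cutoff must satisfy 0 < cutoff < fs/2")
  }
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LP prototype poles
  warped <- 4 * tan(pi * (cutoff / (fs / 2)) / 2)       # pre-warped (fs2 = 2)
  ph <- warped / p                                      # LP -> HP poles
  zh <- rep(0 + 0i, order)                              # HP zeros at s = 0
  kh <- Re(1 / prod(-p))                                # = 1 for Butterworth
  fs4 <- 4                                              # 2 * fs2
  zd <- (fs4 + zh) / (fs4 - zh)
  pd <- (fs4 + ph) / (fs4 - ph)
  kd <- kh * Re(prod(fs4 - zh) / prod(fs4 - ph))
  poly_from_roots <- function(r) {
    coefs <- 1 + 0i
    for (ri in r) coefs <- c(coefs, 0) - ri * c(0, coefs)
    coefs
  }
  list(b = Re(kd * poly_from_roots(zd)), a = Re(poly_from_roots(pd)))
}

# Direct IIR application, zero initial conditions (vectorized C via
# stats::filter: FIR part by convolution, feedback part recursively).
iir_apply <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(length(x) + nb - 1L)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Forward-backward filtering with odd-reflection padding so that transients
# decay inside the pads and peak times are not shifted.
filtfilt_ba <- function(x, b, a, padlen) {
  n <- length(x)
  padlen <- max(0L, min(as.integer(padlen), n - 2L))
  if (padlen > 0) {
    front <- 2 * x[1] - x[(padlen + 1):2]
    back <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xe <- c(front, x, back)
  } else {
    xe <- x
  }
  y <- iir_apply(xe, b, a)
  y <- rev(iir_apply(rev(y), b, a))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

#' Zero-phase high-pass filtering of a pitch signal
#'
#' Removes drift and DC offset with an order-`order` Butterworth high-pass
#' applied forward and backward (zero phase), so midswing peak times are
#' preserved.
#'
#' @param signal a [pitch_signal()].
#' @param cutoff cutoff frequency in Hz (default 0.3, well below the gait
#'   band of roughly 0.5-3 Hz).
#' @param order filter order (default 4).
#' @return the filtered [pitch_signal()] (`filtered = TRUE`).
#' @export
highpass_filter <- function(signal, cutoff = 0.3, order = 4) {
  stopifnot(inherits(signal, "pitch_signal"))
  fs <- signal$sampling_rate
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    stop_param("cutoff must satisfy 0 < cutoff < fs/2")
  }
  ba <- butter_highpass(order, cutoff, fs)
  padlen <- ceiling(3 * fs / cutoff)
  out <- signal
  out$values <- filtfilt_ba(signal$values, ba$b, ba$a, padlen)
  out$filtered <- TRUE
  out
}

#' Find the onset of the first sustained lying posture
#'
#' Out-of-laboratory recordings start with the participant lying still; on the
#' accelerometer this shows as a norm of about 1 g held for several seconds,
#' and is used to align the recording start.
#'
#' @param accel numeric matrix, n x 3, acceleration in g.
#' @param sampling_rate sampling rate in Hz.
#' @param min_duration minimum still duration in seconds (default 3).
#' @param target_norm expected acceleration norm in g (default 1).
#' @param tolerance allowed deviation from `target_norm` in g (default 0.05).
#' @return onset time in seconds from the first sample, or `NA` with a classed
#'   warning (`gaitbouts_not_found`) when no qualifying window exists.
#' @export
find_lying_onset <- function(accel, sampling_rate, min_duration = 3,
                             target_norm = 1, tolerance = 0.05) {
  if (is.null(accel)) stop_data("accel data required")
  accel <- as.matrix(accel)
  nrm <- sqrt(rowSums(accel^2))
  ok <- abs(nrm - target_norm) <= tolerance
  need <- ceiling(min_duration * sampling_rate)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) {
    warn_gb("gaitbouts_not_found",
            "no sustained lying window found; proceed from t = 0")
    return(NA_real_)
  }
  (starts[hit[1]] - 1L) / sampling_rate
}
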