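`%||%` <- function(x, y) if (is.null(x)) y else x

#' Indices of strict local maxima
#'
#' A sample is a strict local maximum when it exceeds both neighbours.
#' Endpoints and plateau samples are never maxima.
#'
#' @param v numeric vector.
#' @return integer vector of indices.
#' @keywords internal
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

local_minima <- function(v) local_maxima(-v)

#' Find peaks with a prominence criterion
#'
#' Strict local maxima whose topographic prominence (height above the higher
#' of the two flanking valleys, searched until a taller sample is met or the
#' signal ends) is at least `min_prominence`.
#'
#' @param v numeric vector.
#' @param min_prominence minimum prominence, same units as `v`.
#' @return integer vector of peak indices.
#' @export
find_peaks <- function(v, min_prominence = 0) {
  idx <- local_maxima(v)
  if (!length(idx) || min_prominence <= 0) return(idx)
  keep <- vapply(idx, function(i) {
    vi <- v[i]
    j <- i - 1L
    lmin <- vi
    while (j >= 1L && v[j] <= vi) {
      if (v[j] < lmin) lmin <- v[j]
      j <- j - 1L
    }
    j <- i + 1L
    rmin <- vi
    n <- length(v)
    while (j <= n && v[j] <= vi) {
      if (v[j] < rmin) rmin <- v[j]
      j <- j + 1L
    }
    (vi - max(lmin, rmin)) >= min_prominence
  }, logical(1))
  idx[keep]
}

# 95th percentile of the strictly positive part of a signal (type-7 quantile).
positive_p95 <- function(values) {
  pos <- values[values > 0]
  if (!length(pos)) return(NA_real_)
  as.numeric(stats::quantile(pos, 0.95, names = FALSE))
}
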