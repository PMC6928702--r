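# Walking-speed distribution descriptors and the normality-gated comparison
# of two detection methods' speed distributions.

#' Summarize a walking-speed sample
#'
#' Returns the descriptor set commonly reported for per-bout speed
#' distributions: n, mean, SD, median, minimum, maximum, quartiles (type-7
#' linear interpolation), skewness and raw kurtosis (normal ~ 3). Skewness
#' and kurtosis are `NA` when `n < 3` or the SD is zero.
#'
#' @param speeds numeric vector of walking speeds in m/s (positive, finite).
#' @return a list of class `distribution_summary`.
#' @export
summarize_speeds <- function(speeds) {
  speeds <- as.numeric(speeds)
  if (!length(speeds)) stop_data("empty speed sample")
  if (any(!is.finite(speeds)) || any(speeds <= 0)) {
    stop_data("speeds must be positive and finite")
  }
  n <- length(speeds)
  m <- mean(speeds)
  s <- if (n > 1) stats::sd(speeds) else 0
  qs <- as.numeric(stats::quantile(speeds, c(0.25, 0.5, 0.75), names = FALSE))
  if (n >= 3 && s > 0) {
    m2 <- mean((speeds - m)^2)
    skew <- mean((speeds - m)^3) / m2^1.5
    kurt <- mean((speeds - m)^4) / m2^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  structure(
    list(n = n, mean = m, sd = s, median = qs[2], minimum = min(speeds),
         maximum = max(speeds), q1 = qs[1], q3 = qs[3],
         skewness = skew, kurtosis = kurt),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "<distribution_summary> n=%d mean=%.3f sd=%.3f median=%.3f [%.3f, %.3f] q1=%.3f q3=%.3f skew=%.2f kurt=%.2f\n",
    x$n, x$mean, x$sd, x$median, x$minimum, x$maximum, x$q1, x$q3,
    x$skewness, x$kurtosis))
  invisible(x)
}

#' Compare two speed distributions with a normality gate
#'
#' Normality of each sample is assessed with the Shapiro-Wilk test (on a
#' deterministic thinning when n exceeds the test's 5000-sample limit). If
#' either sample departs from normality, an unpaired Wilcoxon rank-sum test
#' compares the distributions; otherwise an F-test compares variances and a
#' two-sample t-test follows (pooled when variances are compatible, Welch
#' otherwise).
#'
#' @param a,b numeric speed samples (each n >= 3).
#' @param alpha significance level for the comparison (default 0.05).
#' @param normality_alpha level of the Shapiro-Wilk gate (default 0.05).
#' @return list of class `comparison_result` with `test_used`
#'   (`"wilcoxon_ranksum"` or `"t_test"`), `variance_test_p`, `p_value`,
#'   `significant`, `alpha`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05, normality_alpha = 0.05) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) {
    stop_data("both samples must have n >= 3")
  }
  shap_p <- function(x) {
    if (length(x) > 5000) x <- x[round(seq(1, length(x), length.out = 5000))]
    if (stats::sd(x) == 0) return(0) # constant: not normal
    stats::shapiro.test(x)$p.value
  }
  normal <- shap_p(a) >= normality_alpha && shap_p(b) >= normality_alpha
  if (!normal) {
    test_used <- "wilcoxon_ranksum"
    var_p <- NA_real_
    p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  } else {
    test_used <- "t_test"
    var_p <- stats::var.test(a, b)$p.value
    p <- stats::t.test(a, b, var.equal = var_p >= alpha)$p.value
  }
  structure(
    list(test_used = test_used, variance_test_p = var_p, p_value = p,
         significant = p < alpha, alpha = alpha),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s p=%.4g (%ssignificant at alpha=%g)\n",
              x$test_used, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Empirical cumulative distribution function points
#'
#' Right-continuous step-function support points: unique sorted speeds with
#' cumulative fractions; the last fraction is 1.
#'
#' @param speeds numeric vector (n >= 1).
#' @return data.frame with columns `speed` and `fraction`.
#' @export
speed_ecdf <- function(speeds) {
  speeds <- sort(as.numeric(speeds))
  if (!length(speeds)) stop_data("empty speed sample")
  u <- unique(speeds)
  counts <- cumsum(tabulate(match(speeds, u), nbins = length(u)))
  data.frame(speed = u, fraction = counts / length(speeds))
}
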