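#' f2 similarity factor between two dissolution profiles
#'
#' The f2 similarity factor is a logarithmic transform of the mean
#' squared difference between a reference and a test profile over their
#' shared sampling times:
#'
#' \deqn{f_2 = 50 \log_{10}\!\left(100 \left[1 + \frac{1}{n}
#'   \sum_{t=1}^{n} (R_t - T_t)^2\right]^{-1/2}\right)}
#'
#' Identical profiles score 100; a uniform 10-percentage-point gap
#' scores about 50, the conventional similarity cutoff. The statistic is
#' symmetric in its arguments and depends only on the multiset of
#' per-time squared differences.
#'
#' All shared time points enter the sum by default. Regulatory practice
#' sometimes drops sampling times after both profiles exceed 85%
#' released (keeping the first such point); set `truncate_85 = TRUE` for
#' that convention.
#'
#' Values outside \[0, 100] (possible for raw surrogate predictions) are
#' accepted: f2 is defined on the numbers as given.
#'
#' @param reference,test [dissolution_profile()] objects on identical
#'   sampling schedules, or plain numeric vectors of equal length
#'   (assumed aligned).
#' @param min_n Minimum number of shared time points (default 3; the
#'   statistic itself is defined for any n >= 1).
#' @param truncate_85 Apply the post-85%-release truncation rule.
#' @return An object of class `f2_result`: list with `f2`, `n` and
#'   `per_time_sq_diff` (the audit trail of squared differences).
#' @examples
#' f2_similarity(c(32.6, 43.6, 60.7, 74.3, 85.1, 96.2),
#'               c(32.5, 43.4, 60.9, 74.4, 85.8, 96.4))
#' @export
f2_similarity <- function(reference, test, min_n = 3L, truncate_85 = FALSE) {
  if (inherits(reference, "dissolution_profile") ||
      inherits(test, "dissolution_profile")) {
    if (!(inherits(reference, "dissolution_profile") &&
          inherits(test, "dissolution_profile"))) {
      stopf("compare two dissolution_profile objects or two numeric vectors")
    }
    if (!same_schedule(reference, test)) {
      stopf("profiles are on different sampling schedules")
    }
    r <- reference$release_pct; s <- test$release_pct
  } else {
    r <- as.numeric(reference); s <- as.numeric(test)
    if (length(r) != length(s)) {
      stopf("profiles differ in length (%d vs %d)", length(r), length(s))
    }
  }
  if (length(r) < 1L) stopf("profiles are empty")
  if (truncate_85) {
    over <- which(r > 85 & s > 85)
    if (length(over) > 1L) {
      keep <- seq_len(over[1])
      r <- r[keep]; s <- s[keep]
    }
  }
  if (length(r) < min_n) {
    stopf("only %d shared time points; minimum is %d", length(r), min_n)
  }
  sq <- (r - s)^2
  f2 <- 50 * log10(100 / sqrt(1 + mean(sq)))
  structure(list(f2 = f2, n = length(sq), per_time_sq_diff = sq),
            class = "f2_result")
}

#' @export
print.f2_result <- function(x, ...) {
  cat(sprintf("f2 = %.2f over %d time points\n", x$f2, x$n))
  invisible(x)
}

# Vectorized f2 of each row of a prediction matrix against one reference
# vector; used by the grid optimizer (identical arithmetic to
# f2_similarity, one matrix pass).
f2_rows <- function(pred, ref) {
  msd <- rowMeans(sweep(pred, 2, ref, `-`)^2)
  50 * log10(100 / sqrt(1 + msd))
}
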