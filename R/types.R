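# Experimental composition domain: the factor ranges spanned by the
# central composite design (per-factor min/max in original units).
.factor_names <- c("methocel_mg", "xanthan_mg", "carbopol_mg", "surelease_pct")
.factor_min <- c(methocel_mg = 0, xanthan_mg = 0, carbopol_mg = 0,
                 surelease_pct = 4)
.factor_max <- c(methocel_mg = 120, xanthan_mg = 100, carbopol_mg = 20,
                 surelease_pct = 20)

# Canonical dissolution sampling schedule (hours).
.canonical_times <- c(1, 2, 4, 6, 8, 12)

#' Formulation domain limits
#'
#' The experimental composition domain: per-factor minimum and maximum for
#' Methocel K100M (mg), xanthan gum (mg), Carbopol 974P (mg) and Surelease
#' concentration (% w/w). The surrogate model is only valid for
#' compositions inside this domain.
#'
#' @return A data frame with columns `factor`, `min`, `max`.
#' @export
formulation_domain <- function() {
  data.frame(factor = .factor_names, min = unname(.factor_min),
             max = unname(.factor_max), stringsAsFactors = FALSE)
}

#' Construct a formulation
#'
#' A formulation is one point in the four-factor composition space: masses
#' (mg) of the three release-controlling polymers and the concentration
#' (% w/w) of the ethylcellulose granulating dispersion.
#'
#' @param methocel_mg Methocel K100M (HPMC) mass per tablet, mg, in
#'   \[0, 120].
#' @param xanthan_mg Xanthan gum mass per tablet, mg, in \[0, 100].
#' @param carbopol_mg Carbopol 974P mass per tablet, mg, in \[0, 20].
#' @param surelease_pct Surelease concentration of the granulating
#'   dispersion, % w/w, in \[4, 20].
#' @param check If `TRUE` (default), values outside the experimental
#'   domain are an error. `check = FALSE` builds an unchecked formulation
#'   for deliberate extrapolation experiments; predictions outside the
#'   domain are not supported by the training data.
#' @return An object of class `formulation`: a named numeric vector of the
#'   four factor levels.
#' @examples
#' formulation(60, 50, 10, 12)
#' @export
formulation <- function(methocel_mg, xanthan_mg, carbopol_mg, surelease_pct,
                        check = TRUE) {
  x <- c(methocel_mg = as.numeric(methocel_mg),
         xanthan_mg = as.numeric(xanthan_mg),
         carbopol_mg = as.numeric(carbopol_mg),
         surelease_pct = as.numeric(surelease_pct))
  if (anyNA(x) || any(!is.finite(x))) {
    stopf("formulation values must be finite numbers")
  }
  if (check) {
    bad <- which(x < .factor_min | x > .factor_max)
    if (length(bad)) {
      stopf("formulation outside the experimental domain: %s = %g (allowed [%g, %g])",
            .factor_names[bad[1]], x[bad[1]],
            .factor_min[bad[1]], .factor_max[bad[1]])
    }
  }
  structure(x, class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf(
    "Formulation: Methocel %g mg, xanthan %g mg, Carbopol %g mg, Surelease %g%% w/w\n",
    x[["methocel_mg"]], x[["xanthan_mg"]], x[["carbopol_mg"]],
    x[["surelease_pct"]]))
  invisible(x)
}

# coerce a formulation / named or plain length-4 numeric to the canonical
# factor order
as_formulation_vector <- function(x) {
  if (inherits(x, "formulation")) return(unclass(x))
  x <- as.numeric(x)
  if (length(x) != 4L) stopf("expected 4 factor levels, got %d", length(x))
  names(x) <- .factor_names
  x
}

#' Construct a dissolution profile
#'
#' A dissolution profile records the cumulative percent of drug released
#' at an ordered set of sampling times in a standardized in vitro test.
#'
#' @param release_pct Percent of dose released at each sampling time.
#'   Observed profiles lie in \[0, 100]; raw surrogate predictions may
#'   transiently fall outside that range (see [clip_profile()]).
#' @param times_h Sampling times in hours, strictly increasing and
#'   positive. Defaults to the canonical 1, 2, 4, 6, 8, 12 h schedule.
#' @param check If `TRUE`, observed-range bounds \[0, 100] are enforced;
#'   set to `FALSE` for unclipped model predictions.
#' @return An object of class `dissolution_profile` with fields `times_h`
#'   and `release_pct`.
#' @examples
#' dissolution_profile(c(32.6, 43.6, 60.7, 74.3, 85.1, 96.2))
#' @export
dissolution_profile <- function(release_pct, times_h = canonical_times(),
                                check = TRUE) {
  times_h <- as.numeric(times_h)
  release_pct <- as.numeric(release_pct)
  if (length(times_h) < 1L) stopf("profile needs at least one sampling time")
  if (any(!is.finite(times_h)) || any(times_h <= 0)) {
    stopf("sampling times must be finite and positive")
  }
  if (is.unsorted(times_h, strictly = TRUE)) {
    stopf("sampling times must be strictly increasing")
  }
  if (length(release_pct) != length(times_h)) {
    stopf("release_pct length (%d) must match times_h length (%d)",
          length(release_pct), length(times_h))
  }
  if (anyNA(release_pct) || any(!is.finite(release_pct))) {
    stopf("release values must be finite")
  }
  if (check && (any(release_pct < 0) || any(release_pct > 100))) {
    stopf("observed release values must lie in [0, 100]; use check = FALSE for raw predictions")
  }
  structure(list(times_h = times_h, release_pct = release_pct),
            class = "dissolution_profile")
}

#' Canonical sampling schedule
#'
#' @return The default dissolution sampling times in hours:
#'   1, 2, 4, 6, 8, 12.
#' @export
canonical_times <- function() .canonical_times

#' @export
print.dissolution_profile <- function(x, ...) {
  cat("Dissolution profile (% released):\n")
  print(stats::setNames(round(x$release_pct, 2),
                        paste0(format(x$times_h), " h")))
  invisible(x)
}

#' Clip a predicted profile to the observable range
#'
#' Raw surrogate predictions are linear in the scaled output space and can
#' slightly exceed \[0, 100]. Clipping is applied only when reporting or
#' serializing profiles, never inside training or during f2 ranking, where
#' it would silently change optimization results.
#'
#' @param profile A [dissolution_profile()].
#' @return The profile with `release_pct` clipped to \[0, 100].
#' @export
clip_profile <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  profile$release_pct <- pmin(100, pmax(0, profile$release_pct))
  profile
}

same_schedule <- function(a, b, tol = 1e-9) {
  length(a$times_h) == length(b$times_h) &&
    all(abs(a$times_h - b$times_h) <= tol)
}
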