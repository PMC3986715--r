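#' Specify the brute-force search grid
#'
#' The optimizer enumerates the Cartesian product of per-factor
#' arithmetic sequences `min, min + step, ...` up to `max`. The default
#' grid covers the full experimental domain at roughly 4% resolution per
#' axis — 25 x 21 x 9 x 9 = 42,525 candidates, cheap enough for
#' exhaustive evaluation.
#'
#' @param min,max,step Length-4 numeric vectors (factor order
#'   methocel_mg, xanthan_mg, carbopol_mg, surelease_pct).
#' @return An object of class `search_grid`.
#' @export
search_grid <- function(min = c(0, 0, 0, 4), max = c(120, 100, 20, 20),
                        step = c(5, 5, 2.5, 2)) {
  min <- as.numeric(min); max <- as.numeric(max); step <- as.numeric(step)
  if (length(min) != 4L || length(max) != 4L || length(step) != 4L) {
    stopf("min, max and step must each have 4 entries")
  }
  if (any(min > max)) stopf("grid minimum exceeds maximum")
  if (any(step <= 0)) stopf("grid steps must be positive")
  bad <- which(min < .factor_min | max > .factor_max)
  if (length(bad)) {
    stopf("grid for %s leaves the experimental domain [%g, %g]",
          .factor_names[bad[1]], .factor_min[bad[1]], .factor_max[bad[1]])
  }
  structure(list(min = stats::setNames(min, .factor_names),
                 max = stats::setNames(max, .factor_names),
                 step = stats::setNames(step, .factor_names)),
            class = "search_grid")
}

grid_levels <- function(grid) {
  lapply(seq_len(4L), function(j) {
    seq(grid$min[j], grid$max[j], by = grid$step[j])
  })
}

#' Enumerate all grid candidates
#'
#' @param grid A [search_grid()].
#' @return A numeric matrix (candidates x 4) in deterministic
#'   lexicographic order: the first factor varies slowest, the last
#'   fastest.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  lv <- grid_levels(grid)
  if (any(lengths(lv) == 0L)) stopf("a grid axis is empty")
  m <- as.matrix(expand.grid(lv[[4]], lv[[3]], lv[[2]], lv[[1]],
                             KEEP.OUT.ATTRS = FALSE))[, 4:1, drop = FALSE]
  dimnames(m) <- list(NULL, .factor_names)
  m
}

#' Brute-force formulation optimization against a reference profile
#'
#' Evaluates the surrogate at every grid candidate and scores each
#' simulated profile against the reference with the f2 similarity
#' factor; the candidate with the highest f2 wins (ties broken by
#' enumeration order). Predicted profiles are not clipped to \[0, 100]
#' during ranking, so the ranking reflects the model as fitted.
#'
#' @param net An [mlp_surrogate()].
#' @param reference A [dissolution_profile()] on the network's sampling
#'   schedule.
#' @param grid A [search_grid()].
#' @param top_k How many runner-up candidates to report (default 10).
#' @return An object of class `optimization_result`: `best` (the winning
#'   [formulation()]), `predicted_profile`, `f2`, `n_evaluated`, and
#'   `top_k` (a data frame of the highest-f2 candidates in descending
#'   order).
#' @export
optimize_formulation <- function(net, reference, grid = search_grid(),
                                 top_k = 10L) {
  stopifnot(inherits(net, "mlp_surrogate"),
            inherits(reference, "dissolution_profile"))
  if (length(reference$times_h) != length(net$times_h) ||
      any(abs(reference$times_h - net$times_h) > 1e-9)) {
    stopf("reference profile is not on the network's sampling schedule")
  }
  cand <- enumerate_grid(grid)
  # chunked batch evaluation: purely functional, identical results to
  # one-at-a-time scoring
  n <- nrow(cand)
  f2s <- numeric(n)
  chunk <- 10000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    pred <- predict_profiles(net, cand[s:e, , drop = FALSE])
    f2s[s:e] <- f2_rows(pred, reference$release_pct)
  }
  best_i <- which.max(f2s)
  k <- min(top_k, n)
  ord <- order(-f2s, seq_len(n))[seq_len(k)]
  top <- data.frame(cand[ord, , drop = FALSE], f2 = f2s[ord])
  best <- formulation(cand[best_i, 1], cand[best_i, 2], cand[best_i, 3],
                      cand[best_i, 4])
  structure(list(best = best,
                 predicted_profile = forward(net, best),
                 f2 = f2s[best_i],
                 n_evaluated = n,
                 top_k = top),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Optimized formulation (f2 = %.1f over %d candidates):\n",
              x$f2, x$n_evaluated))
  print(x$best)
  print(clip_profile(x$predicted_profile))
  invisible(x)
}
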