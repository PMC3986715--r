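#' Specify a four-factor central composite design
#'
#' A central composite design (CCD) samples a second-order response
#' surface with 2^k factorial points at coded levels +/-1, 2k axial
#' points at +/- `axial_distance` coded units on one factor at a time,
#' and replicated center points. For k = 4 factors the axial distance 2
#' is also the rotatable choice (alpha = (2^4)^(1/4) = 2).
#'
#' @param center Factor centers, original units; defaults to the study
#'   centers (60 mg, 50 mg, 10 mg, 12 % w/w).
#' @param step Coded-unit step per factor; defaults 30 mg, 25 mg, 5 mg,
#'   4 % w/w.
#' @param axial_distance Axial distance in coded units (default 2).
#' @param n_center Number of center-point replicates (default 6).
#' @return An object of class `ccd_spec`.
#' @export
ccd_spec <- function(center = c(60, 50, 10, 12), step = c(30, 25, 5, 4),
                     axial_distance = 2, n_center = 6) {
  center <- as.numeric(center); step <- as.numeric(step)
  if (length(center) != 4L || length(step) != 4L) {
    stopf("center and step must each have 4 entries")
  }
  if (any(step <= 0)) stopf("steps must be positive")
  if (axial_distance <= 0) stopf("axial_distance must be positive")
  if (n_center < 1) stopf("n_center must be at least 1")
  lo <- center - axial_distance * step
  hi <- center + axial_distance * step
  bad <- which(lo < .factor_min | hi > .factor_max)
  if (length(bad)) {
    stopf("axial levels for %s (%g to %g) leave the experimental domain [%g, %g]",
          .factor_names[bad[1]], lo[bad[1]], hi[bad[1]],
          .factor_min[bad[1]], .factor_max[bad[1]])
  }
  structure(list(center = stats::setNames(center, .factor_names),
                 step = stats::setNames(step, .factor_names),
                 axial_distance = axial_distance, n_center = n_center),
            class = "ccd_spec")
}

#' Generate a central composite design
#'
#' Produces the design points in a fixed order — 16 factorial, 8 axial,
#' then the center replicates — so that a design is reproducible without
#' reference to the randomized manufacture order; use
#' [shuffle_dataset()] for a seeded run-order randomization.
#'
#' @param spec A [ccd_spec()]. The defaults reproduce the 30-run study
#'   design (identical, as a multiset, to [study_design()]).
#' @param ids Optional record ids; default `CCD001...`.
#' @return A [formulation_dataset()] without profiles.
#' @examples
#' d <- generate_ccd()
#' length(d)  # 30
#' @export
generate_ccd <- function(spec = ccd_spec(), ids = NULL) {
  stopifnot(inherits(spec, "ccd_spec"))
  # factorial block: all sign combinations, last factor varying fastest
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))[, 4:1]
  dimnames(signs) <- NULL
  axial <- matrix(0, nrow = 8, ncol = 4)
  for (j in 1:4) {
    axial[2 * j - 1, j] <- -spec$axial_distance
    axial[2 * j, j] <- spec$axial_distance
  }
  coded <- rbind(signs, axial,
                 matrix(0, nrow = spec$n_center, ncol = 4))
  actual <- sweep(sweep(coded, 2, spec$step, `*`), 2, spec$center, `+`)
  n <- nrow(actual)
  if (is.null(ids)) ids <- sprintf("CCD%03d", seq_len(n))
  formulation_dataset(ids, actual)
}

#' Seeded run-order shuffle
#'
#' Randomizes the record order of a dataset (as a manufacture schedule
#' would), deterministically for a given seed. Profiles, if present,
#' travel with their formulations.
#'
#' @param dataset A [formulation_dataset()].
#' @param seed Integer seed.
#' @return The dataset with records permuted.
#' @export
shuffle_dataset <- function(dataset, seed) {
  stopifnot(inherits(dataset, "formulation_dataset"))
  perm <- with_seed(seed, sample.int(length(dataset)))
  formulation_dataset(dataset$id[perm],
                      dataset$composition[perm, , drop = FALSE],
                      release = if (is.null(dataset$release)) NULL
                                else dataset$release[perm, , drop = FALSE],
                      times_h = dataset$times_h)
}
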