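#' Fit a min-max scaler
#'
#' Records the per-dimension minimum and maximum of a data matrix so
#' inputs and targets can be rescaled linearly to \[-1, +1], the range
#' in which the perceptron is trained. A dimension with zero range is
#' degenerate and maps to 0 (its midpoint) rather than dividing by zero.
#'
#' @param data Numeric matrix, samples in rows.
#' @return An object of class `minmax_scaler` with fields `min`, `max`.
#' @export
fit_scaler <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stopf("cannot fit a scaler to an empty matrix")
  if (anyNA(data) || any(!is.finite(data))) stopf("data must be finite")
  structure(list(min = apply(data, 2, min), max = apply(data, 2, max)),
            class = "minmax_scaler")
}

#' Apply / invert a min-max scaler
#'
#' `apply_scaler()` maps each dimension linearly so that the fitted
#' minimum becomes -1 and the fitted maximum +1; `invert_scaler()` is its
#' exact inverse. Values outside the fitted range extrapolate linearly.
#'
#' @param scaler A [fit_scaler()] result.
#' @param x Numeric vector (one sample) or matrix (samples in rows) with
#'   as many columns as the scaler has dimensions.
#' @return Scaled (resp. unscaled) values with the shape of `x`.
#' @export
apply_scaler <- function(scaler, x) {
  scale_dispatch(scaler, x, forward = TRUE)
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, x) {
  scale_dispatch(scaler, x, forward = FALSE)
}

scale_dispatch <- function(scaler, x, forward) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  d <- length(scaler$min)
  if (ncol(m) != d) {
    stopf("scaler has %d dimensions but data has %d columns", d, ncol(m))
  }
  rng <- scaler$max - scaler$min
  half <- ifelse(rng == 0, 1, rng / 2)  # degenerate dims collapse to 0
  mid <- (scaler$max + scaler$min) / 2
  out <- if (forward) {
    sweep(sweep(m, 2, mid, `-`), 2, half, `/`)
  } else {
    sweep(sweep(m, 2, half, `*`), 2, mid, `+`)
  }
  if (vec) drop(out) else out
}
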