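#' Construct an MLP surrogate
#'
#' The surrogate is a single-hidden-layer perceptron operating in scaled
#' space: inputs are min-max scaled to \[-1, 1], the hidden layer applies
#' a logistic sigmoid (logsig) to a weighted sum of the scaled inputs,
#' the output layer is linear (purelin), and predictions are mapped back
#' to percent released with the inverse target scaling. Together with its
#' two scalers the network is a composition-to-profile predictor.
#'
#' @param input_weights H x 4 matrix of hidden-layer weights.
#' @param input_biases Length-H hidden biases.
#' @param output_weights 6 x H (more generally n_out x H) output weights.
#' @param output_biases Length-n_out output biases.
#' @param input_scaler,target_scaler [fit_scaler()] parameters for the
#'   four factors and the n_out release values respectively.
#' @param times_h Sampling schedule the outputs correspond to.
#' @return An object of class `mlp_surrogate`.
#' @export
mlp_surrogate <- function(input_weights, input_biases, output_weights,
                          output_biases, input_scaler, target_scaler,
                          times_h = canonical_times()) {
  input_weights <- as.matrix(input_weights)
  output_weights <- as.matrix(output_weights)
  input_biases <- as.numeric(input_biases)
  output_biases <- as.numeric(output_biases)
  h <- nrow(input_weights)
  if (h < 1L) stopf("network needs at least one hidden node")
  if (length(input_biases) != h || ncol(output_weights) != h) {
    stopf("hidden-layer dimensions are inconsistent")
  }
  if (nrow(output_weights) != length(output_biases)) {
    stopf("output-layer dimensions are inconsistent")
  }
  if (ncol(input_weights) != length(fit <- input_scaler$min)) {
    stopf("input weights have %d columns but the input scaler has %d dimensions",
          ncol(input_weights), length(fit))
  }
  if (nrow(output_weights) != length(target_scaler$min)) {
    stopf("output layer has %d rows but the target scaler has %d dimensions",
          nrow(output_weights), length(target_scaler$min))
  }
  if (length(times_h) != nrow(output_weights)) {
    stopf("times_h must have one entry per output")
  }
  pars <- c(input_weights, input_biases, output_weights, output_biases)
  if (anyNA(pars) || any(!is.finite(pars))) {
    stopf("network parameters must be finite")
  }
  structure(list(input_weights = input_weights, input_biases = input_biases,
                 output_weights = output_weights,
                 output_biases = output_biases,
                 input_scaler = input_scaler, target_scaler = target_scaler,
                 times_h = as.numeric(times_h)),
            class = "mlp_surrogate")
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat(sprintf("MLP surrogate: %d -> %d (logsig) -> %d (linear)\n",
              ncol(x$input_weights), nrow(x$input_weights),
              nrow(x$output_weights)))
  invisible(x)
}

#' Number of hidden nodes
#' @param net An [mlp_surrogate()].
#' @return Integer count of hidden-layer nodes.
#' @export
n_hidden <- function(net) nrow(net$input_weights)

logsig <- function(z) 1 / (1 + exp(-z))

# Batched scaled-space evaluation: X_scaled is n x 4, returns n x n_out.
mlp_eval_scaled <- function(net, x_scaled) {
  z <- tcrossprod(x_scaled, net$input_weights)          # n x H
  h <- logsig(sweep(z, 2, net$input_biases, `+`))
  sweep(tcrossprod(h, net$output_weights), 2, net$output_biases, `+`)
}

#' Predict dissolution profiles for a matrix of compositions
#'
#' Vectorized forward pass in original units: compositions are scaled,
#' pushed through the network and the predictions unscaled. No clipping
#' is applied (see [clip_profile()]).
#'
#' @param net An [mlp_surrogate()].
#' @param compositions n x 4 matrix of factor levels, columns in the
#'   order methocel_mg, xanthan_mg, carbopol_mg, surelease_pct.
#' @return n x n_out matrix of predicted percent released.
#' @export
predict_profiles <- function(net, compositions) {
  stopifnot(inherits(net, "mlp_surrogate"))
  x <- apply_scaler(net$input_scaler, as.matrix(compositions))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  invert_scaler(net$target_scaler, mlp_eval_scaled(net, x))
}

#' Forward pass for one formulation
#'
#' @param net An [mlp_surrogate()].
#' @param formulation A [formulation()] (or length-4 numeric).
#' @param clip Clip the predicted profile to \[0, 100]? Default `FALSE`:
#'   raw predictions are reported so that downstream ranking is not
#'   silently distorted.
#' @return The predicted [dissolution_profile()].
#' @examples
#' \dontrun{
#' forward(net, formulation(30, 75, 5, 16))
#' }
#' @export
forward <- function(net, formulation, clip = FALSE) {
  x <- as_formulation_vector(formulation)
  y <- drop(predict_profiles(net, matrix(x, nrow = 1)))
  p <- dissolution_profile(y, net$times_h, check = FALSE)
  if (clip) clip_profile(p) else p
}

#' Serialize / deserialize a surrogate model
#'
#' The model file is a versioned JSON document holding both scalers and
#' all weight matrices at 17 significant digits, so a write/read round
#' trip reproduces the model exactly.
#'
#' @param net An [mlp_surrogate()].
#' @param path File path.
#' @return `write_surrogate()` returns `path` invisibly;
#'   `read_surrogate()` returns the reconstructed [mlp_surrogate()].
#' @export
write_surrogate <- function(net, path) {
  stopifnot(inherits(net, "mlp_surrogate"))
  # numbers are stored as 17-significant-digit decimal strings, which is
  # enough to reproduce every IEEE double exactly on re-parse
  num <- function(x) sprintf("%.17g", as.numeric(x))
  doc <- list(
    schema = "dissopt-mlp", version = 1L,
    n_hidden = n_hidden(net),
    n_out = nrow(net$output_weights),
    times_h = num(net$times_h),
    input_scaler = list(min = num(net$input_scaler$min),
                        max = num(net$input_scaler$max)),
    target_scaler = list(min = num(net$target_scaler$min),
                         max = num(net$target_scaler$max)),
    input_weights = num(net$input_weights),
    input_biases = num(net$input_biases),
    output_weights = num(net$output_weights),
    output_biases = num(net$output_biases))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "dissopt-mlp")) {
    stopf("not a surrogate model file: %s", path)
  }
  if (!identical(as.integer(doc$version), 1L)) {
    stopf("unsupported model schema version %s", doc$version)
  }
  h <- as.integer(doc$n_hidden)
  k <- as.integer(doc$n_out)
  num <- function(x) as.numeric(x)
  mlp_surrogate(matrix(num(doc$input_weights), h),
                num(doc$input_biases),
                matrix(num(doc$output_weights), k),
                num(doc$output_biases),
                structure(list(min = num(doc$input_scaler$min),
                               max = num(doc$input_scaler$max)),
                          class = "minmax_scaler"),
                structure(list(min = num(doc$target_scaler$min),
                               max = num(doc$target_scaler$max)),
                          class = "minmax_scaler"),
                times_h = num(doc$times_h))
}
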