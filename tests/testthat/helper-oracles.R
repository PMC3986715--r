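# Independent oracles kept deliberately separate from the package's own
# code paths: scalar formula transcriptions and explicit-loop evaluation.

# f2 written directly from the defining formula, scalar arithmetic only
oracle_f2 <- function(r, t) {
  n <- length(r)
  s <- 0
  for (i in seq_len(n)) s <- s + (r[i] - t[i])^2
  50 * log10(100 * (1 + s / n)^(-0.5))
}

# brute-force forward pass: explicit loops over nodes, no linear algebra
oracle_forward <- function(net, x) {
  x <- as.numeric(x)
  d <- length(net$input_scaler$min)
  xs <- numeric(d)
  for (m in seq_len(d)) {
    rng <- net$input_scaler$max[m] - net$input_scaler$min[m]
    half <- if (rng == 0) 1 else rng / 2
    xs[m] <- (x[m] - (net$input_scaler$max[m] + net$input_scaler$min[m]) / 2) / half
  }
  H <- nrow(net$input_weights)
  K <- nrow(net$output_weights)
  h <- numeric(H)
  for (j in seq_len(H)) {
    z <- net$input_biases[j]
    for (m in seq_len(d)) z <- z + net$input_weights[j, m] * xs[m]
    h[j] <- 1 / (1 + exp(-z))
  }
  y <- numeric(K)
  for (k in seq_len(K)) {
    acc <- net$output_biases[k]
    for (j in seq_len(H)) acc <- acc + net$output_weights[k, j] * h[j]
    rng <- net$target_scaler$max[k] - net$target_scaler$min[k]
    half <- if (rng == 0) 1 else rng / 2
    y[k] <- acc * half + (net$target_scaler$max[k] + net$target_scaler$min[k]) / 2
  }
  y
}

# a random small surrogate with well-separated scaler ranges
random_net <- function(n_hidden = 3L, n_in = 4L, n_out = 6L) {
  scaler <- function(d, lo, hi) {
    a <- sort(runif(2, lo, hi))
    structure(list(min = runif(d, lo, a[1]), max = runif(d, a[2], hi)),
              class = "minmax_scaler")
  }
  mlp_surrogate(matrix(rnorm(n_hidden * n_in), n_hidden, n_in),
                rnorm(n_hidden),
                matrix(rnorm(n_out * n_hidden), n_out, n_hidden),
                rnorm(n_out),
                scaler(n_in, -5, 5), scaler(n_out, 0, 100),
                times_h = canonical_times()[seq_len(n_out)])
}

# a dataset whose targets are exactly realizable by a known 1-hidden-node
# network (in original units), on the 30-run design
realizable_dataset <- function(seed = 1L) {
  comp <- study_design()$composition
  win <- matrix(c(0.8, -0.5, 0.3, 0.6), 1, 4)
  in_sc <- fit_scaler(comp)
  xs <- apply_scaler(in_sc, comp)
  h <- 1 / (1 + exp(-(xs %*% t(win) + 0.1)))
  # six outputs, each an affine map of the single hidden activation,
  # kept well inside [0, 100]
  wout <- seq(10, 35, by = 5)
  bout <- seq(30, 55, by = 5)
  rel <- sweep(h %*% matrix(wout, 1, 6), 2, bout, `+`)
  formulation_dataset(sprintf("RZ%03d", 1:30), comp, release = rel)
}
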