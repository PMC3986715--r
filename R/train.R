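#' Specify a train/validation/test split
#'
#' Records are split at the formulation level: all six time points of a
#' record travel together, so no formulation leaks information across
#' partitions. By default 67% of records train the network and 33% are
#' held out; of the held-out records, 67% form the validation set that
#' drives early stopping and the remainder form the test set. Fractional
#' record counts round half up (30 records -> 20 train, 7 validation,
#' 3 test).
#'
#' @param train_fraction Fraction of records used for training,
#'   in (0, 1).
#' @param validation_fraction_of_test Fraction of the held-out records
#'   assigned to validation, in (0, 1).
#' @param seed Integer seed for the random partition.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.67,
                       validation_fraction_of_test = 0.67, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must lie strictly between 0 and 1")
  }
  if (!(validation_fraction_of_test > 0 && validation_fraction_of_test < 1)) {
    stopf("validation_fraction_of_test must lie strictly between 0 and 1")
  }
  structure(list(train_fraction = train_fraction,
                 validation_fraction_of_test = validation_fraction_of_test,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition a dataset into train / validation / test index sets
#'
#' @param dataset A [formulation_dataset()] with at least 3 records.
#' @param spec A [split_spec()].
#' @return A list with integer index vectors `train`, `validation`,
#'   `test`; together they cover the record indices exactly once.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "formulation_dataset"),
            inherits(spec, "split_spec"))
  n <- length(dataset)
  if (n < 3L) stopf("need at least 3 records to split, have %d", n)
  n_train <- round_half_up(n * spec$train_fraction)
  n_rest <- n - n_train
  n_val <- round_half_up(n_rest * spec$validation_fraction_of_test)
  n_test <- n_rest - n_val
  if (n_train < 1L || n_val < 1L || n_test < 1L) {
    stopf("split leaves an empty partition (train %d, validation %d, test %d)",
          n_train, n_val, n_test)
  }
  perm <- with_seed(spec$seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Training limits
#'
#' @param max_epochs Maximum number of accepted Levenberg-Marquardt
#'   iterations (default 800).
#' @param max_validation_failures Stop after this many epochs without a
#'   new best validation error (default 200).
#' @param grad_tol Gradient infinity-norm convergence tolerance in
#'   scaled units (default 1e-7).
#' @param mu0,mu_up,mu_down,mu_max Levenberg-Marquardt damping schedule:
#'   initial damping, factors applied after a rejected / accepted step,
#'   and the ceiling beyond which training stops.
#' @return A list of class `train_limits`.
#' @export
train_limits <- function(max_epochs = 800L, max_validation_failures = 200L,
                         grad_tol = 1e-7, mu0 = 1e-3, mu_up = 10,
                         mu_down = 10, mu_max = 1e10) {
  stopifnot(max_epochs >= 1, max_validation_failures >= 1, mu0 > 0,
            mu_up > 1, mu_down > 1, mu_max > mu0)
  structure(list(max_epochs = as.integer(max_epochs),
                 max_validation_failures = as.integer(max_validation_failures),
                 grad_tol = grad_tol, mu0 = mu0, mu_up = mu_up,
                 mu_down = mu_down, mu_max = mu_max),
            class = "train_limits")
}

# Seeded initialization: uniform in [-0.5, 0.5], weights shrunk by the
# square root of the node's fan-in so initial hidden activations stay in
# the responsive part of the sigmoid.
init_params <- function(n_in, n_hid, n_out, seed) {
  with_seed(seed, {
    list(W_in = matrix(stats::runif(n_hid * n_in, -0.5, 0.5) / sqrt(n_in),
                       n_hid, n_in),
         b_in = stats::runif(n_hid, -0.5, 0.5),
         W_out = matrix(stats::runif(n_out * n_hid, -0.5, 0.5) / sqrt(n_hid),
                        n_out, n_hid),
         b_out = stats::runif(n_out, -0.5, 0.5))
  })
}

pack_params <- function(p) c(p$W_in, p$b_in, p$W_out, p$b_out)

unpack_params <- function(v, n_in, n_hid, n_out) {
  i <- 0L
  W_in <- matrix(v[i + seq_len(n_hid * n_in)], n_hid, n_in)
  i <- i + n_hid * n_in
  b_in <- v[i + seq_len(n_hid)]; i <- i + n_hid
  W_out <- matrix(v[i + seq_len(n_out * n_hid)], n_out, n_hid)
  i <- i + n_out * n_hid
  b_out <- v[i + seq_len(n_out)]
  list(W_in = W_in, b_in = b_in, W_out = W_out, b_out = b_out)
}

# scaled-space network evaluation from a raw parameter list
eval_params <- function(p, X) {
  z <- sweep(tcrossprod(X, p$W_in), 2, p$b_in, `+`)
  H <- 1 / (1 + exp(-z))
  list(H = H,
       Y = sweep(tcrossprod(H, p$W_out), 2, p$b_out, `+`))
}

# Analytic Jacobian of the residual vector (column-major over samples
# then outputs) with respect to the packed parameter vector.
mlp_jacobian <- function(p, X, H) {
  n <- nrow(X); n_in <- ncol(X)
  n_hid <- nrow(p$W_in); n_out <- nrow(p$W_out)
  npar <- n_hid * n_in + n_hid + n_out * n_hid + n_out
  J <- matrix(0, n * n_out, npar)
  dH <- H * (1 - H)                      # n x n_hid, sigmoid derivative
  off_bin <- n_hid * n_in
  off_wout <- off_bin + n_hid
  off_bout <- off_wout + n_out * n_hid
  for (j in seq_len(n_hid)) {
    aj <- dH[, j]
    wj <- p$W_out[, j]
    # hidden weights and bias: chain rule through node j
    for (m in seq_len(n_in)) {
      J[, (m - 1L) * n_hid + j] <- as.vector(outer(aj * X[, m], wj))
    }
    J[, off_bin + j] <- as.vector(outer(aj, wj))
    # output weights from node j: block-diagonal in the output index
    for (k in seq_len(n_out)) {
      J[(k - 1L) * n + seq_len(n), off_wout + (j - 1L) * n_out + k] <- H[, j]
    }
  }
  for (k in seq_len(n_out)) {
    J[(k - 1L) * n + seq_len(n), off_bout + k] <- 1
  }
  J
}

mse_of <- function(p, X, Tm) {
  if (nrow(X) == 0L) return(NA_real_)
  mean((eval_params(p, X)$Y - Tm)^2)
}

# Core Levenberg-Marquardt loop on scaled data. One epoch is one
# accepted damped Gauss-Newton step (the damping mu is escalated within
# the epoch until a step reduces the training error). Returns the
# parameters of the best-validation epoch (or the final epoch when no
# validation set is supplied) plus the full per-epoch history.
lm_fit <- function(X_train, T_train, H_nodes, seed, limits,
                   X_val = NULL, T_val = NULL, X_test = NULL, T_test = NULL) {
  n_in <- ncol(X_train); n_out <- ncol(T_train)
  p <- init_params(n_in, H_nodes, n_out, seed)
  has_val <- !is.null(X_val) && nrow(X_val) > 0L
  mu <- limits$mu0
  ev <- eval_params(p, X_train)
  sse <- sum((ev$Y - T_train)^2)
  if (!is.finite(sse)) stopf("non-finite training loss at initialization")

  hist_train <- hist_val <- hist_test <- numeric(0)
  best_val <- Inf; best_epoch <- 0L; best_p <- p
  stop_reason <- "max_epochs"
  epoch <- 0L

  while (epoch < limits$max_epochs) {
    r <- as.vector(ev$Y - T_train)
    J <- mlp_jacobian(p, X_train, ev$H)
    g <- crossprod(J, r)
    if (max(abs(g)) < limits$grad_tol) { stop_reason <- "gradient_converged"; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      A <- JtJ + diag(mu, ncol(JtJ))
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        p_new <- unpack_params(pack_params(p) + as.vector(delta),
                               n_in, H_nodes, n_out)
        ev_new <- eval_params(p_new, X_train)
        sse_new <- sum((ev_new$Y - T_train)^2)
        if (is.finite(sse_new) && sse_new < sse) {
          p <- p_new; ev <- ev_new; sse <- sse_new
          mu <- max(mu / limits$mu_down, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * limits$mu_up
      if (mu > limits$mu_max) break
    }
    if (!accepted) { stop_reason <- "gradient_converged"; break }

    epoch <- epoch + 1L
    hist_train[epoch] <- sse / (nrow(X_train) * n_out)
    hist_val[epoch] <- if (has_val) mse_of(p, X_val, T_val) else NA_real_
    hist_test[epoch] <- if (!is.null(X_test) && nrow(X_test) > 0L) {
      mse_of(p, X_test, T_test)
    } else NA_real_

    if (has_val) {
      if (hist_val[epoch] < best_val) {
        best_val <- hist_val[epoch]; best_epoch <- epoch; best_p <- p
      } else if (epoch - best_epoch >= limits$max_validation_failures) {
        stop_reason <- "validation_failures"
        break
      }
    } else {
      best_epoch <- epoch; best_p <- p
      best_val <- hist_train[epoch]
    }
  }

  if (epoch == 0L) { best_p <- p; best_epoch <- 0L }
  list(params = best_p,
       history = structure(list(
         epochs = data.frame(epoch = seq_len(epoch),
                             train_mse = hist_train,
                             validation_mse = hist_val,
                             test_mse = hist_test),
         stop_reason = stop_reason,
         best_epoch = best_epoch,
         best_validation_mse = if (has_val && is.finite(best_val)) best_val
                               else NA_real_),
         class = "training_history"))
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs, stopped on %s\n",
              nrow(x$epochs), x$stop_reason))
  if (!is.na(x$best_validation_mse)) {
    cat(sprintf("  best validation MSE %.4g at epoch %d\n",
                x$best_validation_mse, x$best_epoch))
  }
  invisible(x)
}

dataset_scaled <- function(dataset) {
  in_sc <- fit_scaler(dataset$composition)
  tg_sc <- fit_scaler(dataset$release)
  list(input_scaler = in_sc, target_scaler = tg_sc,
       X = apply_scaler(in_sc, dataset$composition),
       T = apply_scaler(tg_sc, dataset$release))
}

#' Train the MLP surrogate by Levenberg-Marquardt
#'
#' Inputs and targets are min-max scaled to \[-1, 1] (the scalers are
#' fitted on the full dataset, as the extremes of the design define the
#' model's valid range). Training minimizes the mean squared error of
#' the scaled targets on the training partition with damped Gauss-Newton
#' steps; after each accepted step the validation error is evaluated and
#' the parameters at the epoch of minimum validation error are retained
#' (best-checkpoint restore). Training stops at `max_epochs`, after
#' `max_validation_failures` epochs without a validation improvement, or
#' when the gradient norm converges.
#'
#' @param dataset A [formulation_dataset()] with profiles.
#' @param n_hidden Number of hidden nodes.
#' @param split A [split_spec()].
#' @param limits A [train_limits()].
#' @param seed Seed for weight initialization.
#' @return A list with components `net` (the [mlp_surrogate()] at the
#'   best-validation checkpoint), `history` (per-epoch scaled MSEs, stop
#'   reason, best epoch) and `split` (the index partition used).
#' @export
train_mlp <- function(dataset, n_hidden, split = split_spec(),
                      limits = train_limits(), seed = 1L) {
  stopifnot(inherits(dataset, "formulation_dataset"))
  if (is.null(dataset$release)) stopf("dataset has no dissolution profiles")
  if (n_hidden < 1) stopf("n_hidden must be at least 1")
  idx <- split_dataset(dataset, split)
  sc <- dataset_scaled(dataset)
  fit <- lm_fit(sc$X[idx$train, , drop = FALSE],
                sc$T[idx$train, , drop = FALSE],
                n_hidden, seed, limits,
                X_val = sc$X[idx$validation, , drop = FALSE],
                T_val = sc$T[idx$validation, , drop = FALSE],
                X_test = sc$X[idx$test, , drop = FALSE],
                T_test = sc$T[idx$test, , drop = FALSE])
  net <- mlp_surrogate(fit$params$W_in, fit$params$b_in, fit$params$W_out,
                       fit$params$b_out, sc$input_scaler, sc$target_scaler,
                       times_h = dataset$times_h)
  list(net = net, history = fit$history, split = idx)
}

#' Retrain on the full dataset
#'
#' After model selection, the chosen architecture is retrained on every
#' record (no held-out partitions) to produce the network used for
#' formulation optimization. Stopping is on `max_epochs` or gradient
#' convergence only.
#'
#' @inheritParams train_mlp
#' @return The trained [mlp_surrogate()]; the training history is
#'   attached as attribute `"history"`.
#' @export
retrain_full <- function(dataset, n_hidden, limits = train_limits(),
                         seed = 1L) {
  stopifnot(inherits(dataset, "formulation_dataset"))
  if (is.null(dataset$release)) stopf("dataset has no dissolution profiles")
  sc <- dataset_scaled(dataset)
  fit <- lm_fit(sc$X, sc$T, n_hidden, seed, limits)
  net <- mlp_surrogate(fit$params$W_in, fit$params$b_in, fit$params$W_out,
                       fit$params$b_out, sc$input_scaler, sc$target_scaler,
                       times_h = dataset$times_h)
  attr(net, "history") <- fit$history
  net
}
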