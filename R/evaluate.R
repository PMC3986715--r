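#' Per-time-point R-squared of predicted vs observed release
#'
#' For each sampling time, computes the squared Pearson correlation
#' between the network's predicted percent released and the observed
#' values across the chosen records — the standard predicted-vs-observed
#' diagnostic for surrogate quality.
#'
#' Degenerate cases: if the observed values at a time point have zero
#' variance the correlation is undefined and `NA` is returned for that
#' time point; if the predictions are constant while the observations
#' vary, 0 is returned with a warning (the model explains nothing).
#'
#' @param net An [mlp_surrogate()].
#' @param dataset A [formulation_dataset()] with profiles.
#' @param indices Record indices to evaluate (default: all records).
#' @return Named numeric vector of R-squared values, one per time point.
#' @export
evaluate_r2 <- function(net, dataset, indices = NULL) {
  stopifnot(inherits(net, "mlp_surrogate"),
            inherits(dataset, "formulation_dataset"))
  if (is.null(dataset$release)) stopf("dataset has no dissolution profiles")
  indices <- indices %||% seq_len(length(dataset))
  if (length(indices) < 2L) stopf("need at least 2 records for correlation")
  pred <- predict_profiles(net, dataset$composition[indices, , drop = FALSE])
  obs <- dataset$release[indices, , drop = FALSE]
  r2 <- numeric(ncol(obs))
  flat <- logical(ncol(obs))
  for (j in seq_len(ncol(obs))) {
    if (stats::sd(obs[, j]) == 0) {
      r2[j] <- NA_real_
    } else if (stats::sd(pred[, j]) == 0) {
      flat[j] <- TRUE
      r2[j] <- 0
    } else {
      r2[j] <- stats::cor(pred[, j], obs[, j])^2
    }
  }
  if (any(flat)) {
    warning("constant predictions at ",
            paste0(dataset$times_h[flat], collapse = ", "),
            " h; R^2 reported as 0", call. = FALSE)
  }
  stats::setNames(r2, profile_colnames(dataset$times_h))
}

#' Hidden-node sweep for architecture selection
#'
#' Trains networks with each candidate hidden-layer size (by default 3
#' to 10 nodes) and compares their held-out predicted-vs-observed
#' R-squared per time point. Each candidate is trained `repeats` times
#' with derived seeds (the data split is shared across candidates within
#' a repeat, so architectures are compared on identical partitions) and
#' the per-time-point R-squared values, evaluated on the records not
#' used for weight updates (validation and test sets), are averaged.
#' The candidate with the highest mean R-squared across time points is
#' selected; ties go to the smaller network.
#'
#' @param dataset A [formulation_dataset()] with profiles.
#' @param candidates Integer vector of hidden-node counts to try,
#'   within \[1, 64].
#' @param repeats Training repetitions per candidate (>= 1).
#' @param split A [split_spec()]; its seed is re-derived per repeat.
#' @param limits A [train_limits()].
#' @param seed Base seed; every repeat's split and initialization seed
#'   derives from it deterministically.
#' @return A list of class `node_sweep` with `table` (one row per
#'   candidate: mean held-out R-squared per time point and overall) and
#'   `selected` (the chosen hidden-node count).
#' @export
node_sweep <- function(dataset, candidates = 3:10, repeats = 1L,
                       split = split_spec(), limits = train_limits(),
                       seed = 1L) {
  stopifnot(inherits(dataset, "formulation_dataset"))
  candidates <- as.integer(candidates)
  if (length(candidates) < 1L) stopf("candidate list must not be empty")
  if (any(candidates < 1L | candidates > 64L)) {
    stopf("candidate node counts must lie in [1, 64]")
  }
  if (repeats < 1L) stopf("repeats must be at least 1")
  nt <- length(dataset$times_h)
  acc <- matrix(NA_real_, length(candidates), nt)
  n_ok <- integer(length(candidates))
  for (ci in seq_along(candidates)) {
    sums <- numeric(nt); ok <- 0L
    for (r in seq_len(repeats)) {
      sp <- split_spec(split$train_fraction,
                       split$validation_fraction_of_test,
                       seed = derive_seed(seed, r))
      res <- try(train_mlp(dataset, candidates[ci], split = sp,
                           limits = limits,
                           seed = derive_seed(seed, 1000L * candidates[ci] + r)),
                 silent = TRUE)
      if (inherits(res, "try-error")) next
      held_out <- c(res$split$validation, res$split$test)
      r2 <- evaluate_r2(res$net, dataset, held_out)
      sums <- sums + ifelse(is.na(r2), 0, r2)
      ok <- ok + 1L
    }
    n_ok[ci] <- ok
    if (ok > 0L) acc[ci, ] <- sums / ok
  }
  if (all(n_ok == 0L)) stopf("training failed for every candidate")
  tab <- data.frame(n_hidden = candidates, acc,
                    mean_r2 = rowMeans(acc),
                    n_successful = n_ok)
  names(tab)[1L + seq_len(nt)] <- paste0("r2_",
                                         profile_colnames(dataset$times_h))
  usable <- which(n_ok > 0L)
  best <- usable[order(-tab$mean_r2[usable], tab$n_hidden[usable])][1L]
  structure(list(table = tab, selected = candidates[best]),
            class = "node_sweep")
}

#' @export
print.node_sweep <- function(x, ...) {
  cat("Hidden-node sweep (held-out R^2 per time point):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Selected hidden nodes: %d\n", x$selected))
  invisible(x)
}
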