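test_that("records split 20/7/3 under the default fractions", {
  ds <- realizable_dataset()
  idx <- split_dataset(ds, split_spec(seed = 4))
  expect_length(idx$train, 20L)
  expect_length(idx$validation, 7L)
  expect_length(idx$test, 3L)
  expect_setequal(c(idx$train, idx$validation, idx$test), 1:30)
  # deterministic given the seed
  expect_identical(idx, split_dataset(ds, split_spec(seed = 4)))
  expect_false(identical(idx, split_dataset(ds, split_spec(seed = 5))))
})

test_that("degenerate split fractions are rejected", {
  expect_error(split_spec(train_fraction = 1), "strictly between")
  expect_error(split_spec(train_fraction = 0), "strictly between")
  expect_error(split_spec(validation_fraction_of_test = 1.2),
               "strictly between")
  ds <- realizable_dataset()
  small <- formulation_dataset(ds$id[1:2], ds$composition[1:2, ],
                               ds$release[1:2, ])
  expect_error(split_dataset(small), "at least 3")
  # 3 records train/validation/test = 2/1/0: empty test partition
  three <- formulation_dataset(ds$id[1:3], ds$composition[1:3, ],
                               ds$release[1:3, ])
  expect_error(split_dataset(three), "empty")
})

test_that("a realizable one-node target is recovered to near-zero error", {
  ds <- realizable_dataset()
  res <- train_mlp(ds, 1, split = split_spec(seed = 2), seed = 8)
  ep <- res$history$epochs
  expect_lt(min(ep$train_mse), 1e-6)
  # LM acceptance rule: training error never increases across epochs
  expect_true(all(diff(ep$train_mse) <= 0))
  expect_true(res$history$stop_reason %in%
                c("max_epochs", "validation_failures", "gradient_converged"))
})

test_that("training is deterministic given seeds", {
  ds <- generate_study(seed = 17)
  lim <- train_limits(max_epochs = 60)
  a <- train_mlp(ds, 3, split = split_spec(seed = 1), limits = lim, seed = 5)
  b <- train_mlp(ds, 3, split = split_spec(seed = 1), limits = lim, seed = 5)
  expect_identical(a$net$input_weights, b$net$input_weights)
  expect_identical(a$history$epochs, b$history$epochs)
  c <- train_mlp(ds, 3, split = split_spec(seed = 1), limits = lim, seed = 6)
  expect_false(identical(a$net$input_weights, c$net$input_weights))
})

test_that("the best-validation checkpoint is what the history claims", {
  ds <- generate_study(seed = 23)
  res <- train_mlp(ds, 4, split = split_spec(seed = 3),
                   limits = train_limits(max_epochs = 150), seed = 9)
  h <- res$history
  expect_equal(h$best_validation_mse, min(h$epochs$validation_mse))
  expect_equal(h$best_epoch, which.min(h$epochs$validation_mse))
  # the returned network reproduces the checkpointed validation error
  idx <- res$split$validation
  sc_in <- res$net$input_scaler; sc_tg <- res$net$target_scaler
  pred <- apply_scaler(sc_tg, predict_profiles(res$net,
                                               ds$composition[idx, ]))
  obs <- apply_scaler(sc_tg, ds$release[idx, ])
  expect_equal(mean((pred - obs)^2), h$best_validation_mse,
               tolerance = 1e-10)
})

test_that("in the near-linear regime LM matches the least-squares optimum", {
  # targets generated by a tiny-weight network, so the hidden sigmoids
  # operate in their linear region and the affine least-squares fit
  # (normal equations) is the relevant error floor
  set.seed(77)
  comp <- study_design()$composition
  in_sc <- fit_scaler(comp)
  xs <- apply_scaler(in_sc, comp)
  w <- matrix(runif(4, -0.02, 0.02), 1, 4)
  h <- 1 / (1 + exp(-(xs %*% t(w) + 0.01)))
  rel <- sweep(h %*% matrix(seq(20, 45, 5), 1, 6), 2, seq(30, 55, 5), `+`)
  ds <- formulation_dataset(sprintf("L%02d", 1:30), comp, rel)
  net <- retrain_full(ds, 2, limits = train_limits(max_epochs = 400),
                      seed = 3)
  pred <- apply_scaler(net$target_scaler, predict_profiles(net, comp))
  obs <- apply_scaler(net$target_scaler, ds$release)
  mlp_mse <- mean((pred - obs)^2)
  X <- cbind(1, xs)
  ls_mse <- mean((obs - X %*% solve(crossprod(X), crossprod(X, obs)))^2)
  expect_lt(abs(mlp_mse - ls_mse), 1e-6)
})

test_that("retraining on the full corpus is deterministic and unsplit", {
  ds <- realizable_dataset()
  lim <- train_limits(max_epochs = 200)
  n1 <- retrain_full(ds, 1, limits = lim, seed = 12)
  n2 <- retrain_full(ds, 1, limits = lim, seed = 12)
  expect_identical(n1$input_weights, n2$input_weights)
  h <- attr(n1, "history")
  expect_true(all(is.na(h$epochs$validation_mse)))
  expect_true(all(diff(h$epochs$train_mse) <= 0))
  expect_lt(min(h$epochs$train_mse), 1e-6)
})

test_that("the surrogate recovers the noiseless release function on held-out records", {
  # function recovery: with no observation noise, some hidden size in
  # 5..10 must predict held-out records with R^2 >= 0.95 at every time
  # point (checked at each of three seeds)
  p <- release_model_params(noise_sd = 0)
  for (s in 1:3) {
    ds <- generate_study(p, seed = 600 + s)
    found <- FALSE
    for (h in 5:10) {
      res <- train_mlp(ds, h, split = split_spec(seed = 700 + s),
                       seed = 800 + 10 * s + h)
      r2 <- evaluate_r2(res$net, ds, c(res$split$validation, res$split$test))
      if (all(r2 >= 0.95)) { found <- TRUE; break }
    }
    expect_true(found,
                label = sprintf("noiseless recovery at seed %d", 600 + s))
  }
})
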