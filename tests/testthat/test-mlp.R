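test_that("a zero network predicts the midpoint of each target range", {
  in_sc <- fit_scaler(study_design()$composition)
  tg_sc <- structure(list(min = seq(10, 60, 10), max = seq(50, 100, 10)),
                     class = "minmax_scaler")
  net <- mlp_surrogate(matrix(0, 3, 4), rep(0, 3), matrix(0, 6, 3),
                       rep(0, 6), in_sc, tg_sc)
  p <- forward(net, formulation(90, 25, 15, 16))
  expect_equal(p$release_pct, (seq(10, 60, 10) + seq(50, 100, 10)) / 2)
})

test_that("a one-node network matches hand evaluation", {
  in_sc <- structure(list(min = rep(-1, 4), max = rep(1, 4)),
                     class = "minmax_scaler")  # identity input scaling
  tg_sc <- structure(list(min = rep(0, 2), max = rep(100, 2)),
                     class = "minmax_scaler")
  net <- mlp_surrogate(matrix(c(0.5, -0.25, 0.1, 0.2), 1, 4), 0.3,
                       matrix(c(0.8, -0.6), 2, 1), c(0.1, -0.2),
                       in_sc, tg_sc, times_h = c(1, 2))
  x <- c(0.4, -0.8, 0.6, 0.2)
  z <- 0.5 * 0.4 - 0.25 * -0.8 + 0.1 * 0.6 + 0.2 * 0.2 + 0.3
  h <- 1 / (1 + exp(-z))
  y_scaled <- c(0.8 * h + 0.1, -0.6 * h - 0.2)
  expected <- y_scaled * 50 + 50
  p <- forward(net, formulation(x[1], x[2], x[3], x[4], check = FALSE))
  expect_equal(p$release_pct, expected, tolerance = 1e-12)
})

test_that("vectorized evaluation agrees with explicit-loop brute force", {
  set.seed(23)
  for (rep in 1:30) {
    net <- random_net(n_hidden = sample(1:6, 1))
    x <- runif(4, -2, 6)
    expect_equal(drop(predict_profiles(net, matrix(x, 1))),
                 oracle_forward(net, x), tolerance = 1e-12)
  }
  # batch evaluation equals one-at-a-time evaluation
  net <- random_net(4)
  X <- matrix(runif(20, 0, 10), 5, 4)
  batch <- predict_profiles(net, X)
  for (i in 1:5) {
    expect_equal(batch[i, ], oracle_forward(net, X[i, ]), tolerance = 1e-12)
  }
})

test_that("inconsistent network dimensions are rejected", {
  in_sc <- fit_scaler(matrix(runif(8), 2, 4))
  tg_sc <- fit_scaler(matrix(runif(12), 2, 6))
  expect_error(mlp_surrogate(matrix(0, 3, 4), rep(0, 2), matrix(0, 6, 3),
                             rep(0, 6), in_sc, tg_sc), "hidden")
  expect_error(mlp_surrogate(matrix(0, 3, 4), rep(0, 3), matrix(0, 6, 2),
                             rep(0, 6), in_sc, tg_sc), "hidden")
  expect_error(mlp_surrogate(matrix(NA_real_, 3, 4), rep(0, 3),
                             matrix(0, 6, 3), rep(0, 6), in_sc, tg_sc),
               "finite")
})

test_that("model serialization round-trips exactly", {
  set.seed(31)
  net <- random_net(5)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(net, path)
  net2 <- read_surrogate(path)
  expect_equal(net2$input_weights, net$input_weights, tolerance = 0)
  expect_equal(net2$output_weights, net$output_weights, tolerance = 0)
  expect_equal(net2$input_biases, net$input_biases, tolerance = 0)
  expect_equal(net2$output_biases, net$output_biases, tolerance = 0)
  expect_equal(net2$target_scaler$min, unname(net$target_scaler$min),
               tolerance = 0)
  x <- matrix(runif(8, 0, 5), 2, 4)
  expect_identical(predict_profiles(net2, x), predict_profiles(net, x))
  expect_error(read_surrogate(withr::local_tempfile(lines = "{}",
                                                    fileext = ".json")),
               "not a surrogate")
})
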