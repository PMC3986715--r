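test_that("grid enumeration counts and ordering are exact", {
  g2 <- search_grid(min = c(0, 0, 0, 4), max = c(5, 5, 2.5, 6),
                    step = c(5, 5, 2.5, 2))
  m <- enumerate_grid(g2)
  expect_equal(nrow(m), 16L)  # two levels per axis
  # lexicographic: first factor slowest, last factor fastest
  expect_equal(m[1, ], c(methocel_mg = 0, xanthan_mg = 0, carbopol_mg = 0,
                         surelease_pct = 4))
  expect_equal(unname(m[2, ]), c(0, 0, 0, 6))
  expect_equal(unname(m[16, ]), c(5, 5, 2.5, 6))
  expect_false(is.unsorted(m[, 1]))

  # a collapsed axis contributes one level
  g1 <- search_grid(min = c(0, 0, 0, 4), max = c(5, 5, 2.5, 4),
                    step = c(5, 5, 2.5, 2))
  expect_equal(nrow(enumerate_grid(g1)), 8L)

  expect_equal(nrow(enumerate_grid(search_grid())), 25L * 21L * 9L * 9L)
})

test_that("grid specifications outside the domain are rejected", {
  expect_error(search_grid(max = c(130, 100, 20, 20)), "methocel_mg")
  expect_error(search_grid(min = c(0, 0, 0, 2)), "surelease_pct")
  expect_error(search_grid(step = c(0, 5, 2.5, 2)), "positive")
  expect_error(search_grid(min = c(10, 0, 0, 4), max = c(5, 100, 20, 20)),
               "exceeds")
})

test_that("a single-candidate grid returns that candidate", {
  set.seed(2)
  net <- random_net(2)
  ref <- dissolution_profile(rep(50, 6), check = FALSE)
  g <- search_grid(min = c(60, 50, 10, 12), max = c(60, 50, 10, 12),
                   step = c(1, 1, 1, 1))
  res <- optimize_formulation(net, ref, g)
  expect_equal(res$n_evaluated, 1L)
  expect_equal(unname(unclass(res$best)), c(60, 50, 10, 12))
})

test_that("planting the reference at a grid member is a perfect self-match", {
  set.seed(3)
  net <- random_net(3)
  g <- search_grid(min = c(30, 25, 5, 8), max = c(90, 75, 15, 16),
                   step = c(30, 25, 5, 4))
  cstar <- formulation(60, 50, 10, 12)
  ref <- forward(net, cstar)
  res <- optimize_formulation(net, ref, g)
  expect_equal(unname(unclass(res$best)), c(60, 50, 10, 12))
  expect_equal(res$f2, 100)
  expect_equal(res$predicted_profile$release_pct, ref$release_pct)
})

test_that("the winner matches an independent exhaustive re-scan", {
  set.seed(13)
  for (rep in 1:5) {
    net <- random_net(3)
    ref <- dissolution_profile(sort(runif(6, 20, 99)), check = FALSE)
    g <- search_grid(min = c(0, 0, 0, 4), max = c(120, 100, 20, 20),
                     step = c(60, 50, 10, 8))  # 3 levels per axis
    res <- optimize_formulation(net, ref, g)
    expect_equal(res$n_evaluated, 81L)
    # oracle: explicit nested loops with the independent f2 transcription
    best_f2 <- -Inf; best_c <- NULL
    for (x1 in c(0, 60, 120)) for (x2 in c(0, 50, 100))
      for (x3 in c(0, 10, 20)) for (x4 in c(4, 12, 20)) {
        y <- oracle_forward(net, c(x1, x2, x3, x4))
        v <- oracle_f2(ref$release_pct, y)
        if (v > best_f2) { best_f2 <- v; best_c <- c(x1, x2, x3, x4) }
      }
    expect_equal(unname(unclass(res$best)), best_c)
    expect_equal(res$f2, best_f2, tolerance = 1e-12)
  }
})

test_that("a sub-grid containing the full-grid winner returns the same winner", {
  set.seed(19)
  net <- random_net(4)
  ref <- dissolution_profile(sort(runif(6, 25, 98)), check = FALSE)
  g <- search_grid(step = c(20, 20, 5, 4))
  res <- optimize_formulation(net, ref, g)
  b <- unclass(res$best)
  sub <- search_grid(min = pmax(c(0, 0, 0, 4), b - c(20, 20, 5, 4)),
                     max = pmin(c(120, 100, 20, 20), b + c(20, 20, 5, 4)),
                     step = c(20, 20, 5, 4))
  res_sub <- optimize_formulation(net, ref, sub)
  expect_equal(unclass(res_sub$best), b)
  expect_equal(res_sub$f2, res$f2)
})

test_that("the top-k table is ranked and headed by the winner", {
  set.seed(29)
  net <- random_net(3)
  ref <- dissolution_profile(sort(runif(6, 25, 98)), check = FALSE)
  res <- optimize_formulation(net, ref,
                              search_grid(step = c(30, 25, 10, 8)),
                              top_k = 5L)
  expect_equal(nrow(res$top_k), 5L)
  expect_false(is.unsorted(rev(res$top_k$f2)))
  expect_equal(res$top_k$f2[1], res$f2)
  expect_equal(unname(unlist(res$top_k[1, 1:4])), unname(unclass(res$best)))
})
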