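test_that("the release curve matches the closed form at a known point", {
  # tau fixed at 2 h, beta at 1: y(1) = 100 (1 - exp(-1/2))
  p <- release_model_params(a0 = log(2), a1 = 0, a2 = 0, a3 = 0, a4 = 0,
                            a12 = 0, beta_base = 1, beta_slope = 0,
                            noise_sd = 0)
  prof <- simulate_profile(formulation(60, 50, 10, 12), p)
  expect_equal(prof$release_pct[1], 100 * (1 - exp(-0.5)), tolerance = 1e-12)
  expect_equal(prof$release_pct[1], 39.346934028736655, tolerance = 1e-9)
  # late-time asymptote approaches complete release
  far <- simulate_profile(formulation(60, 50, 10, 12), p,
                          times_h = c(1, 1000))
  expect_equal(far$release_pct[2], 100, tolerance = 1e-6)
})

test_that("release model parameter invariants are enforced", {
  expect_error(release_model_params(noise_sd = -1), "non-negative")
  expect_error(release_model_params(beta_base = 0.3, beta_slope = 0.05),
               "beta")
  expect_error(release_model_params(beta_base = 1.49, beta_slope = 0.05),
               "beta")
  expect_error(release_model_params(a0 = Inf), "finite")
})

test_that("noiseless profiles rise with time and fall with polymer level", {
  p <- release_model_params(noise_sd = 0)
  base <- simulate_profile(formulation(60, 50, 10, 12), p)$release_pct
  expect_true(all(diff(base) > 0))
  expect_true(all(base <= 100))
  # raising any retarding factor never increases release at any time
  up <- list(formulation(90, 50, 10, 12), formulation(60, 75, 10, 12),
             formulation(60, 50, 15, 12), formulation(60, 50, 10, 16))
  for (f in up) {
    expect_true(all(simulate_profile(f, p)$release_pct <= base))
  }
})

test_that("the design corpus lands in the study's release envelope", {
  p <- release_model_params(noise_sd = 0)
  ds <- generate_study(p, seed = 1)
  expect_equal(length(ds), 30L)
  expect_identical(ds$id, sprintf("SAL%03d", 1:30))
  expect_true(all(ds$release[, 1] >= 20 & ds$release[, 1] <= 55))
  expect_true(all(ds$release[, 6] >= 80))
})

test_that("noise is seeded, bounded and monotone-repaired", {
  p <- release_model_params()  # noise_sd = 1
  a <- generate_study(p, seed = 6)
  b <- generate_study(p, seed = 6)
  c <- generate_study(p, seed = 7)
  expect_identical(a$release, b$release)
  expect_false(identical(a$release, c$release))
  # noise perturbs profiles but only within a plausible Gaussian band
  noiseless <- generate_study(release_model_params(noise_sd = 0))
  expect_lte(max(abs(a$release - noiseless$release)), 5 * p$noise_sd)
  expect_true(all(apply(a$release, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(a$release >= 0 & a$release <= 100))
  # zero noise is reproducible without any seed dependence
  expect_identical(generate_study(release_model_params(noise_sd = 0), seed = 1)$release,
                   generate_study(release_model_params(noise_sd = 0), seed = 99)$release)
})

test_that("the synthetic reference is the noiseless profile at its composition", {
  p <- release_model_params()
  centre <- formulation(60, 50, 10, 12)
  ref <- make_reference(p, centre)
  expect_equal(ref$release_pct,
               simulate_profile(centre, p)$release_pct)
  expect_equal(f2_similarity(ref, simulate_profile(centre, p))$f2, 100)
  # profiles at opposite factorial corners are distinct but comparable
  lo <- make_reference(p, formulation(30, 25, 5, 8))
  hi <- make_reference(p, formulation(90, 75, 15, 16))
  v <- f2_similarity(lo, hi)
  expect_lt(v$f2, 100)
  expect_equal(v$f2, oracle_f2(lo$release_pct, hi$release_pct),
               tolerance = 1e-12)
})
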