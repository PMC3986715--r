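#' Parameters of the synthetic Weibull release model
#'
#' The synthetic generator stands in for an in vitro dissolution study:
#' it maps a composition to a cumulative release curve with the
#' qualitative structure of hydrophilic matrix dissolution — fast early
#' release that slows as the gel layer forms, roughly 25-50% released at
#' 1 h and >80% at 12 h across the design, and higher polymer levels
#' retarding release.
#'
#' The noiseless curve is a Weibull cumulative form
#' `y(t) = 100 (1 - exp(-(t / tau)^beta))`, bounded at 100% and concave
#' for `beta < 1` (diffusion-like kinetics). The time scale `tau`
#' depends log-linearly on the domain-scaled composition
#' `u` in \[-1, 1]^4 (with one interaction between the two main gelling
#' polymers), and the shape `beta` drifts with the HPMC level:
#' `tau = exp(a0 + a1 u1 + a2 u2 + a3 u3 + a4 u4 + a12 u1 u2)`,
#' `beta = beta_base + beta_slope * u1`.
#'
#' @param a0,a1,a2,a3,a4,a12 Log-time-scale coefficients (intercept, four
#'   main effects, HPMC-xanthan interaction).
#' @param beta_base,beta_slope Weibull shape intercept and HPMC slope;
#'   the resulting beta must stay in (0.3, 1.5) over the domain.
#' @param noise_sd Standard deviation of additive measurement noise, in
#'   percentage points (default 1).
#' @return An object of class `release_model_params`.
#' @export
release_model_params <- function(a0 = 0.9, a1 = 0.18, a2 = 0.13, a3 = 0.06,
                                 a4 = 0.09, a12 = 0.03, beta_base = 0.75,
                                 beta_slope = 0.05, noise_sd = 1) {
  a <- c(a0 = a0, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a12 = a12)
  if (anyNA(a) || any(!is.finite(a))) stopf("coefficients must be finite")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  beta_rng <- beta_base + c(-1, 1) * abs(beta_slope)
  if (beta_rng[1] <= 0.3 || beta_rng[2] >= 1.5) {
    stopf("beta must stay within (0.3, 1.5) over the domain; got [%g, %g]",
          beta_rng[1], beta_rng[2])
  }
  structure(list(a = a, beta_base = beta_base, beta_slope = beta_slope,
                 noise_sd = noise_sd),
            class = "release_model_params")
}

# domain-scaled composition: each factor mapped linearly onto [-1, 1]
# over the experimental domain
domain_scale <- function(x) {
  x <- as_formulation_vector(x)
  2 * (x - .factor_min) / (.factor_max - .factor_min) - 1
}

weibull_release <- function(times_h, tau, beta) {
  100 * (1 - exp(-(times_h / tau)^beta))
}

#' Simulate a dissolution profile for one composition
#'
#' Evaluates the synthetic release model at the canonical sampling
#' times. With `with_noise = TRUE`, seeded Gaussian noise is added, the
#' values are clipped to \[0, 100] and monotone non-decrease is restored
#' by a running maximum (cumulative release cannot fall).
#'
#' @param formulation A [formulation()] (in the experimental domain).
#' @param params A [release_model_params()].
#' @param with_noise Add measurement noise?
#' @param seed Seed for the noise draw (required when `with_noise`).
#' @param times_h Sampling times (default canonical schedule).
#' @return A [dissolution_profile()].
#' @examples
#' simulate_profile(formulation(60, 50, 10, 12), release_model_params())
#' @export
simulate_profile <- function(formulation, params = release_model_params(),
                             with_noise = FALSE, seed = 1L,
                             times_h = canonical_times()) {
  stopifnot(inherits(params, "release_model_params"))
  u <- domain_scale(formulation)
  a <- params$a
  tau <- exp(a[["a0"]] + a[["a1"]] * u[1] + a[["a2"]] * u[2] +
             a[["a3"]] * u[3] + a[["a4"]] * u[4] + a[["a12"]] * u[1] * u[2])
  beta <- params$beta_base + params$beta_slope * u[1]
  y <- weibull_release(times_h, tau, beta)
  if (with_noise && params$noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, params$noise_sd))
    y <- pmin(100, pmax(0, y))
    y <- cummax(y)
  }
  dissolution_profile(y, times_h)
}

#' Generate a synthetic dissolution study
#'
#' Simulates one noisy dissolution profile per design formulation,
#' producing a complete training corpus with the structure of the
#' 30-run central composite study. Deterministic for a given seed.
#'
#' @param params A [release_model_params()].
#' @param design A [formulation_dataset()] (profiles ignored) or a
#'   compositions matrix; defaults to the study design
#'   [study_design()].
#' @param seed Integer seed; per-record noise seeds are derived from it.
#' @return A [formulation_dataset()] with profiles.
#' @export
generate_study <- function(params = release_model_params(),
                           design = study_design(), seed = 1L) {
  stopifnot(inherits(params, "release_model_params"))
  if (inherits(design, "formulation_dataset")) {
    comp <- design$composition
    ids <- design$id
  } else {
    comp <- as.matrix(design)
    ids <- sprintf("SAL%03d", seq_len(nrow(comp)))
  }
  if (nrow(comp) < 1L) stopf("design is empty")
  rel <- matrix(NA_real_, nrow(comp), length(canonical_times()))
  for (i in seq_len(nrow(comp))) {
    rel[i, ] <- simulate_profile(comp[i, ], params,
                                 with_noise = params$noise_sd > 0,
                                 seed = derive_seed(seed, i))$release_pct
  }
  formulation_dataset(ids, comp, release = rel)
}

#' Synthetic reference profile
#'
#' The noiseless model profile at a chosen composition, used as the
#' target that the optimizer tries to match (a stand-in for a marketed
#' reference product whose profile is not publicly tabulated).
#'
#' @param params A [release_model_params()].
#' @param composition A [formulation()] in the domain.
#' @return A [dissolution_profile()].
#' @export
make_reference <- function(params = release_model_params(),
                           composition = formulation(45, 30, 5, 10)) {
  simulate_profile(composition, params, with_noise = FALSE)
}
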