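test_that("feature cost matches its definition", {
  y <- list(profile = c(1, 2, 3))
  expect_equal(feature_cost(y, y), 0)
  expect_equal(feature_cost(y, list(profile = rep(2, 3))), 1)
  expect_equal(feature_cost(y, list(profile = c(1, 2, 4))), 0.5)
  two <- list(a = c(1, 2, 3), b = c(0, 1))
  expect_equal(feature_cost(two, list(a = c(1, 2, 4), b = c(0, 1))), 0.25)
  expect_error(feature_cost(list(a = c(1, 1)), list(a = c(1, 1))), "variance")
  expect_error(feature_cost(y, list(other = 1:3)), "names")
})

test_that("pattern search solves quadratics and never regresses", {
  r <- pattern_search(function(x) (x - 2)^2, 0, budget = 600)
  expect_lt(abs(r$x - 2), 1e-4)
  expect_equal(pattern_search(function(x) x^2, 3, budget = 0)$x, 3)
  f2 <- function(x) (x[1] - 1)^2 + (100 * x[2] - 1)^2
  r2 <- pattern_search(f2, c(5, 0.5), scale = c(1, 0.01), budget = 2000,
                       mesh_tol = 1e-7)
  expect_lt(abs(r2$x[1] - 1), 1e-3)
  expect_lt(abs(r2$x[2] - 0.01), 1e-3)
  set.seed(2)
  for (i in 1:10) {
    x0 <- rnorm(3)
    f <- function(x) sum(sin(3 * x) + x^2)
    expect_lte(pattern_search(f, x0, budget = 60)$value, f(x0))
  }
})

test_that("profile BIC has the Gaussian-residual algebra", {
  expect_equal(bic_profile(1, 16, 5) - bic_profile(1, 16, 3), 2 * log(16))
  expect_equal(bic_profile(0.5, 16, 3) - bic_profile(1, 16, 3), -16 * log(2))
  expect_lt(bic_profile(0, 16, 3), -1e9)
})

test_that("envelope-model fitting recovers an OU target", {
  env <- simulate_ou(1, 1, 1e-3, 5e3, seed = 21)
  target <- burst_profiles(env, min_duration = 0)
  fit <- fit_envelope_model(target, degree = 1, n_starts = 50,
                            refine_top = 5, budget = 400, seed = 4)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(abs(-fit$coeffs[2] - 1), 0.2)
  # self-fit on an analytic cubic target
  cub <- cubic_fixture_drift()
  target2 <- analytic_profile(cub, 1, 1e-3)
  fit2 <- fit_envelope_model(target2, degree = 3, n_starts = 200,
                             refine_top = 10, budget = 600, seed = 5)
  expect_gte(fit2$r_squared, 0.95)
})

test_that("more random starts never hurt the attained cost", {
  env <- simulate_ou(1, 1, 1e-3, 2e3, seed = 31)
  target <- burst_profiles(env, min_duration = 0)
  costs <- vapply(1:8, function(s) {
    c(fit_envelope_model(target, 1, n_starts = 1, refine_top = 1,
                         budget = 60, seed = s)$cost,
      fit_envelope_model(target, 1, n_starts = 10, refine_top = 2,
                         budget = 60, seed = s)$cost)
  }, numeric(2))
  expect_lte(mean(costs[2, ]), mean(costs[1, ]))
})

test_that("envelope-PDF rejection rule fires on grossly wrong fits", {
  env <- simulate_ou(1, 1, 1e-3, 2e3, seed = 41)
  target <- burst_profiles(env, min_duration = 0)
  pdf <- envelope_pdf(env, n_bins = 40)
  # profile fits are scale-degenerate: a target PDF pins the amplitude scale,
  # and fits with a stationary density unrelated to it are rejected
  expect_error(
    fit_envelope_model(target, degree = 1, n_starts = 1, refine_top = 1,
                       budget = 5, seed = 300, target_pdf = pdf,
                       zeta_bounds = 0.01),
    "PDF")
})

test_that("Wilson-Cowan self-fit attains a usable fit at desk scale", {
  p <- wc_linear_fixture()
  target <- wc_features(p, n_repeats = 2, repeat_duration = 50,
                        min_duration = 0, seed = 77)
  fit <- fit_wc(target, "linear", n_starts = 50, refine_top = 3, budget = 150,
                n_repeats = 2, repeat_duration = 50, min_duration = 0,
                seed = 8)
  expect_gte(fit$r_squared, 0.75)
  # every accepted candidate satisfied the closed-form peak screen by design;
  # the best fit must too
  sp <- wc_psd_linear(fit$params, seq(1, 100, by = 0.5), dt = 1e-3)
  dp <- target$psd
  expect_lt(abs(seq(1, 100, by = 0.5)[which.max(sp)] -
                  dp$freq[which.max(dp$power)]), 2)
})

test_that("a nonlinear delayed target favours the sigmoid variant", {
  ps <- wc_sigmoid_fixture()
  target <- wc_features(ps, n_repeats = 2, repeat_duration = 50,
                        min_duration = 0, seed = 55)
  fs <- fit_wc(target, "sigmoid_delays", n_starts = 30, refine_top = 3,
               budget = 120, n_repeats = 2, repeat_duration = 40,
               min_duration = 0, screen_duration = 5, peak_mag_tol = 0.5,
               seed = 9)
  fl <- fit_wc(target, "linear", n_starts = 30, refine_top = 3, budget = 120,
               n_repeats = 2, repeat_duration = 40, min_duration = 0,
               peak_mag_tol = 0.5, seed = 9)
  expect_gt(fs$r_squared, fl$r_squared)
  expect_lt(fs$bic, fl$bic)
})
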