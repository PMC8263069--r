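test_that("the linear variant sits at its fixed point without noise", {
  p <- wc_linear_fixture()
  p$zeta <- 1e-12
  sim <- simulate_wc(p, 1e-3, 2, seed = 1, burn_in = 0, init = c(0, 0))
  expect_true(all(abs(as.numeric(sim$E)) < 1e-9))
  expect_true(all(abs(as.numeric(sim$I)) < 1e-9))
})

test_that("deterministic delayed sigmoid dynamics are step-size consistent", {
  # short horizon from identical initial data: on a periodic attractor the
  # O(dt) phase drift accumulates with time, so consistency is a
  # short-horizon statement
  p <- wc_sigmoid_fixture()
  p$zeta <- 1e-12
  dur <- 0.1
  sim <- function(dt) as.numeric(
    simulate_wc(p, dt, dur, seed = 1, burn_in = 0, init = c(0.5, 0.5))$E)
  a <- sim(1e-3)
  b <- sim(5e-4)[seq(2, 2 * length(a), by = 2)]
  d <- sim(2.5e-4)[seq(4, 4 * length(a), by = 4)]
  e1 <- sqrt(mean((a - b)^2))
  e2 <- sqrt(mean((b - d)^2))
  expect_lt(e1 / sd(a), 0.06)       # small discrepancy at the base step
  expect_gt(e1 / e2, 1.5)           # and it halves when the step halves
  expect_lt(e1 / e2, 2.5)
  # the trajectory settles onto a bounded attractor
  aL <- sim(1e-3)
  expect_lt(max(abs(aL)), 10)
})

test_that("the linear spectrum peaks at the Jacobian's imaginary part", {
  p <- wc_linear_fixture()
  ev <- eigen(wc_jacobian(p))$values
  f_pred <- abs(Im(ev[1])) / (2 * pi)
  sim <- simulate_wc(p, 2.5e-4, 120, seed = 3)
  sp <- psd(sim$E, window_s = 2)
  expect_lt(abs(sp$freq[which.max(sp$power)] - f_pred), 0.5)
  sim <- simulate_wc(p, 1e-3, 120, seed = 3)
  sp <- psd(sim$E)
  # the discretized closed-form spectrum matches the Welch estimate
  sel <- sp$freq >= f_pred - 10 & sp$freq <= f_pred + 10
  cf <- wc_psd_linear(p, sp$freq[sel], dt = 1e-3)
  expect_lt(max(abs(cf - sp$power[sel]) / cf), 0.25)
})

test_that("linear output is Gaussian", {
  p <- wc_linear_fixture()
  sim <- simulate_wc(p, 1e-3, 1000, seed = 4)
  e <- as.numeric(sim$E)
  expect_lt(abs(mean((e - mean(e))^4) / sd(e)^4 - 3), 0.1)
  expect_lt(abs(mean((e - mean(e))^3) / sd(e)^3), 0.05)
})

test_that("zero delays reproduce the non-delayed trajectory exactly", {
  p <- wc_sigmoid_fixture()
  p0 <- p
  p0$delta_IE <- p0$delta_EI <- p0$delta_II <- 0
  a <- simulate_wc(p0, 1e-3, 5, seed = 6)
  b <- simulate_wc(p0, 1e-3, 5, seed = 6)
  expect_identical(as.numeric(a$E), as.numeric(b$E))
  # and differs from the delayed dynamics with the same seed
  d <- simulate_wc(p, 1e-3, 5, seed = 6)
  expect_false(identical(as.numeric(a$E), as.numeric(d$E)))
})

test_that("simulated variance is finite exactly when the discretized system is stable", {
  # the Euler map x -> (I + M dt) x is the system actually simulated; its
  # spectral radius, not the continuous eigenvalues, decides stability
  set.seed(8)
  dt <- 1e-3
  n_stable <- 0; n_unstable <- 0
  for (i in 1:20) {
    p <- wc_params(w_IE = runif(1, 0.5, 8), w_EI = runif(1, 0.5, 8),
                   w_II = runif(1, 0, 2), omega_E = runif(1, 0.012, 0.04),
                   omega_I = runif(1, 0.012, 0.04), zeta = 0.3,
                   activation = "linear", beta = runif(1, 0.5, 3))
    ev <- eigen(wc_jacobian(p), only.values = TRUE)$values
    expect_true(all(Re(ev) < 0))  # this model class is always stable in
    # continuous time; discretization can still destabilize it
    stable_disc <- all(Mod(1 + ev * dt) < 1)
    sim <- tryCatch(simulate_wc(p, dt, 8, seed = i, burn_in = 0),
                    error = function(e) NULL)
    if (stable_disc) {
      n_stable <- n_stable + 1
      expect_false(is.null(sim))
      expect_lt(var(as.numeric(sim$E)), 1e4)
    } else {
      n_unstable <- n_unstable + 1
      expect_true(is.null(sim) || var(as.numeric(sim$E)) > 1e4)
    }
  }
  expect_gt(n_stable, 0)
  expect_gt(n_unstable, 0)
})

test_that("repeat-averaged features are less variable and keep the grid", {
  p <- wc_linear_fixture()
  pct <- seq(0.2, 0.9, by = 0.1)
  ft <- wc_features(p, n_repeats = 3, repeat_duration = 30, percentiles = pct,
                    min_duration = 0, seed = 5)
  expect_equal(ft$profile$percentile, pct)
  set.seed(9)
  seeds <- sample.int(1e6, 8)
  single <- sapply(seeds, function(s)
    wc_features(p, n_repeats = 1, repeat_duration = 30, percentiles = pct,
                min_duration = 0, seed = s)$profile$mean_duration_s)
  avg <- sapply(seeds, function(s)
    wc_features(p, n_repeats = 3, repeat_duration = 30, percentiles = pct,
                min_duration = 0, seed = s)$profile$mean_duration_s)
  expect_lt(mean(apply(avg, 1, var)) / mean(apply(single, 1, var)), 1)
})
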