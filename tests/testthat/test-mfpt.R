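test_that("continuous MFPT has its boundary behaviour and matches an ODE oracle", {
  dr <- ou_drift(1)
  expect_equal(continuous_mfpt(dr, 1, 1, 1), 0)
  taus <- vapply(c(0.5, 1, 1.5, 2), function(x0)
    continuous_mfpt(dr, 1, x0, 0.2), numeric(1))
  expect_true(all(diff(taus) > 0))
  # independent oracle: integrate dT/dx = -2/zeta^2 - (2 mu / zeta^2) T
  # inward from a far boundary where T has its asymptotic 1/(theta x) form
  skip_if_not_installed("deSolve")
  xmax <- 12
  # integrate in the substituted variable s = xmax - x so time increases
  sol <- deSolve::ode(
    y = c(T = 1 / xmax), times = seq(0, xmax, by = 0.001),
    func = function(s, y, p) list(2 - 2 * (xmax - s) * y[1]), parms = NULL,
    method = "ode45")
  Tgrid <- approx(xmax - sol[, 1], sol[, 2], xout = seq(0, 1, by = 1e-3))$y
  tau_oracle <- sum((Tgrid[-1] + Tgrid[-length(Tgrid)]) / 2) * 1e-3
  expect_lt(abs(continuous_mfpt(dr, 1, 1, 0) - tau_oracle) / tau_oracle, 0.01)
  expect_error(continuous_mfpt(polynomial_drift(c(0, -1)), 1, 0.5, 1), "x0")
})

test_that("discrete burst duration reduces to the closed forms", {
  for (th in c(0.5, 1, 2)) {
    L <- c(0, 0.4, 1.1)
    expect_equal(discrete_burst_duration(ou_drift(th), 1, 1e-3, L),
                 ou_burst_duration(th, 1, 1e-3, L), tolerance = 1e-3)
  }
  # Rayleigh drift: quadrature of the general formula hits the closed form
  th <- 1.3; z <- 0.9; L <- 0.7; dt <- 1e-3
  quad <- sqrt(2 * pi * dt) / z *
    integrate(function(x) (x / L) * exp(-th * (x^2 - L^2) / z^2), L, Inf,
              rel.tol = 1e-10)$value
  expect_equal(quad, rayleigh_burst_duration(th, z, dt, L), tolerance = 1e-6)
  # explicit sqrt(dt) scaling
  t1 <- discrete_burst_duration(ou_drift(1), 1, 1e-3, 0.5)
  t2 <- discrete_burst_duration(ou_drift(1), 1, 4e-3, 0.5)
  expect_equal(t2 / t1, 2, tolerance = 1e-9)
})

test_that("OU closed forms evaluate to independently computed values", {
  expect_equal(ou_burst_duration(1, 1, 1e-3, 0), pi * sqrt(5e-4),
               tolerance = 1e-9)
  skip_if_not_installed("pracma")
  # independent special-function implementations for the expected values
  expect_equal(ou_burst_duration(1, 1, 1e-3, 1 / sqrt(2)),
               pi * sqrt(5e-4) * exp(0.5) * pracma::erfc(1 / sqrt(2)),
               tolerance = 1e-9)
  expect_equal(ou_burst_duration_percentile(1, 1e-3, 0.5), pi * sqrt(5e-4),
               tolerance = 1e-9)
  expect_equal(ou_burst_duration_percentile(1, 1e-3, 0.75),
               pi * sqrt(2e-3) * 0.25 * exp(pracma::erfinv(0.5)^2),
               tolerance = 1e-9)
  # exact discrete-time oracle at the median: 0.5 dt / P(below then above)
  a <- exp(-1e-3)
  p_up <- 1 / 4 - asin(a) / (2 * pi)
  expect_equal(ou_burst_duration(1, 1, 1e-3, 0), 0.5 * 1e-3 / p_up,
               tolerance = 5e-4)
})

test_that("threshold and percentile forms are equivalent under the CDF map", {
  set.seed(3)
  for (i in 1:20) {
    th <- runif(1, 0.2, 3); z <- runif(1, 0.1, 10); p <- runif(1, 0.05, 0.95)
    L <- z / sqrt(th) * qnorm(p) / sqrt(2)  # erfinv(2p - 1) via qnorm
    expect_equal(ou_burst_duration(th, z, 1e-3, L),
                 ou_burst_duration_percentile(th, 1e-3, p), tolerance = 1e-12)
  }
})

test_that("cubic burst duration has the right limits and monotonicity", {
  eps <- 1e-9
  near_ou <- cubic_burst_duration(c(0, -1, -eps, -eps), 1, 1e-3,
                                  c(0.2, 0.8, 1.5))
  expect_equal(near_ou, ou_burst_duration(1, 1, 1e-3, c(0.2, 0.8, 1.5)),
               tolerance = 5e-3)
  # monotone decay holds for a monostable drift without a shoulder (the
  # shoulder fixture is non-monotonic by design)
  plain <- polynomial_drift(c(1, -1, -0.2, -0.1))
  L <- seq(0.5, 4, by = 0.25)
  tau <- discrete_burst_duration(plain, 1, 1e-3, L)
  expect_true(all(diff(tau) < 0))
  expect_error(cubic_burst_duration(c(0, -1, 0, 1), 1, 1e-3, 1), "negative")
})

test_that("correction constants and the prefactor identity hold", {
  cc <- correction_constants(1, 1e-3)
  expect_equal(cc$gamma_bar, 0.02523133, tolerance = 1e-6)
  expect_equal(cc$delta_bar, 0.01981664, tolerance = 1e-6)
  expect_equal(cc$a0_first_step, 1 / pi - 1 / 2)
  expect_equal(cc$a0_empirical, (pi - 4) / (pi + 4))
  for (z in c(0.3, 1, 2.5)) for (dt in c(1e-4, 1e-3, 5e-2)) {
    cc <- correction_constants(z, dt)
    expect_equal((cc$delta_bar + cc$gamma_bar) * (2 * pi / (pi + 4)),
                 sqrt(pi * dt / 2) * z, tolerance = 1e-12)
  }
})

test_that("analytic percentile profiles are exact for OU and accurate on grids", {
  prof_ou <- analytic_profile(ou_drift(1), 1, 1e-3)
  expect_equal(prof_ou$mean_duration_s,
               ou_burst_duration_percentile(1, 1e-3, prof_ou$percentile),
               tolerance = 1e-12)
  # the fast grid path agrees with adaptive quadrature at its own thresholds
  cub <- cubic_fixture_drift()
  prof <- analytic_profile(cub, 1, 1e-3)
  expect_equal(prof$mean_duration_s,
               discrete_burst_duration(cub, 1, 1e-3, prof$threshold),
               tolerance = 1e-3)
})
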