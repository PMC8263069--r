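test_that("band preparation finds the OFF-state peak and z-scores both series", {
  dt <- 1e-3
  t <- seq(0, 30 - dt, by = dt)
  withr_seed <- function(s, n) { set.seed(s); rnorm(n) }
  off <- bd_timeseries(sin(2 * pi * 25 * t) + 0.05 * withr_seed(1, length(t)), dt)
  on <- bd_timeseries(sin(2 * pi * 25 * t + 1) + 0.05 * withr_seed(2, length(t)), dt)
  prep <- prepare_pair(on, off)
  expect_equal(prep$peak_hz, 25, tolerance = 0.5)
  expect_lt(abs(mean(prep$on)), 1e-9)
  expect_lt(abs(mean(prep$off)), 1e-9)
  expect_equal(sd(prep$on), 1, tolerance = 1e-9)
  expect_equal(sd(prep$off), 1, tolerance = 1e-9)
})

test_that("peak detection is accurate for band-limited noise across seeds", {
  dt <- 1e-3
  peaks <- vapply(1:50, function(s) {
    ts <- gen_pink_noise(20, dt, seed = s, band = c(17, 23))
    prepare_pair(ts, ts)$peak_hz
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 20), 0.5)
})

test_that("a spectrum with no peak inside the search band is rejected", {
  # out-of-band tone at a non-bin frequency: its leakage falls monotonically
  # through the band, so the in-band maximum sits at the band edge
  set.seed(11)
  t <- seq(0, 20 - 1e-3, by = 1e-3)
  tone <- bd_timeseries(sin(2 * pi * 36.5 * t) + 1e-3 * rnorm(length(t)), 1e-3)
  expect_error(prepare_pair(tone, tone), "no beta peak")
})

test_that("hilbert envelope recovers known amplitude structure", {
  dt <- 1e-3
  t <- seq(0, 10 - dt, by = dt)
  env <- hilbert_envelope(bd_timeseries(2 * cos(2 * pi * 20 * t), dt))
  core <- env[500:(length(env) - 500)]
  expect_lt(abs(median(core) - 2) / 2, 0.01)

  mod <- 1 + 0.5 * sin(2 * pi * 1 * t)
  am <- bd_timeseries(mod * cos(2 * pi * 20 * t), dt)
  e <- hilbert_envelope(am)
  idx <- 500:(length(t) - 500)
  expect_lt(sqrt(mean((e[idx] - mod[idx])^2)), 0.05)

  z <- hilbert_envelope(bd_timeseries(rep(0, 1000), dt))
  expect_true(all(z == 0))
})

test_that("burst detection matches hand enumeration and handles minimum duration", {
  env <- bd_envelope(c(0, 1, 1, 1, 0, 1, 1, 0), 0.01)
  b <- detect_bursts(env, 0.5, min_duration = 0)
  expect_equal(nrow(b), 2)
  expect_equal(b$duration, c(0.03, 0.02))
  expect_equal(mean(b$duration), 0.025)
  b2 <- detect_bursts(env, 0.5, min_duration = 0.025)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$duration, 0.03)
  expect_equal(nrow(detect_bursts(bd_envelope(rep(0, 50), 0.01), 0.5)), 0)
})

test_that("burst detection equals a brute-force run-length scanner on random envelopes", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    env <- round(abs(rnorm(n)), 2)
    thr <- round(runif(1, 0, 1.5), 2)
    mind <- sample(c(0, 0.02, 0.05), 1)
    got <- detect_bursts(bd_envelope(env, 0.01), thr, mind)
    want <- brute_force_bursts(env, thr, mind, 0.01)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("profiles reproduce hand-computed statistics on a step envelope", {
  env <- hand_envelope()
  pr <- burst_profiles(env, percentiles = c(0.3, 0.75, 0.9), min_duration = 0)
  # plateaus: 1 (5 samples), 2 (8), 3 (4), 4 (6); 50 zeros; N = 73
  thr <- quantile(as.numeric(env), c(0.3, 0.75, 0.9), names = FALSE)
  for (k in seq_along(thr)) {
    b <- brute_force_bursts(as.numeric(env), thr[k], 0, 0.01)
    expect_equal(pr$n_bursts[k], nrow(b))
    expect_equal(pr$mean_duration_s[k], mean((b$end - b$start) * 0.01))
  }
  expect_true(all(pr$mean_amplitude >= pr$threshold, na.rm = TRUE))
  expect_error(burst_profiles(bd_envelope(rep(1, 100), 0.01)), "degenerate")
})

test_that("burst rate satisfies the supra-threshold conservation identity", {
  env <- hand_envelope()
  pr <- burst_profiles(env, min_duration = 0)
  frac_above <- vapply(pr$threshold, function(L) mean(as.numeric(env) > L),
                       numeric(1))
  has <- pr$n_bursts > 0  # thresholds at the envelope maximum have no bursts
  expect_equal(pr$rate_hz[has] * pr$mean_duration_s[has], frac_above[has],
               tolerance = 1e-12)
  expect_true(all(frac_above[!has] == 0))
  # hand example: 2 bursts in 0.08 s
  e2 <- bd_envelope(c(0, 1, 1, 1, 0, 1, 1, 0), 0.01)
  expect_equal(detect_bursts(e2, 0.5, 0)$duration, c(0.03, 0.02))
  expect_equal(nrow(detect_bursts(e2, 0.5, 0)) / (8 * 0.01), 25)
  # identity on a simulated envelope
  sim <- simulate_ou(1, 1, 1e-3, 20, seed = 5)
  pr2 <- burst_profiles(sim, min_duration = 0)
  frac2 <- vapply(pr2$threshold, function(L) mean(as.numeric(sim) > L),
                  numeric(1))
  expect_equal(pr2$rate_hz * pr2$mean_duration_s, frac2, tolerance = 1e-12)
  # monotone supra-threshold counts
  expect_true(all(diff(frac2) <= 0))
})

test_that("envelope PDF is a normalized density with correct uniform limit", {
  set.seed(8)
  u <- runif(1e6)
  pdf <- envelope_pdf(u, n_bins = 10)
  expect_true(all(abs(pdf$density - 1) < 0.03))
  w <- pdf$bin_hi - pdf$bin_lo
  expect_equal(sum(pdf$density * w), 1, tolerance = 1e-12)
  # shifted OU stationary density is Gaussian-shaped around its mode
  env <- simulate_ou(1, 1, 1e-3, 2000, seed = 3)
  p2 <- envelope_pdf(env, n_bins = 60)
  sh <- attr(env, "shift")
  gauss <- dnorm(p2$mid, mean = sh, sd = 1 / sqrt(2))
  i_mode <- which.max(gauss)
  expect_lt(abs(p2$density[i_mode] - gauss[i_mode]) / gauss[i_mode], 0.05)
})

test_that("Welch PSD integrates to the variance and finds tones", {
  set.seed(9)
  wn <- bd_timeseries(rnorm(1e5), 1e-3)
  sp <- psd(wn)
  expect_lt(abs(sum(sp$power) * diff(sp$freq[1:2]) - var(as.numeric(wn))), 0.05)
  expect_true(all(sp$power >= 0))
  t <- seq(0, 10, by = 1e-3)
  tone <- bd_timeseries(sin(2 * pi * 20 * t), 1e-3)
  sp2 <- psd(tone)
  expect_equal(sp2$freq[which.max(sp2$power)], 20, tolerance = 1)
})

test_that("segmentation produces independent equal-length parts", {
  ts <- bd_timeseries(rnorm(10000), 1e-3)
  segs <- segment_features(ts, n_segments = 5, fun = function(s, ...) length(s))
  expect_equal(unlist(segs), rep(2000, 5))
  ts2 <- bd_timeseries(rnorm(10003), 1e-3)
  segs2 <- segment_features(ts2, 5, fun = function(s, ...) length(s))
  expect_equal(sum(unlist(segs2)), 5 * floor(10003 / 5))
  # stationary envelope: segment-mean of profile means tracks the whole series
  env <- simulate_ou(1, 1, 1e-3, 500, seed = 10)
  whole <- burst_profiles(env, min_duration = 0)
  parts <- segment_features(env, 5, min_duration = 0)
  m <- rowMeans(sapply(parts, function(p) p$mean_duration_s))
  sems <- apply(sapply(parts, function(p) p$mean_duration_s), 1, sd) / sqrt(5)
  expect_true(mean(abs(m - whole$mean_duration_s) <= 3 * sems) > 0.8)
})
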