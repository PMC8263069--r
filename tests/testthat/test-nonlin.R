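mk_profile <- function(dur, pct = seq(0.2, 0.2 + 0.05 * (length(dur) - 1), by = 0.05)) {
  structure(data.frame(percentile = pct, threshold = pct,
                       mean_duration_s = dur),
            class = c("bd_profile", "data.frame"))
}

test_that("BDDLS matches hand calculation and is scale invariant", {
  d <- mk_profile(c(0.3, 0.2, 0.1))
  s <- mk_profile(c(0.2, 0.2, 0.2))
  expect_equal(bddls(d, d), 0)
  expect_equal(bddls(d, s), 0.5)  # ssd 0.02 over mean^2 0.04
  k <- 3.7
  dk <- mk_profile(k * d$mean_duration_s); sk <- mk_profile(k * s$mean_duration_s)
  expect_equal(bddls(dk, sk), bddls(d, s))
  expect_error(bddls(d, mk_profile(c(0.2, 0.2, 0.2), pct = c(0.1, 0.2, 0.3))),
               "grid")
})

test_that("ON/OFF contrasts have the documented algebra", {
  on <- mk_profile(c(0.1, 0.1, 0.1)); off <- mk_profile(c(0.3, 0.2, 0.1))
  s_on <- mk_profile(c(0.1, 0.1, 0.1)); s_off <- mk_profile(c(0.2, 0.2, 0.2))
  psd0 <- structure(data.frame(freq = 1:10, power = rep(1, 10)),
                    class = c("bd_psd", "data.frame"))
  psd2 <- psd0; psd2$power <- 2 * psd0$power
  same <- nonlin_contrasts(on, on, s_on, s_on, psd0, psd0)
  expect_equal(same$bddls_diff, 0)
  expect_equal(same$dur_diff, 0)
  expect_equal(same$psd_diff, 0)
  r <- nonlin_contrasts(on, off, s_on, s_off, psd0, psd2)
  expect_equal(r$dur_diff, 0.3)
  expect_equal(r$psd_diff, 1)  # doubling OFF power = +100% of the ON integral
  expect_equal(r$bddls_diff, bddls(off, s_off) - bddls(on, s_on))
})

test_that("adaptive FDR matches a step-by-step oracle and its edge cases", {
  expect_equal(adaptive_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_equal(adaptive_fdr(rep(0, 6)), rep(TRUE, 6))
  expect_equal(adaptive_fdr(numeric(0)), logical(0))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.3, 0.9)
  expect_equal(adaptive_fdr(p, 0.05), brute_force_two_stage_fdr(p, 0.05))
  set.seed(11)
  for (i in 1:50) {
    pr <- runif(sample(3:30, 1))
    expect_equal(adaptive_fdr(pr, 0.05), brute_force_two_stage_fdr(pr, 0.05))
  }
})

test_that("adaptive FDR controls the realized false discovery proportion", {
  set.seed(13)
  fdp <- replicate(400, {
    m <- 40
    null <- runif(m / 2)
    alt <- pmin(rexp(m / 2, rate = 40), 1)
    rej <- adaptive_fdr(c(null, alt), 0.05)
    if (!any(rej)) 0 else sum(rej[seq_len(m / 2)]) / sum(rej)
  })
  expect_lte(mean(fdp), 0.06)
})

test_that("cluster permutation test is calibrated and detects shifts", {
  set.seed(21)
  g <- matrix(rnorm(5 * 20), 5, 20)
  same <- cluster_permutation_test(g, g, n_perm = 100)
  expect_equal(same$p_min, 1)
  # with n = 5 pairs the exhaustive sign-flip null is +/- symmetric, so the
  # smallest attainable p is 2/32 > 0.05; calibration and power are checked
  # at n = 10 pairs where the 5% level is attainable
  rate <- mean(replicate(200, {
    a <- matrix(rnorm(10 * 15), 10, 15); b <- matrix(rnorm(10 * 15), 10, 15)
    cluster_permutation_test(a, b, n_perm = 1e3)$p_min <= 0.05
  }))
  expect_lt(rate, 0.12)
  expect_gt(rate, 0.005)
  # power: group b shifted by 1 SD
  hits <- mean(replicate(100, {
    a <- matrix(rnorm(10 * 15), 10, 15); b <- matrix(rnorm(10 * 15, -1), 10, 15)
    cluster_permutation_test(a, b, n_perm = 1e3)$p_min <= 0.05
  }))
  expect_gte(hits, 0.9)
})

test_that("per-threshold profile tests reject only genuine differences", {
  set.seed(31)
  mk_segs <- function(shift_at = NULL) {
    lapply(1:5, function(i) {
      base <- c(0.30, 0.25, 0.20, 0.15) + rnorm(4, sd = 0.01)
      if (!is.null(shift_at)) base[shift_at] <- base[shift_at] + 0.5
      mk_profile(base, pct = c(0.2, 0.25, 0.3, 0.35))
    })
  }
  on <- mk_segs(); off <- mk_segs()
  expect_false(any(paired_profile_tests(on, off)$rejected))
  off2 <- mk_segs(shift_at = 2)
  expect_true(paired_profile_tests(on, off2)$rejected[2])
  # p-value agrees with the textbook pooled two-sample t
  x <- c(0.1, 0.2, 0.3, 0.25, 0.15); y <- c(0.4, 0.5, 0.45, 0.35, 0.55)
  segs_x <- lapply(x, function(v) mk_profile(v, pct = 0.2))
  segs_y <- lapply(y, function(v) mk_profile(v, pct = 0.2))
  got <- paired_profile_tests(segs_x, segs_y)
  sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(2 / 5))
  expect_equal(got$t, t_hand)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df = 8))
})

test_that("rank tests reproduce exact small-sample results", {
  expect_equal(rank_tests(1:8, (1:8)^2, "spearman")$estimate, 1)
  set.seed(5)
  x <- rnorm(16); y <- x - abs(rnorm(16)) - 0.1  # x - y all positive
  expect_equal(rank_tests(x, y, "wilcoxon_one_tailed")$p_value, 1 / 2^16)
  expect_equal(rank_tests(c(1, 2, 3, 4), c(1, 2, 4, 3), "spearman")$estimate, 0.8)
  expect_equal(rank_tests(rep(1, 5), rep(1, 5), "wilcoxon_one_tailed")$p_value, 1)
})

test_that("binomial upper-tail test reproduces the reference computation", {
  expect_lt(abs(binomial_tail_test(10, 16, 0.3438)$p_value - 0.020), 5e-4)
  expect_equal(binomial_tail_test(0, 16, 0.3438)$p_value, 1)
  expect_equal(binomial_tail_test(2, 2, 0.5)$p_value, 0.25)
})

test_that("Barnard test matches brute-force enumeration and degenerate cases", {
  expect_gt(barnard_test(matrix(c(3, 5, 3, 5), 2))$p_value, 0.999)
  got <- barnard_test(matrix(c(2, 0, 0, 2), 2))$p_value
  want <- brute_force_barnard(2, 0, 2, 2)
  expect_equal(got, want, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:3) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2)
    expect_equal(barnard_test(tab)$p_value,
                 brute_force_barnard(k1, k2, n1, n2), tolerance = 2e-3)
  }
})
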