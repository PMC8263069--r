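#' Burst duration distance to linear surrogates (BDDLS)
#'
#' Sum over thresholds of the squared differences between the data and
#' surrogate average burst duration profiles, divided by the square of the
#' mean value of the surrogate profile. Dimensionless and invariant to a
#' common amplitude rescaling of both profiles.
#'
#' @param data_profile,surrogate_profile `bd_profile` data frames on the same
#'   percentile grid with no missing mean durations.
#' @return Non-negative scalar.
#' @export
bddls <- function(data_profile, surrogate_profile) {
  d <- data_profile$mean_duration_s
  s <- surrogate_profile$mean_duration_s
  if (!isTRUE(all.equal(data_profile$percentile, surrogate_profile$percentile)))
    stop("profiles are not on the same percentile grid")
  if (anyNA(d) || anyNA(s))
    stop("profiles carry missing mean durations on the shared grid")
  sum((d - s)^2) / mean(s)^2
}

#' ON/OFF contrasts: BDDLSdiff, DURdiff and PSDdiff
#'
#' `bddls_diff = bddls_off - bddls_on`; `dur_diff` is the sum across
#' thresholds of (OFF minus ON) mean burst durations; `psd_diff` is the
#' relative difference of band-integrated power, `(P_off - P_on) / P_on`
#' (alternative `psd_mode = "per_freq"` sums per-frequency relative
#' differences instead).
#'
#' @param profile_on,profile_off data burst duration profiles (matched grids).
#' @param surr_on,surr_off matching surrogate mean profiles.
#' @param psd_on,psd_off `bd_psd` data frames (optional).
#' @param band c(lo, hi) Hz integration band for PSDdiff (defaults to the full
#'   overlap of the two PSDs).
#' @param psd_mode `"integrated"` (default) or `"per_freq"`.
#' @param rho the GWR level the surrogates were computed at (metadata).
#' @return list of class `bd_nonlin_report` with fields `bddls_on`,
#'   `bddls_off`, `bddls_diff`, `dur_diff`, `psd_diff`, `rho`.
#' @export
nonlin_contrasts <- function(profile_on, profile_off, surr_on, surr_off,
                             psd_on = NULL, psd_off = NULL, band = NULL,
                             psd_mode = c("integrated", "per_freq"), rho = NA) {
  psd_mode <- match.arg(psd_mode)
  if (!isTRUE(all.equal(profile_on$percentile, profile_off$percentile)))
    stop("ON and OFF profiles are not on the same percentile grid")
  b_on <- bddls(profile_on, surr_on)
  b_off <- bddls(profile_off, surr_off)
  dur_diff <- sum(profile_off$mean_duration_s - profile_on$mean_duration_s)
  psd_diff <- NA_real_
  if (!is.null(psd_on) && !is.null(psd_off)) {
    if (is.null(band)) band <- range(psd_on$freq)
    sel_on <- psd_on$freq >= band[1] & psd_on$freq <= band[2]
    sel_off <- psd_off$freq >= band[1] & psd_off$freq <= band[2]
    if (psd_mode == "integrated") {
      df_on <- mean(diff(psd_on$freq)); df_off <- mean(diff(psd_off$freq))
      p_on <- sum(psd_on$power[sel_on]) * df_on
      p_off <- sum(psd_off$power[sel_off]) * df_off
      psd_diff <- (p_off - p_on) / p_on
    } else {
      if (sum(sel_on) != sum(sel_off))
        stop("per-frequency PSDdiff needs matching frequency grids")
      psd_diff <- sum((psd_off$power[sel_off] - psd_on$power[sel_on]) /
                        psd_on$power[sel_on])
    }
  }
  structure(list(bddls_on = b_on, bddls_off = b_off,
                 bddls_diff = b_off - b_on, dur_diff = dur_diff,
                 psd_diff = psd_diff, rho = rho),
            class = "bd_nonlin_report")
}

#' @export
print.bd_nonlin_report <- function(x, ...) {
  cat(sprintf(
    "<bd_nonlin_report> rho=%s\n  BDDLS ON %.4g | OFF %.4g | diff %.4g\n  DURdiff %.4g s | PSDdiff %.4g\n",
    format(x$rho), x$bddls_on, x$bddls_off, x$bddls_diff, x$dur_diff, x$psd_diff))
  invisible(x)
}

#' One-sided rank test of a data statistic against a surrogate ensemble
#'
#' Classic surrogate significance test: with `n` surrogates, the data
#' statistic is ranked among the `n + 1` values and the one-sided p-value is
#' `(1 + #\{surrogate >= data\}) / (n + 1)`. With 19 surrogates the smallest
#' attainable p is exactly 0.05. Here the statistic is BDDLS: the data profile
#' is compared against the ensemble mean profile, and each surrogate against
#' the mean of the other realizations (leave-one-out null).
#'
#' @param ts filtered [bd_timeseries()].
#' @param n ensemble size (default 19).
#' @param rho GWR level (default 0 = IAAFT).
#' @param percentiles,min_duration,smooth_span profile settings.
#' @param seed master seed.
#' @param ... passed to [surrogate_ensemble()].
#' @return list: `statistic` (data BDDLS), `null` (surrogate BDDLS values),
#'   `p_value`.
#' @export
bddls_rank_test <- function(ts, n = 19, rho = 0,
                            percentiles = default_percentiles(),
                            min_duration = 0.1, smooth_span = 0.005,
                            seed = NULL, ...) {
  ens <- surrogate_ensemble(ts, n = n, method = if (rho > 0) "gwr" else "iaaft",
                            rho = rho, seed = seed, ...)
  profs <- lapply(ens, function(s)
    burst_profiles(hilbert_envelope(s, smooth_span), percentiles, min_duration))
  dmat <- sapply(profs, function(p) p$mean_duration_s)
  dprof <- burst_profiles(hilbert_envelope(ts, smooth_span), percentiles,
                          min_duration)
  mk <- function(v) {
    out <- profs[[1]]
    out$mean_duration_s <- v
    out
  }
  stat <- bddls(dprof, mk(rowMeans(dmat)))
  null <- vapply(seq_len(n), function(i)
    bddls(mk(dmat[, i]), mk(rowMeans(dmat[, -i, drop = FALSE]))), numeric(1))
  p <- (1 + sum(null >= stat)) / (n + 1)
  list(statistic = stat, null = null, p_value = p)
}

#' Adaptive linear step-up FDR control
#'
#' Two-stage adaptive procedure (default): a first linear step-up pass at
#' level q/(1+q) estimates the number of true nulls as m minus the number of
#' first-stage rejections, and a second pass runs the linear step-up at level
#' q/(1+q) * m/m0_hat. `estimator = "lowest_slope"` instead estimates m0 by
#' the lowest-slope rule before a single step-up pass.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @param q FDR level (default 0.05).
#' @param estimator `"two_stage"` (default) or `"lowest_slope"`.
#' @return Logical rejection mask (empty input gives an empty mask).
#' @export
adaptive_fdr <- function(p, q = 0.05, estimator = c("two_stage", "lowest_slope")) {
  estimator <- match.arg(estimator)
  m <- length(p)
  if (m == 0) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  step_up <- function(p, level) {
    o <- order(p)
    crit <- level * seq_len(m) / m
    k <- which(p[o] <= crit)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  if (estimator == "two_stage") {
    q1 <- q / (1 + q)
    r1 <- sum(step_up(p, q1))
    if (r1 == 0) return(logical(m))
    if (r1 == m) return(rep(TRUE, m))
    m0 <- m - r1
    step_up(p, q1 * m / m0)
  } else {
    ps <- sort(p)
    # lowest slope: first i where the slope estimate of m0 starts increasing
    s <- (1 - ps) / (m + 1 - seq_len(m))
    i <- which(diff(s) > 0)[1]
    m0 <- if (is.na(i)) 1 else min(ceiling(1 / s[i + 1]) + 1, m)
    step_up(p, q * m / m0)
  }
}

#' Cluster-based permutation test on paired binned curves
#'
#' Bin-wise paired t statistics are thresholded at the two-sided critical
#' value (`cluster_alpha`); contiguous supra-critical bins of the same sign
#' form clusters scored by their summed t. The null distribution of the
#' maximum absolute cluster mass is built by randomly sign-flipping the paired
#' differences (exhaustive when feasible).
#'
#' @param group_a,group_b matrices (subjects x bins) of paired curves, e.g.
#'   stacked envelope PDF densities.
#' @param n_perm number of permutations (default 1e4; exhaustive enumeration
#'   is used when `2^n <= n_perm`).
#' @param cluster_alpha cluster-forming two-sided alpha (default 0.05).
#' @param seed integer seed for the Monte-Carlo branch.
#' @return list: `clusters` data frame (`start`, `end`, `mass`, `p_value`)
#'   and `p_min`. Permutation p-values are never below 1/(n_perm + 1).
#' @export
cluster_permutation_test <- function(group_a, group_b, n_perm = 1e4,
                                     cluster_alpha = 0.05, seed = NULL) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (!all(dim(group_a) == dim(group_b))) stop("groups must share bin grids")
  d <- group_a - group_b
  n <- nrow(d)
  tcrit <- qt(1 - cluster_alpha / 2, df = n - 1)
  tstat <- function(dd) {
    mu <- colMeans(dd)
    se <- apply(dd, 2, stats::sd) / sqrt(n)
    ifelse(se > 0, mu / se, 0)
  }
  find_clusters <- function(t) {
    lab <- sign(t) * (abs(t) > tcrit)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    keep <- r$values != 0
    data.frame(start = (ends - r$lengths + 1)[keep], end = ends[keep],
               mass = vapply(which(keep), function(i)
                 sum(t[(ends[i] - r$lengths[i] + 1):ends[i]]), numeric(1)))
  }
  obs <- find_clusters(tstat(d))
  exhaustive <- 2^n <= n_perm
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else NULL
  null_max <- with_seed(seed, {
    nn <- if (exhaustive) nrow(signs) else n_perm
    vapply(seq_len(nn), function(k) {
      s <- if (exhaustive) signs[k, ] else sample(c(-1, 1), n, replace = TRUE)
      cl <- find_clusters(tstat(d * s))
      if (nrow(cl)) max(abs(cl$mass)) else 0
    }, numeric(1))
  })
  denom <- length(null_max) + !exhaustive
  obs$p_value <- if (nrow(obs)) vapply(obs$mass, function(m)
    (sum(null_max >= abs(m)) + !exhaustive) / denom, numeric(1)) else numeric(0)
  list(clusters = obs, p_min = if (nrow(obs)) min(obs$p_value) else 1)
}

#' Per-threshold paired t-tests between segment profiles, with adaptive FDR
#'
#' Two-sample pooled-variance t-test per threshold between the per-segment
#' mean burst durations of the two conditions (five segments per condition
#' give df = 8), followed by adaptive FDR control across thresholds.
#' Thresholds where both groups have zero variance return p = 1.
#'
#' @param on_segments,off_segments lists of segment `bd_profile`s (from
#'   [segment_features()]).
#' @param q FDR level.
#' @param column profile column tested (default `"mean_duration_s"`).
#' @return data frame: `percentile`, `t`, `p_value`, `rejected`.
#' @export
paired_profile_tests <- function(on_segments, off_segments, q = 0.05,
                                 column = "mean_duration_s") {
  a <- sapply(on_segments, function(p) p[[column]])
  b <- sapply(off_segments, function(p) p[[column]])
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  pct <- on_segments[[1]]$percentile
  res <- t(vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(c(NA_real_, NA_real_))
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(c(0, 1))
    tt <- t.test(x, y, var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }, numeric(2)))
  p <- res[, 2]
  rej <- rep(FALSE, length(p))
  ok <- is.finite(p)
  rej[ok] <- adaptive_fdr(p[ok], q)
  data.frame(percentile = pct, t = res[, 1], p_value = p, rejected = rej)
}

#' Rank-based tests (one-tailed Wilcoxon signed rank; Spearman correlation)
#'
#' Thin wrappers over the exact small-sample implementations in stats. The
#' one-tailed direction is "first argument greater". All-zero paired
#' differences return p = 1.
#'
#' @param x,y numeric vectors (paired for the Wilcoxon test).
#' @param kind `"wilcoxon_one_tailed"` or `"spearman"`.
#' @return list of class `bd_stat`: `statistic`, `p_value`, `n`, `method`,
#'   `sidedness`, and `estimate` (Spearman rho) where applicable.
#' @export
rank_tests <- function(x, y, kind = c("wilcoxon_one_tailed", "spearman")) {
  kind <- match.arg(kind)
  if (kind == "wilcoxon_one_tailed") {
    if (length(x) != length(y)) stop("paired samples required")
    if (all(x - y == 0))
      return(structure(list(statistic = 0, p_value = 1, n = length(x),
                            method = "wilcoxon signed rank",
                            sidedness = "greater"), class = "bd_stat"))
    wt <- wilcox.test(x, y, paired = TRUE, alternative = "greater",
                      exact = TRUE)
    structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                   n = length(x), method = "wilcoxon signed rank",
                   sidedness = "greater"), class = "bd_stat")
  } else {
    if (length(x) < 3) stop("n >= 3 required")
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    structure(list(statistic = unname(ct$statistic), p_value = ct$p.value,
                   estimate = unname(ct$estimate), n = length(x),
                   method = "spearman", sidedness = "two-sided"),
              class = "bd_stat")
  }
}

#' @export
print.bd_stat <- function(x, ...) {
  cat(sprintf("<bd_stat> %s (%s), n=%d: statistic=%.4g, p=%.4g\n",
              x$method, x$sidedness, x$n, x$statistic, x$p_value))
  invisible(x)
}

#' One-sided upper-tail binomial test
#'
#' P(X >= k) for X ~ Binomial(n, p0).
#'
#' @param k observed successes.
#' @param n number of trials.
#' @param p0 null success probability.
#' @return list of class `bd_stat`.
#' @export
binomial_tail_test <- function(k, n, p0) {
  if (k < 0 || k > n || p0 < 0 || p0 > 1) stop("invalid binomial parameters")
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  structure(list(statistic = k, p_value = p, n = n, method = "binomial upper tail",
                 sidedness = "greater"), class = "bd_stat")
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' Column totals are fixed (two independent binomials); the Wald (pooled)
#' statistic is computed for every outcome table and the p-value is the
#' maximum over a fine grid of the nuisance success probability of the
#' probability of outcomes at least as extreme as observed.
#'
#' @param table 2x2 matrix of non-negative integer counts; columns are the
#'   two groups, row 1 the "success" count.
#' @param alternative `"greater"` (default: success proportion larger in
#'   column 1) or `"two_sided"`.
#' @param n_grid nuisance-parameter grid size (default 1001).
#' @return list of class `bd_stat`.
#' @export
barnard_test <- function(table, alternative = c("greater", "two_sided"),
                         n_grid = 1001) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop("need a 2x2 table of non-negative integer counts")
  n1 <- sum(table[, 1]); n2 <- sum(table[, 2])
  if (n1 == 0 || n2 == 0) stop("zero-total column")
  wald <- function(k1, k2) {
    p1 <- k1 / n1; p2 <- k2 / n2
    pp <- (k1 + k2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    ifelse(se == 0, 0, (p1 - p2) / se)
  }
  k1 <- rep(0:n1, times = n2 + 1)
  k2 <- rep(0:n2, each = n1 + 1)
  tall <- wald(k1, k2)
  tobs <- wald(table[1, 1], table[1, 2])
  extreme <- if (alternative == "greater") tall >= tobs - 1e-12 else
    abs(tall) >= abs(tobs) - 1e-12
  pi_grid <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  lchoose1 <- lchoose(n1, 0:n1); lchoose2 <- lchoose(n2, 0:n2)
  pmax_val <- 0
  for (pi in pi_grid) {
    lp <- lchoose1[k1 + 1] + k1 * log(pi) + (n1 - k1) * log1p(-pi) +
      lchoose2[k2 + 1] + k2 * log(pi) + (n2 - k2) * log1p(-pi)
    val <- sum(exp(lp[extreme]))
    if (val > pmax_val) pmax_val <- val
  }
  structure(list(statistic = tobs, p_value = min(pmax_val, 1),
                 n = n1 + n2, method = "barnard exact (Wald)",
                 sidedness = alternative), class = "bd_stat")
}
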