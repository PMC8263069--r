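#' Fourier-transform (phase-randomized) surrogate
#'
#' Keeps the Fourier amplitude spectrum of the data bit-exactly (up to inverse
#' transform rounding) and randomizes the phases with conjugate symmetry; DC
#' and Nyquist components are untouched.
#'
#' @param ts a [bd_timeseries()].
#' @param seed integer seed (optional).
#' @return A surrogate [bd_timeseries()] of the same length and `dt`.
#' @export
ft_surrogate <- function(ts, seed = NULL) {
  x <- as.numeric(ts)
  n <- length(x)
  if (n < 4) stop("need at least 4 samples")
  with_seed(seed, {
    X <- fft(x)
    half <- if (n %% 2 == 0) (n / 2 - 1) else ((n - 1) / 2)
    idx <- 2:(1 + half)
    ph <- runif(half, 0, 2 * pi)
    X[idx] <- Mod(X[idx]) * exp(1i * ph)
    X[n + 2 - idx] <- Conj(X[idx])
    bd_timeseries(Re(fft(X, inverse = TRUE)) / n, ts_dt(ts))
  })
}

# One IAAFT loop on a plain vector: alternate spectral-amplitude adjustment
# and rank-matching to the original values; ends on the rank step so the value
# multiset is exact. `fixed` positions (if any) are restored after each step.
iaaft_core <- function(x, max_iter, tol, fixed = NULL) {
  n <- length(x)
  amp <- Mod(fft(x))
  xs <- sort(x)
  y <- x[sample.int(n)]
  if (!is.null(fixed)) y[fixed] <- x[fixed]
  prev_mismatch <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    Y <- fft(y)
    m <- Mod(Y)
    y2 <- Re(fft(amp * Y / ifelse(m == 0, 1, m), inverse = TRUE)) / n
    y <- xs[rank(y2, ties.method = "first")]
    if (!is.null(fixed)) y[fixed] <- x[fixed]
    mismatch <- sqrt(sum((Mod(fft(y)) - amp)^2)) / sqrt(sum(amp^2))
    if (it >= max_iter || abs(prev_mismatch - mismatch) < tol) break
    prev_mismatch <- mismatch
  }
  attr(y, "iterations") <- it
  attr(y, "spectral_mismatch") <- mismatch
  y
}

#' Iterated amplitude-adjusted Fourier transform (IAAFT) surrogate
#'
#' The surrogate has exactly the same value multiset as the data and
#' approximately the same power spectrum (iterative amplitude/rank
#' adjustment). Non-convergence is not an error; the iteration count and final
#' relative spectral mismatch are attached as attributes.
#'
#' @param ts a [bd_timeseries()].
#' @param seed integer seed (optional).
#' @param max_iter maximum number of iterations (default 100).
#' @param tol stop when the relative spectral mismatch changes by less than
#'   this between iterations (default 1e-6).
#' @return A surrogate [bd_timeseries()] with attributes `iterations` and
#'   `spectral_mismatch`.
#' @export
iaaft_surrogate <- function(ts, seed = NULL, max_iter = 100, tol = 1e-6) {
  x <- as.numeric(ts)
  if (length(x) < 4) stop("need at least 4 samples")
  if (max(x) == min(x)) return(bd_timeseries(x, ts_dt(ts)))
  y <- with_seed(seed, iaaft_core(x, max_iter, tol))
  out <- bd_timeseries(as.numeric(y), ts_dt(ts))
  attr(out, "iterations") <- attr(y, "iterations")
  attr(out, "spectral_mismatch") <- attr(y, "spectral_mismatch")
  out
}

# ---- MODWT ------------------------------------------------------------------

# LA(8): least-asymmetric Daubechies scaling filter, 8 taps (standard
# published constants).
la8_scaling <- c(
  -7.576571478927333e-02, -2.963552764599851e-02, 4.976186676320155e-01,
   8.037387518059161e-01,  2.978577956052774e-01, -9.921954357684722e-02,
  -1.260396726203783e-02,  3.222310060404270e-02)

modwt_filters <- function(wavelet = "la8") {
  g <- switch(wavelet,
              la8 = la8_scaling,
              haar = c(1, 1) / sqrt(2),
              stop("unknown wavelet: ", wavelet))
  Lf <- length(g)
  h <- rev(g) * (-1)^(seq_len(Lf) - 1)  # QMF
  list(g = g / sqrt(2), h = h / sqrt(2))  # MODWT rescaling
}

# circular filtering with the level-j upsampled filter (shift step 2^(j-1))
modwt_conv <- function(v, f, step) {
  n <- length(v)
  out <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    shift <- (l - 1) * step
    out <- out + f[l] * v[((idx - 1 - shift) %% n) + 1]
  }
  out
}

imodwt_conv <- function(v, f, step) {
  n <- length(v)
  out <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    shift <- (l - 1) * step
    out <- out + f[l] * v[((idx - 1 + shift) %% n) + 1]
  }
  out
}

#' Maximal overlap discrete wavelet transform (pyramid algorithm)
#'
#' @param x numeric vector (any length; circular boundary).
#' @param n_levels decomposition depth.
#' @param wavelet `"la8"` (default) or `"haar"`.
#' @return list with `W` (n x n_levels matrix of wavelet coefficients) and `V`
#'   (final-level scaling coefficients).
#' @export
modwt <- function(x, n_levels, wavelet = "la8") {
  f <- modwt_filters(wavelet)
  n <- length(x)
  if (n < 2^n_levels) stop("series too short for ", n_levels, " levels")
  W <- matrix(0, n, n_levels)
  v <- x
  for (j in seq_len(n_levels)) {
    step <- 2^(j - 1)
    W[, j] <- modwt_conv(v, f$h, step)
    v <- modwt_conv(v, f$g, step)
  }
  list(W = W, V = v, wavelet = wavelet)
}

#' Inverse maximal overlap discrete wavelet transform
#' @param w a decomposition from [modwt()].
#' @return The reconstructed numeric vector.
#' @export
imodwt <- function(w) {
  f <- modwt_filters(w$wavelet)
  J <- ncol(w$W)
  v <- w$V
  for (j in rev(seq_len(J))) {
    step <- 2^(j - 1)
    v <- imodwt_conv(w$W[, j], f$h, step) + imodwt_conv(v, f$g, step)
  }
  v
}

#' GWR surrogate configuration
#'
#' @param rho fixed-energy fraction in \[0, 1\]: the largest squared wavelet
#'   coefficients summing (across all scales and positions) to at least
#'   `rho` of the total wavelet energy are pinned; the rest are randomized.
#' @param wavelet MODWT wavelet (default `"la8"`).
#' @param n_levels decomposition depth; default `floor(log2(N)) - 2`.
#' @param max_iaaft_iter,tol IAAFT controls for the randomization passes.
#' @export
gwr_config <- function(rho, wavelet = "la8", n_levels = NULL,
                       max_iaaft_iter = 100, tol = 1e-6) {
  stopifnot_scalar(rho, "rho")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(list(rho = rho, wavelet = wavelet, n_levels = n_levels,
                 max_iaaft_iter = max_iaaft_iter, tol = tol),
            class = "gwr_config")
}

#' Gradual wavelet reconstruction (GWR) surrogate
#'
#' MODWT-based IAAFT surrogate: wavelet coefficients are ranked by squared
#' magnitude irrespective of scale and position, and the largest ones covering
#' an energy fraction of at least `rho` are fixed. The remaining coefficients
#' of each scale are IAAFT-randomized within the scale; after inverse
#' transform, a final IAAFT pass on the dataset as a whole restores the exact
#' data value multiset. The final-level scaling coefficients (the slow trend)
#' are always kept. `rho = 0` reduces to [iaaft_surrogate()]; `rho = 1`
#' returns the data unchanged.
#'
#' @param ts a [bd_timeseries()].
#' @param config a [gwr_config()] (or a bare `rho` value).
#' @param seed integer seed (optional).
#' @return A surrogate [bd_timeseries()] with attribute
#'   `fixed_energy_fraction`.
#' @export
gwr_surrogate <- function(ts, config, seed = NULL) {
  if (is.numeric(config)) config <- gwr_config(config)
  x <- as.numeric(ts)
  n <- length(x)
  rho <- config$rho
  if (rho >= 1) {
    out <- bd_timeseries(x, ts_dt(ts))
    attr(out, "fixed_energy_fraction") <- 1
    return(out)
  }
  if (rho == 0) {
    out <- iaaft_surrogate(ts, seed, config$max_iaaft_iter, config$tol)
    attr(out, "fixed_energy_fraction") <- 0
    return(out)
  }
  J <- if (is.null(config$n_levels)) max(1L, floor(log2(n)) - 2L) else config$n_levels
  with_seed(seed, {
    dec <- modwt(x, J, config$wavelet)
    W <- dec$W
    e <- as.numeric(W)^2
    ord <- order(e, decreasing = TRUE)
    cume <- cumsum(e[ord])
    k <- which(cume >= rho * sum(e))[1]
    fixed <- logical(length(e))
    fixed[ord[seq_len(k)]] <- TRUE
    fixed <- matrix(fixed, n, J)
    for (j in seq_len(J)) {
      if (all(fixed[, j])) next
      W[, j] <- iaaft_core(dec$W[, j], config$max_iaaft_iter, config$tol,
                           fixed = which(fixed[, j]))
    }
    rec <- imodwt(list(W = W, V = dec$V, wavelet = dec$wavelet))
    # dataset-as-a-whole IAAFT pass, rank-matched to the original values
    amp <- Mod(fft(x))
    xs <- sort(x)
    y <- rec
    for (it in 1:10) {
      Y <- fft(y)
      m <- Mod(Y)
      y2 <- Re(fft(amp * Y / ifelse(m == 0, 1, m), inverse = TRUE)) / n
      y <- xs[rank(y2, ties.method = "first")]
    }
    out <- bd_timeseries(y, ts_dt(ts))
    attr(out, "fixed_energy_fraction") <- cume[k] / sum(e)
    out
  })
}

#' Surrogate ensemble
#'
#' Generates `n` surrogate realizations with seeds derived from a master seed
#' by a fixed counter scheme.
#'
#' @param ts a [bd_timeseries()] (already filtered; surrogates reproduce its
#'   spectrum and are not re-filtered).
#' @param n ensemble size (default 19, so that a one-sided rank test against
#'   the ensemble has exact level 1/20).
#' @param method `"gwr"`, `"iaaft"` or `"ft"`.
#' @param rho GWR energy fraction (ignored for other methods).
#' @param seed master seed.
#' @param ... further arguments for the surrogate generator.
#' @return list of surrogate [bd_timeseries()] with attribute `seeds`.
#' @export
surrogate_ensemble <- function(ts, n = 19, method = c("gwr", "iaaft", "ft"),
                               rho = 0, seed = NULL, ...) {
  method <- match.arg(method)
  if (is.null(seed)) seed <- 1L
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), numeric(1))
  gen <- switch(method,
                ft = function(s) ft_surrogate(ts, s),
                iaaft = function(s) iaaft_surrogate(ts, s, ...),
                gwr = function(s) gwr_surrogate(ts, gwr_config(rho, ...), s))
  out <- lapply(seeds, gen)
  attr(out, "seeds") <- seeds
  attr(out, "method") <- method
  attr(out, "rho") <- rho
  out
}

#' Across-realization mean burst duration profile of a surrogate ensemble
#'
#' Generates `n` surrogates of an already-filtered signal, computes each one's
#' envelope and burst duration profile (no re-filtering, no segmentation), and
#' returns the across-realization mean profile with SEM (sample SD across
#' realizations / sqrt(n)).
#'
#' @inheritParams surrogate_ensemble
#' @param percentiles percentile grid (default 0.20..0.95 step 0.05).
#' @param min_duration minimum burst duration in seconds.
#' @param smooth_span envelope smoothing span (s), as for the data envelope.
#' @return A `bd_profile` data frame (SEM columns are across realizations).
#' @export
surrogate_profile <- function(ts, n = 19, rho = 0,
                              percentiles = default_percentiles(),
                              min_duration = 0.1, seed = NULL,
                              method = "gwr", smooth_span = 0.005, ...) {
  ens <- surrogate_ensemble(ts, n = n, method = method, rho = rho,
                            seed = seed, ...)
  profs <- lapply(ens, function(s)
    burst_profiles(hilbert_envelope(s, smooth_span), percentiles, min_duration))
  agg <- function(col) {
    m <- sapply(profs, function(p) p[[col]])
    list(mean = rowMeans(m, na.rm = TRUE),
         sem = apply(m, 1, function(r) {
           r <- r[is.finite(r)]
           if (length(r) < 2) NA_real_ else stats::sd(r) / sqrt(length(r))
         }))
  }
  dur <- agg("mean_duration_s"); amp <- agg("mean_amplitude")
  thr <- agg("threshold"); rate <- agg("rate_hz")
  out <- data.frame(percentile = percentiles, threshold = thr$mean,
                    mean_duration_s = dur$mean, sem_duration_s = dur$sem,
                    mean_amplitude = amp$mean, sem_amplitude = amp$sem,
                    rate_hz = rate$mean,
                    n_bursts = rowMeans(sapply(profs, function(p) p$n_bursts)))
  structure(out, dt = ts_dt(ts), min_duration = min_duration, n_realizations = n,
            class = c("bd_profile", "data.frame"))
}
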