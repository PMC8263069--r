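#' Band-pass filter a medication-state pair around the OFF-state spectral peak
#'
#' Finds the spectral peak of the OFF-state series inside the search band,
#' band-pass filters both series `half_width` Hz around that peak with a
#' zero-phase (forward-backward) 4th-order Butterworth filter, and z-scores
#' each filtered series to mean 0, sd 1.
#'
#' @param ts_on,ts_off [bd_timeseries()] sharing the same `dt` (ON / OFF
#'   medication, or any matched pair of conditions).
#' @param band_lo,band_hi search band for the spectral peak, Hz.
#' @param half_width half-width of the pass band around the peak, Hz.
#' @return list with elements `on`, `off` (filtered, z-scored
#'   [bd_timeseries()]) and `peak_hz`.
#' @export
prepare_pair <- function(ts_on, ts_off, band_lo = 13, band_hi = 35,
                         half_width = 3) {
  dt <- ts_dt(ts_off)
  if (abs(ts_dt(ts_on) - dt) > 1e-12) stop("ON and OFF series must share dt")
  spec <- psd(ts_off)
  inside <- spec$freq > band_lo & spec$freq < band_hi
  if (!any(inside)) stop("no beta peak: search band contains no frequencies")
  peak_hz <- spec$freq[inside][which.max(spec$power[inside])]
  # a maximum at the first/last in-band bin means the spectrum is monotone
  # through the band (no peak strictly inside it)
  if (peak_hz %in% range(spec$freq[inside]))
    stop("no beta peak: spectral maximum not strictly inside the search band")
  filt <- band_filter(peak_hz - half_width, peak_hz + half_width, dt)
  zfilt <- function(x) {
    y <- signal::filtfilt(filt, as.numeric(x))
    bd_timeseries((y - mean(y)) / stats::sd(y), dt)
  }
  list(on = zfilt(ts_on), off = zfilt(ts_off), peak_hz = peak_hz)
}

# Zero-phase 4th-order Butterworth band-pass (2nd-order prototype -> 4th-order
# band-pass polynomial), as an Arma filter for signal::filtfilt.
band_filter <- function(lo, hi, dt) {
  nyq <- 1 / (2 * dt)
  if (lo <= 0 || hi >= nyq) stop("pass band must lie strictly inside (0, Nyquist)")
  signal::butter(2, c(lo, hi) / nyq, type = "pass")
}

#' Amplitude envelope via the analytic signal
#'
#' Modulus of the discrete analytic signal (Hilbert transform via FFT),
#' smoothed with a centered moving average of span `smooth_span` seconds
#' (edges reflected). `smooth_span = 0` disables smoothing.
#'
#' @param ts a [bd_timeseries()].
#' @param smooth_span smoothing span in seconds (default 0.005).
#' @return A [bd_envelope()] of the same length.
#' @export
hilbert_envelope <- function(ts, smooth_span = 0.005) {
  dt <- ts_dt(ts)
  x <- as.numeric(ts)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(fft(fft(x) * h, inverse = TRUE) / n)
  k <- round(smooth_span / dt)
  if (k > 1) {
    if (k %% 2 == 0) k <- k + 1  # centered window
    half <- (k - 1) / 2
    pad <- c(rev(env[seq_len(half) + 1]), env, rev(env[n - seq_len(half)]))
    env <- as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))[half + seq_len(n)]
  }
  bd_envelope(pmax(env, 0), dt)
}

#' Detect supra-threshold bursts
#'
#' Maximal runs of consecutive samples with `env > threshold` (strict), kept
#' if their duration `run_length * dt` is at least `min_duration`. Runs
#' touching either end of the recording are kept.
#'
#' @param env a [bd_envelope()].
#' @param threshold amplitude threshold.
#' @param min_duration minimum burst duration in seconds (default 0.1).
#' @return A `bd_burstset`: data frame with half-open 0-based sample intervals
#'   `start`, `end`, plus `duration` (s) and `amplitude` (peak envelope).
#' @export
detect_bursts <- function(env, threshold, min_duration = 0.1) {
  dt <- ts_dt(env)
  stopifnot_scalar(threshold, "threshold")
  r <- rle(as.numeric(env) > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths * dt >= min_duration
  starts <- starts[keep]; ends <- ends[keep]
  amp <- vapply(seq_along(starts),
                function(i) max(env[(starts[i] + 1):ends[i]]), numeric(1))
  out <- data.frame(start = starts, end = ends,
                    duration = (ends - starts) * dt,
                    amplitude = if (length(starts)) amp else numeric(0))
  structure(out, dt = dt, threshold = threshold, min_duration = min_duration,
            class = c("bd_burstset", "data.frame"))
}

# profile grid used throughout: 20th to 95th envelope percentile in 5% steps
default_percentiles <- function() seq(0.20, 0.95, by = 0.05)

#' Average burst duration/amplitude profile across percentile thresholds
#'
#' For each percentile rank, the threshold is the empirical percentile of the
#' envelope (linear interpolation between order statistics) and burst
#' statistics are computed over all bursts at that threshold. Percentiles with
#' no qualifying burst carry `NA`, never 0.
#'
#' @param env a [bd_envelope()].
#' @param percentiles percentile ranks in \[0, 1) (default 0.20 to 0.95 in
#'   steps of 0.05).
#' @param min_duration minimum burst duration in seconds (default 0.1; use 0
#'   when comparing with the analytic formulas, which model no minimum).
#' @return A `bd_profile` data frame with columns `percentile`, `threshold`,
#'   `mean_duration_s`, `sem_duration_s`, `mean_amplitude`, `sem_amplitude`,
#'   `rate_hz`, `n_bursts`.
#' @export
burst_profiles <- function(env, percentiles = default_percentiles(),
                           min_duration = 0.1) {
  dt <- ts_dt(env)
  x <- as.numeric(env)
  if (max(x) - min(x) <= 0) stop("degenerate envelope: constant values")
  if (is.unsorted(percentiles, strictly = TRUE))
    stop("percentiles must be strictly increasing")
  thr <- as.numeric(quantile(x, percentiles, names = FALSE))  # type 7
  min_samples <- if (min_duration <= 0) 1L else as.integer(ceiling(min_duration / dt - 1e-9))
  st <- burst_scan_cpp(x, thr, min_samples)
  nb <- st[, "n_bursts"]
  mean_dur <- ifelse(nb > 0, st[, "sum_dur"] / nb * dt, NA_real_)
  sd_dur <- ifelse(nb > 1,
                   sqrt(pmax(st[, "sum_dur2"] - st[, "sum_dur"]^2 / nb, 0) / (nb - 1)) * dt,
                   NA_real_)
  mean_amp <- ifelse(nb > 0, st[, "sum_amp"] / nb, NA_real_)
  sd_amp <- ifelse(nb > 1,
                   sqrt(pmax(st[, "sum_amp2"] - st[, "sum_amp"]^2 / nb, 0) / (nb - 1)),
                   NA_real_)
  out <- data.frame(
    percentile = percentiles, threshold = thr,
    mean_duration_s = mean_dur, sem_duration_s = sd_dur / sqrt(pmax(nb, 1)),
    mean_amplitude = mean_amp, sem_amplitude = sd_amp / sqrt(pmax(nb, 1)),
    rate_hz = nb / (length(x) * dt), n_bursts = nb)
  structure(out, dt = dt, min_duration = min_duration,
            n_samples = length(x), class = c("bd_profile", "data.frame"))
}

#' Burst rate across percentile thresholds
#'
#' Rate is the number of bursts divided by the recording duration. With
#' `min_duration = 0` this satisfies `rate * mean_duration = fraction of
#' samples above threshold` exactly per realization.
#'
#' @inheritParams burst_profiles
#' @return Numeric vector of rates (bursts/s), one per percentile.
#' @export
burst_rate_profile <- function(env, percentiles = default_percentiles(),
                               min_duration = 0) {
  burst_profiles(env, percentiles, min_duration)$rate_hz
}

#' Normalized histogram density of envelope amplitudes
#'
#' @param env a [bd_envelope()] (any numeric vector works).
#' @param n_bins number of equal-width bins (>= 2).
#' @param range optional c(lo, hi) bin range; defaults to the data range.
#' @return A `bd_pdf`: data frame with `bin_lo`, `bin_hi`, `mid`, `density`.
#' @export
envelope_pdf <- function(env, n_bins = 50, range = NULL) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  x <- as.numeric(env)
  if (is.null(range)) range <- c(min(x), max(x))
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  w <- diff(edges)
  dens <- counts / sum(counts) / w
  structure(data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                       mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                       density = dens),
            class = c("bd_pdf", "data.frame"))
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed segments (default 1 s, 50%
#' overlap), one-sided, scaled so that the integral over frequency matches the
#' signal variance. Segment means are removed before windowing.
#'
#' @param ts a [bd_timeseries()].
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return A `bd_psd`: data frame with `freq` (Hz) and `power` (units^2/Hz).
#' @export
psd <- function(ts, window_s = 1, overlap = 0.5) {
  dt <- ts_dt(ts)
  x <- as.numeric(ts)
  nseg <- max(2L, min(round(window_s / dt), length(x)))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / nseg)  # Hann
  norm <- sum(w^2) / dt  # density scaling: dt / sum(w^2) per two-sided bin
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / norm
    acc <- acc + P[seq_len(nf)]
  }
  power <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  structure(data.frame(freq = seq(0, by = 1 / (nseg * dt), length.out = nf),
                       power = power * dbl),
            dt = dt, class = c("bd_psd", "data.frame"))
}

#' Per-segment features for SEM estimates and paired tests
#'
#' Splits the series into `n_segments` contiguous equal-length parts (trailing
#' remainder dropped) and computes a feature on each part independently.
#'
#' @param ts a [bd_timeseries()] or [bd_envelope()].
#' @param n_segments number of parts (default 5).
#' @param fun feature function applied to each segment (default
#'   `burst_profiles` on the segment's envelope when given a time series).
#' @param ... passed on to `fun`.
#' @return List of `n_segments` feature objects.
#' @export
segment_features <- function(ts, n_segments = 5, fun = NULL, ...) {
  dt <- ts_dt(ts)
  x <- as.numeric(ts)
  len <- floor(length(x) / n_segments)
  if (len < 2) stop("series too short for ", n_segments, " segments")
  is_env <- inherits(ts, "bd_envelope")
  if (is.null(fun)) {
    fun <- if (is_env) burst_profiles else
      function(t, ...) burst_profiles(hilbert_envelope(t), ...)
  }
  lapply(seq_len(n_segments), function(i) {
    seg <- x[((i - 1) * len + 1):(i * len)]
    seg <- if (is_env) bd_envelope(seg, dt) else bd_timeseries(seg, dt)
    fun(seg, ...)
  })
}
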