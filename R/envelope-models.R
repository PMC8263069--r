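#' Polynomial drift function
#'
#' Drift mu(x) = sum_i d_i x^i for the stochastic envelope model
#' dx = mu(x) dt + zeta dW. Integrability of the burst-duration integrals
#' requires the leading coefficient to be negative.
#'
#' @param coeffs numeric vector `c(d0, d1, ..., d_nP)`; `d_nP < 0`.
#' @return Object of class `bd_drift` with elements `coeffs` and `degree`.
#' @export
polynomial_drift <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) < 2) stop("degree must be >= 1 (supply at least d0, d1)")
  if (tail(coeffs, 1) >= 0)
    stop("leading drift coefficient must be negative (drift must decay at +Inf)")
  structure(list(coeffs = coeffs, degree = length(coeffs) - 1L),
            class = "bd_drift")
}

#' Ornstein-Uhlenbeck drift mu(x) = -theta x
#' @param theta positive decay parameter (1/s).
#' @export
ou_drift <- function(theta) {
  stopifnot_scalar(theta, "theta", positive = TRUE)
  out <- polynomial_drift(c(0, -theta))
  out$theta <- theta
  out
}

#' @export
print.bd_drift <- function(x, ...) {
  cat(sprintf("<bd_drift> degree %d: mu(x) = %s\n", x$degree,
              paste(sprintf("%+g x^%d", x$coeffs, seq_along(x$coeffs) - 1),
                    collapse = " ")))
  invisible(x)
}

#' Evaluate a polynomial drift
#' @param drift a [polynomial_drift()].
#' @param x numeric vector.
#' @export
drift_mu <- function(drift, x) {
  out <- rep(tail(drift$coeffs, 1), length(x))
  for (k in rev(seq_len(length(drift$coeffs) - 1)))
    out <- out * x + drift$coeffs[k]
  out
}

#' Drift antiderivative Lambda(x) = sum_i d_i x^(i+1) / (i+1), Lambda(0) = 0
#' @inheritParams drift_mu
#' @export
drift_lambda <- function(drift, x) {
  d <- drift$coeffs
  out <- 0
  for (k in rev(seq_along(d))) out <- (out + d[k] / k) * x
  out
}

# largest root of mu with mu' < 0 (stable fixed point); used to initialize
# polynomial simulations
stable_root <- function(drift) {
  r <- polyroot(drift$coeffs)
  r <- Re(r[abs(Im(r)) < 1e-8])
  if (!length(r)) return(0)
  d_prime <- drift$coeffs[-1] * seq_len(drift$degree)
  slope <- vapply(r, function(x) {
    out <- tail(d_prime, 1)
    for (k in rev(seq_len(length(d_prime) - 1))) out <- out * x + d_prime[k]
    out
  }, numeric(1))
  stable <- r[slope < 0]
  if (!length(stable)) max(r) else max(stable)
}

#' Simulate a discretized Ornstein-Uhlenbeck envelope
#'
#' Uses the exact updating equation
#' `x(t+dt) = x(t) exp(-theta dt) + n sqrt(zeta^2 (1 - exp(-2 theta dt)) / (2 theta))`.
#' By default the trajectory is then shifted upward by the absolute value of
#' its 0.1th percentile and floored at zero, so it is a valid (non-negative)
#' envelope; percentile-threshold burst profiles are invariant to this shift.
#'
#' @param theta decay parameter (1/s), > 0.
#' @param zeta noise standard deviation (amplitude / sqrt(s)).
#' @param dt time step (s).
#' @param duration simulated duration (s).
#' @param seed integer seed.
#' @param x0 initial state; `NULL` (default) draws from the stationary
#'   distribution N(0, zeta^2 / (2 theta)), so no burn-in is needed.
#' @param shift apply the positivity shift (default TRUE). With
#'   `shift = FALSE` the raw (possibly negative) trajectory is returned as a
#'   `bd_timeseries`.
#' @return A [bd_envelope()] (or [bd_timeseries()] when `shift = FALSE`) with
#'   attribute `shift` (the applied offset).
#' @export
simulate_ou <- function(theta, zeta, dt, duration, seed = NULL, x0 = NULL,
                        shift = TRUE) {
  stopifnot_scalar(theta, "theta", positive = TRUE)
  n <- round(duration / dt)
  a <- exp(-theta * dt)
  s <- if (zeta > 0) sqrt(zeta^2 * (1 - a^2) / (2 * theta)) else 0
  with_seed(seed, {
    if (is.null(x0)) x0 <- rnorm(1, 0, if (zeta > 0) zeta / sqrt(2 * theta) else 0)
    innov <- if (s > 0) rnorm(n, 0, s) else numeric(n)
    innov[1] <- innov[1] + a * x0
    x <- as.numeric(stats::filter(innov, a, method = "recursive"))
    if (!shift) return(structure(bd_timeseries(x, dt), shift = 0))
    off <- abs(quantile(x, 0.001, names = FALSE))
    structure(bd_envelope(pmax(x + off, 0), dt), shift = off)
  })
}

#' Simulate a polynomial-drift envelope (Euler-Maruyama)
#'
#' `x <- |x + mu(x) dt + zeta sqrt(dt) n|` at each step; the absolute value
#' enforces envelope positivity. Starts at the largest stable root of the
#' drift and discards a 10 s burn-in. Aborts if |x| exceeds 1e6.
#'
#' @param drift a [polynomial_drift()].
#' @param zeta noise SD.
#' @param dt time step in seconds (default 1e-3).
#' @param duration duration after burn-in (s).
#' @param seed integer seed.
#' @param x0 initial state (default: largest stable root of the drift).
#' @param burn_in burn-in discarded, in seconds (default 10).
#' @return A [bd_envelope()].
#' @export
simulate_polynomial <- function(drift, zeta, dt = 1e-3, duration, seed = NULL,
                                x0 = NULL, burn_in = 10) {
  if (tail(drift$coeffs, 1) >= 0) stop("leading drift coefficient must be negative")
  n_burn <- round(burn_in / dt)
  n <- round(duration / dt)
  if (is.null(x0)) x0 <- stable_root(drift)
  with_seed(seed, {
    x <- sim_poly_cpp(drift$coeffs, zeta, dt, n + n_burn, x0)
    bd_envelope(x[(n_burn + 1):(n_burn + n)], dt)
  })
}

#' Turn an envelope into oscillatory activity z(t) = x(t) cos(2 pi nu t)
#'
#' @param env a [bd_envelope()].
#' @param nu carrier frequency in Hz (below Nyquist).
#' @param target_sd optional: rescale so that sd(z) matches this value.
#' @return A [bd_timeseries()].
#' @export
synthesize_oscillation <- function(env, nu, target_sd = NULL) {
  dt <- ts_dt(env)
  if (nu >= 1 / (2 * dt)) stop("carrier frequency must be below Nyquist")
  t <- (seq_along(env) - 1) * dt
  z <- as.numeric(env) * cos(2 * pi * nu * t)
  if (!is.null(target_sd)) z <- z * target_sd / stats::sd(z)
  bd_timeseries(z, dt)
}

#' Stationary density of a polynomial-drift envelope model
#'
#' For the positivity-enforced (reflected) model on \[0, Inf) the stationary
#' density is proportional to exp(2 Lambda(x) / zeta^2).
#'
#' @param drift a [polynomial_drift()].
#' @param zeta noise SD.
#' @param x evaluation grid (non-negative); default: automatic grid covering
#'   the bulk of the mass.
#' @return data frame `x`, `density` (normalized on the grid).
#' @export
stationary_density <- function(drift, zeta, x = NULL) {
  if (is.null(x)) {
    # expand until the log-density has fallen far below its maximum
    hi <- max(2 * abs(stable_root(drift)), 1)
    repeat {
      g <- seq(0, hi, length.out = 2048)
      ld <- 2 * drift_lambda(drift, g) / zeta^2
      if (max(ld) - ld[length(ld)] > 40) break
      hi <- hi * 2
      if (hi > 1e6) break
    }
    x <- g
  }
  ld <- 2 * drift_lambda(drift, x) / zeta^2
  d <- exp(ld - max(ld))
  w <- c(diff(x), 0) / 2 + c(0, diff(x)) / 2
  data.frame(x = x, density = d / sum(d * w))
}
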