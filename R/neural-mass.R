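#' Parameters of the two-population stochastic Wilson-Cowan model
#'
#' Excitatory (E, modelling the STN and hence the recorded LFP) and inhibitory
#' (I, GPe) populations:
#' `dE = (-E + f(lambda_E - w_IE I(t - Delta_IE))) dt / Omega_E + zeta dW_E`
#' `dI = (-I + f(-lambda_I + w_EI E(t - Delta_EI) - w_II I(t - Delta_II))) dt / Omega_I + zeta dW_I`
#' with activation `f(x) = beta x` (linear) or the sigmoid
#' `eta / (1 + exp(-beta (x - 1)))`.
#'
#' @param w_IE,w_EI,w_II non-negative connection weights.
#' @param lambda_E,lambda_I constant inputs (zero only affects transients in
#'   the linear variant).
#' @param omega_E,omega_I population time constants, seconds (> 0).
#' @param zeta noise SD (> 0).
#' @param activation `"linear"` or `"sigmoid"`.
#' @param beta activation slope.
#' @param eta sigmoid scale (> 0; sigmoid only).
#' @param delta_IE,delta_EI,delta_II connection delays, seconds (>= 0).
#' @return list of class `bd_wc_params`.
#' @export
wc_params <- function(w_IE, w_EI, w_II = 0, lambda_E = 0, lambda_I = 0,
                      omega_E, omega_I, zeta,
                      activation = c("linear", "sigmoid"), beta = 1, eta = 1,
                      delta_IE = 0, delta_EI = 0, delta_II = 0) {
  activation <- match.arg(activation)
  if (min(w_IE, w_EI, w_II) < 0) stop("weights must be non-negative")
  stopifnot_scalar(omega_E, "omega_E", positive = TRUE)
  stopifnot_scalar(omega_I, "omega_I", positive = TRUE)
  stopifnot_scalar(zeta, "zeta", positive = TRUE)
  if (min(delta_IE, delta_EI, delta_II) < 0) stop("delays must be >= 0")
  if (activation == "sigmoid" && eta <= 0) stop("sigmoid requires eta > 0")
  structure(list(w_IE = w_IE, w_EI = w_EI, w_II = w_II,
                 lambda_E = lambda_E, lambda_I = lambda_I,
                 omega_E = omega_E, omega_I = omega_I, zeta = zeta,
                 activation = activation, beta = beta, eta = eta,
                 delta_IE = delta_IE, delta_EI = delta_EI,
                 delta_II = delta_II), class = "bd_wc_params")
}

#' @export
print.bd_wc_params <- function(x, ...) {
  cat(sprintf(
    "<bd_wc_params> %s: w_IE=%.3g w_EI=%.3g w_II=%.3g, Omega=(%.3g, %.3g) s, zeta=%.3g\n",
    x$activation, x$w_IE, x$w_EI, x$w_II, x$omega_E, x$omega_I, x$zeta))
  if (x$activation == "sigmoid")
    cat(sprintf("  beta=%.3g eta=%.3g, delays (IE,EI,II)=(%g, %g, %g) s\n",
                x$beta, x$eta, x$delta_IE, x$delta_EI, x$delta_II))
  invisible(x)
}

#' Drift matrix of the linear Wilson-Cowan variant
#'
#' Jacobian of the deterministic part with `f(x) = beta x` and no delays;
#' its eigenvalues determine stability (negative real parts) and the
#' spectral peak (imaginary part / 2 pi Hz).
#'
#' @param params a [wc_params()].
#' @return 2x2 matrix.
#' @export
wc_jacobian <- function(params) {
  with(params, matrix(c(-1 / omega_E, beta * w_EI / omega_I,
                        -beta * w_IE / omega_E,
                        -(1 + beta * w_II) / omega_I), 2, 2))
}

#' Closed-form output spectrum of the linear Wilson-Cowan variant
#'
#' One-sided spectral density of E. With `dt = NULL` the continuous-time
#' system dX = M X dt + (zeta, zeta) dW gives
#' `S_E(f) = 2 zeta^2 sum_j |[(i 2 pi f - M)^-1]_{1j}|^2`. With a time step,
#' the Euler-discretized model is the VAR(1) `x_t = (I + M dt) x_(t-1) + e`,
#' `e ~ N(0, zeta^2 dt I)`, whose density is
#' `2 zeta^2 dt^2 sum_j |[(I - A exp(-i 2 pi f dt))^-1]_{1j}|^2`; the
#' discretization noticeably sharpens and shifts broad peaks, so the discrete
#' form is the right reference for simulated output.
#'
#' @param params a [wc_params()] (linear activation).
#' @param freq frequencies in Hz.
#' @param dt simulation time step in seconds, or `NULL` for the
#'   continuous-time density.
#' @return Numeric vector of spectral densities (units^2/Hz).
#' @export
wc_psd_linear <- function(params, freq, dt = NULL) {
  M <- wc_jacobian(params)
  if (is.null(dt)) {
    iw <- complex(imaginary = 2 * pi * freq)
    det <- (iw - M[1, 1]) * (iw - M[2, 2]) - M[1, 2] * M[2, 1]
    return(2 * params$zeta^2 * (Mod(iw - M[2, 2])^2 + Mod(M[1, 2])^2) /
             Mod(det)^2)
  }
  A <- diag(2) + M * dt
  z <- exp(complex(imaginary = -2 * pi * freq * dt))
  det <- (1 - A[1, 1] * z) * (1 - A[2, 2] * z) - A[1, 2] * A[2, 1] * z^2
  2 * params$zeta^2 * dt^2 * (Mod(1 - A[2, 2] * z)^2 + Mod(A[1, 2] * z)^2) /
    Mod(det)^2
}

#' Simulate the stochastic Wilson-Cowan model
#'
#' Euler-Maruyama with ring-buffer delayed states; delays are rounded to the
#' nearest integer multiple of dt (rounding recorded in the `delays_steps`
#' attribute) and history before t = 0 is held at the initial state.
#'
#' @param params a [wc_params()].
#' @param dt time step, seconds (default 1e-3; must be well below the time
#'   constants).
#' @param duration seconds (after burn-in).
#' @param seed integer seed.
#' @param burn_in discarded initial stretch, seconds (default 10).
#' @param init c(E0, I0) initial state (default c(0, 0) for linear, c(eta/2,
#'   eta/2) for sigmoid).
#' @return list: `E`, `I` as [bd_timeseries()].
#' @export
simulate_wc <- function(params, dt = 1e-3, duration, seed = NULL,
                        burn_in = 10, init = NULL) {
  if (dt > min(params$omega_E, params$omega_I) / 10)
    stop("dt must be < min(omega)/10 for a stable integration")
  if (is.null(init))
    init <- if (params$activation == "linear") c(0, 0) else
      rep(params$eta / 2, 2)
  dsteps <- round(c(params$delta_IE, params$delta_EI, params$delta_II) / dt)
  n_burn <- round(burn_in / dt)
  n <- round(duration / dt)
  m <- with_seed(seed, sim_wc_cpp(
    n + n_burn, dt, params$w_IE, params$w_EI, params$w_II,
    params$lambda_E, params$lambda_I, params$omega_E, params$omega_I,
    params$zeta, if (params$activation == "linear") 0L else 1L,
    params$beta, params$eta, dsteps[1], dsteps[2], dsteps[3],
    init[1], init[2]))
  keep <- (n_burn + 1):(n_burn + n)
  out <- list(E = bd_timeseries(m[keep, 1], dt),
              I = bd_timeseries(m[keep, 2], dt))
  attr(out, "delays_steps") <- dsteps
  out
}

#' Fitting features of a Wilson-Cowan model: PSD and burst duration profile
#'
#' Simulates `n_repeats` independent runs, computes the PSD of E and the burst
#' duration profile of the modulus of E's analytic signal on each, and
#' averages across repeats.
#'
#' @param params a [wc_params()].
#' @param dt time step (s).
#' @param n_repeats repeats (default 5).
#' @param repeat_duration seconds per repeat (default 1000).
#' @param percentiles percentile grid.
#' @param min_duration minimum burst duration, s (default 0.1, as in data
#'   analysis).
#' @param seed master seed.
#' @return list: `psd` (bd_psd, repeat-averaged), `profile` (bd_profile,
#'   repeat-averaged mean durations).
#' @export
wc_features <- function(params, dt = 1e-3, n_repeats = 5,
                        repeat_duration = 1000,
                        percentiles = default_percentiles(),
                        min_duration = 0.1, seed = NULL) {
  if (is.null(seed)) seed <- 1L
  psds <- NULL; profs <- NULL; base_psd <- NULL; base_prof <- NULL
  for (i in seq_len(n_repeats)) {
    sim <- simulate_wc(params, dt, repeat_duration,
                       seed = derive_seed(seed, i))
    p <- psd(sim$E)
    env <- hilbert_envelope(sim$E, smooth_span = 0)
    pr <- burst_profiles(env, percentiles, min_duration)
    psds <- cbind(psds, p$power)
    profs <- cbind(profs, pr$mean_duration_s)
    base_psd <- p; base_prof <- pr
  }
  base_psd$power <- rowMeans(psds)
  base_prof$mean_duration_s <- rowMeans(profs, na.rm = TRUE)
  base_prof$sem_duration_s <- apply(profs, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 2) NA_real_ else stats::sd(r) / sqrt(length(r))
  })
  list(psd = base_psd, profile = base_prof)
}
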