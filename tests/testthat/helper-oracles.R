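# independent brute-force oracles used across test files

erfc <- function(x) 2 * pnorm(-x * sqrt(2))

# run-length burst scanner: plain loop, no vectorization tricks
brute_force_bursts <- function(env, threshold, min_duration, dt) {
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE; s <- 0L
  for (i in seq_along(env)) {
    if (env[i] > threshold) {
      if (!in_run) { in_run <- TRUE; s <- i - 1L }
    } else if (in_run) {
      in_run <- FALSE
      if ((i - 1L - s) * dt >= min_duration) { starts <- c(starts, s); ends <- c(ends, i - 1L) }
    }
  }
  if (in_run && (length(env) - s) * dt >= min_duration) {
    starts <- c(starts, s); ends <- c(ends, length(env))
  }
  data.frame(start = starts, end = ends)
}

# step-by-step two-stage adaptive linear step-up (independent of the package)
brute_force_two_stage_fdr <- function(p, q) {
  m <- length(p)
  bh <- function(p, level) {
    o <- order(p); rej <- logical(m); thr <- 0
    for (i in m:1) if (p[o[i]] <= level * i / m) { thr <- i; break }
    if (thr > 0) rej[o[1:thr]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  r1 <- sum(bh(p, q1))
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, q1 * m / (m - r1))
}

# Barnard: brute-force enumeration over all outcome tables and a nuisance grid
brute_force_barnard <- function(k1, k2, n1, n2, n_grid = 1e4) {
  wald <- function(a, b) {
    p1 <- a / n1; p2 <- b / n2; pp <- (a + b) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    if (se == 0) 0 else (p1 - p2) / se
  }
  tobs <- wald(k1, k2)
  pmax_val <- 0
  for (pi in seq(1e-6, 1 - 1e-6, length.out = n_grid)) {
    tot <- 0
    for (a in 0:n1) for (b in 0:n2) {
      if (wald(a, b) >= tobs - 1e-12)
        tot <- tot + dbinom(a, n1, pi) * dbinom(b, n2, pi)
    }
    if (tot > pmax_val) pmax_val <- tot
  }
  min(pmax_val, 1)
}

# beta-band-like AR(2): complex poles at frequency f_hz with radius r
ar2_beta_spec <- function(f_hz = 20, r = 0.98, dt = 1e-3, sd = 1) {
  arma_spec(ar = c(2 * r * cos(2 * pi * f_hz * dt), -r^2), sd = sd)
}

# hand-built step envelope with known bursts at every profile threshold
hand_envelope <- function(dt = 0.01) {
  # values cycle through plateaus 1..4 with returns to 0; percentile
  # thresholds and per-threshold bursts are enumerable by hand
  v <- c(rep(0, 10), rep(1, 5), rep(0, 10), rep(2, 8), rep(0, 10),
         rep(3, 4), rep(0, 10), rep(4, 6), rep(0, 10))
  bd_envelope(v, dt)
}
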