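# burstdyn

Tools for characterising transient oscillatory **bursts** in neural time
series — beta-band (13–35 Hz) local field potentials being the motivating
case — and for reading the *dynamics* of the oscillation envelope out of
burst statistics.

Neural oscillations come and go in bursts, and burst **duration** (rather
than amplitude) distinguishes physiological from pathological regimes in the
parkinsonian basal ganglia. `burstdyn` is built around the **average burst
duration profile**: with the envelope `x(t)` of the band-limited signal and a
threshold `L` at each envelope percentile from the 20th to the 95th, a burst
is a maximal episode with `x > L` (at least 100 ms in data analysis), and the
profile maps each percentile to the mean burst duration.

The package provides, in one consistent framework:

* **Feature extraction** — zero-phase band-pass filtering around the
  spectral peak, Hilbert envelopes, burst detection, duration/amplitude/rate
  profiles, envelope PDFs, Welch spectra.
* **Linear surrogate testing** — FT, IAAFT and gradual wavelet
  reconstruction (GWR, MODWT-based, parametrised by the pinned energy
  fraction ρ) surrogates, and the **BDDLS** statistic (burst duration
  distance to linear surrogates),
  `BDDLS = Σ_L (τ_data(L) − τ_surr(L))² / mean_L(τ_surr)²`,
  with exact rank-based significance from 19-surrogate ensembles and a
  battery of supporting tests (two-stage adaptive FDR, cluster-based
  permutation tests, exact rank tests, binomial and Barnard tests).
* **Generative models** — stochastic envelope models
  `dx = μ(x) dt + ζ dW` with polynomial drift `μ(x) = Σ d_i x^i`
  (Ornstein–Uhlenbeck `μ = −θx` as the linear case, exact updating), and
  stochastic Wilson–Cowan models of the STN–GPe loop, linear or sigmoid with
  delays (Rcpp integrators).
* **Analytic burst durations** — for the time-discretized envelope model,
  to first order in the time step,

  `τ(L) ≈ √(2π dt)/ζ · ∫_L^∞ exp[(2/ζ²)(Λ(x) − Λ(L))] dx`,  `Λ' = μ`,

  derived from mean-first-passage theory with three discretization
  corrections (threshold-start bias `Γ̄ = ζ√(2dt/π)`, MFPT-derivative
  correction `A0 = (π−4)/(π+4) ≈ −0.12`, mean overshoot
  `Δ̄ = (ζ/2)√(πdt/2)`). For OU this closes to
  `τ = π√(dt/(2θ)) e^{θL²/ζ²} erfc(√θ L/ζ)`, and in percentile form to the
  ζ-free `τ = π√(2dt/θ)(1 − L%) exp(erfinv(2L% − 1)²)`.
* **Fitting** — generalized pattern search ("positive basis 2N") with
  common random numbers, minimal-model selection (lowest polynomial degree
  with profile R² > 0.95, BIC-checked), and Wilson–Cowan fits with
  PSD-peak rejection sampling.
* **The passage method** — inversion of the burst-duration relation,

  `μ(L) ≈ −( ζ√(π dt/2) + (ζ²/2) ∂τ/∂L ) / τ(L)`,

  recovering the envelope drift function from a measured profile, plus a
  direct finite-difference comparator and forward simulation of recovered
  dynamics.

## Worked example

Simulate a discretized OU envelope, compare its burst duration profile with
the closed form, test it for non-linearity, and recover its drift:

```r
library(burstdyn)

env  <- simulate_ou(theta = 1, zeta = 1, dt = 1e-3, duration = 1000, seed = 42)
prof <- burst_profiles(env, min_duration = 0)
head(prof[, c("percentile", "threshold", "mean_duration_s", "rate_hz", "n_bursts")], 4)
#>   percentile threshold mean_duration_s rate_hz n_bursts
#> 1       0.20      1.76          0.1586    5.04     5045
#> 2       0.25      1.88          0.1290    5.82     5815
#> 3       0.30      1.99          0.1118    6.26     6259
#> 4       0.35      2.08          0.0939    6.92     6921

max(abs(prof$mean_duration_s /
        ou_burst_duration_percentile(1, 1e-3, prof$percentile) - 1))
#> [1] 0.099   # largest relative deviation from the closed form (95th pct)

z  <- synthesize_oscillation(env, nu = 20)     # 20 Hz oscillation
rt <- bddls_rank_test(z, n = 19, min_duration = 0, seed = 1)
c(BDDLS = rt$statistic, p = rt$p_value)
#>  BDDLS      p
#>  0.030   0.05    # a linear generator: BDDLS small; p is the rank-test level

est <- infer_drift_passage(env, zeta = 1)      # passage method
sel <- is.finite(est$mu_hat) &
       est$x > quantile(env, 0.2) & est$x < quantile(env, 0.8)
coef(lm(est$mu_hat[sel] ~ est$x[sel]))[2]
#> -1.12    # recovered drift slope; the generator used mu(x) = -1 * x
```

At the 20th–95th percentiles the measured profile tracks the analytic
formula to within ~2% except at the noisy 95th percentile of a single 1000 s
realization; the passage method recovers the linear drift slope within ~12%
from the same data.

A command-line interface over the same functions is installed at
`inst/cli/burstdyn.R` (`Rscript <path> profile in.csv out.csv`, plus
`filter`, `envelope`, `surrogate`, `bddls`, `analytic`, `simulate`,
`fixtures`, `passage`).

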