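---
title: "Burst duration profiles and envelope dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst duration profiles and envelope dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstdyn)
```

## The scientific problem

Beta-band (13–35 Hz) activity in basal-ganglia field potentials comes in
transient bursts, and the *duration* of these bursts carries information
about the dynamical state of the circuit that the average power does not.
`burstdyn` works with the **average burst duration profile**: the envelope of
the band-limited signal is thresholded at every percentile from the 20th to
the 95th (5% steps), a burst is a maximal supra-threshold episode (in data
analysis, one lasting at least 100 ms), and the profile records the mean
burst duration at each threshold. The profile is the package's central
feature: it is cheap to estimate from short recordings, does not depend on
one arbitrary threshold, and — as the passage method below makes precise —
is a direct signature of the envelope's drift function.

The toolkit has five layers:

1. **Feature extraction** — band-pass filtering around the spectral peak,
   Hilbert envelopes, burst detection, threshold profiles, envelope PDFs,
   Welch spectra (`prepare_pair()`, `hilbert_envelope()`, `detect_bursts()`,
   `burst_profiles()`, `envelope_pdf()`, `psd()`).
2. **Linear surrogates and the BDDLS statistic** — Fourier, IAAFT and
   gradual-wavelet-reconstruction (GWR) surrogates preserve the linear
   structure of a signal while destroying non-linear structure; the burst
   duration distance to linear surrogates (BDDLS) quantifies how far the
   observed profile departs from its linear-surrogate expectation
   (`ft_surrogate()`, `iaaft_surrogate()`, `gwr_surrogate()`, `bddls()`),
   with a battery of statistical tests (`adaptive_fdr()`,
   `cluster_permutation_test()`, `barnard_test()`, ...).
3. **Generative models** — stochastic envelope models
   `dx = mu(x) dt + zeta dW` with polynomial drift (the Ornstein–Uhlenbeck
   process is the linear special case), and the stochastic two-population
   Wilson–Cowan model of the STN–GPe loop, linear or sigmoid-activated with
   delays (`simulate_ou()`, `simulate_polynomial()`, `simulate_wc()`).
4. **Analytic burst durations for discretized models** — mean-first-passage
   theory with first-order-in-dt discretization corrections
   (`discrete_burst_duration()`, `ou_burst_duration()`,
   `correction_constants()`, `calibrate_a0()`).
5. **Inference** — model fitting by generalized pattern search with
   minimal-model selection (`fit_envelope_model()`, `select_minimal_model()`,
   `fit_wc()`), and the **passage method**, which inverts a burst duration
   profile into a tabulated drift function (`infer_drift_passage()`).

## Average burst duration as a first passage time

For the continuous-time process `dx = mu(x) dt + zeta dW` the mean first
passage time (MFPT) from `x0` down to a threshold `L` is the classical double
integral with `T(x) = (2/zeta^2) * int_x^Inf exp((2/zeta^2)(Lambda(x1) -
Lambda(x))) dx1`, where `Lambda` is the antiderivative of the drift
(`continuous_mfpt()`). The average burst duration of a *continuous* process
is zero — trajectories started on the threshold recross immediately — so
burst duration is intrinsically a property of the time-discretized process.
Three first-order-in-dt corrections connect the two:

* starting on the threshold, the discrete process takes an extra
  `gamma_bar * T(L)` to exit, with `gamma_bar = zeta * sqrt(2 dt / pi)` the
  mean first step above the threshold;
* the MFPT derivative at the boundary is scaled by `A0 + 1`; a first-step
  analysis gives `A0 = 1/pi - 1/2 ~ -0.18`, while direct calibration against
  simulated discretized processes gives `A0 = (pi-4)/(pi+4) ~ -0.12`
  (`calibrate_a0()` reproduces this number from scratch);
* bursts begin at the *overshoot* of the threshold, whose mean is
  `delta_bar = (zeta/2) * sqrt(pi dt / 2)`.

Combining the three gives the package's workhorse approximation

```
tau(L) = sqrt(2 pi dt) / zeta * int_L^Inf exp((2/zeta^2)(Lambda(x) - Lambda(L))) dx ,
```

implemented by adaptive quadrature in `discrete_burst_duration()`. For the
OU drift `mu(x) = -theta x` it collapses to
`tau(L) = pi sqrt(dt/(2 theta)) exp(theta L^2/zeta^2) erfc(sqrt(theta) L / zeta)`,
and, with thresholds expressed as percentile ranks through the stationary
Gaussian CDF, to the zeta-free form implemented by
`ou_burst_duration_percentile()`. The Rayleigh drift
`mu(x) = -theta x + zeta^2/(2x)` gives
`tau(L) = sqrt(2 pi dt) zeta / (2 theta L)` (`rayleigh_burst_duration()`).
A note on checking these forms: the typeset closed forms are easy to
mis-transcribe (a leading `pi` versus a `pi` under the square root differ by
`sqrt(pi)` ~ 1.77). The package pins them with an exact discrete-time oracle:
for the exact OU updating, the mean burst duration at the median threshold
equals `0.5 dt / P(x_t <= L < x_(t+1))`, with the upcrossing probability
given by the bivariate-normal orthant formula. The test suite asserts this
identity and long-simulation agreement at every percentile.

Because all thresholds are percentile-based, the positivity shift applied to
simulated OU envelopes (adding the absolute 0.1th percentile and flooring at
zero) leaves profiles unchanged; polynomial models instead keep the absolute
value of each Euler–Maruyama step, which only affects thresholds near zero.

## The passage method

Rearranging the boundary-value problem satisfied by `T` and substituting the
discrete-time relation `tau(L) = zeta * sqrt(pi dt / 2) * T(L)` yields

```
mu(L) = -( zeta sqrt(pi dt / 2) + (zeta^2 / 2) dtau/dL ) / tau(L) ,
```

a local inversion from the measured profile to the drift
(`passage_invert()`). `infer_drift_passage()` applies it at 300 thresholds
equally spaced from 1/50 to 90% of the envelope maximum (extreme thresholds
yield unreliable means), with LOWESS smoothing of the profile (span = range/8)
and of its numerical derivative (span/5); central differences are used on the
grid, one-sided at the edges, and SEM bands come from repeating the
estimate on four contiguous data segments with the noise parameter fixed.
Thresholds with no bursts are flagged missing and excluded from the smoothing
fits rather than zero-filled. The method degenerates where `dtau/dL ~ 0`, and
it cannot represent delayed or state-dependent-noise dynamics — the model
class is "complicated dynamics, simple noise".

The noise parameter is known for synthetic data; for recordings
`estimate_noise()` scans a candidate grid, forward-simulates the inferred
dynamics for each candidate (`simulate_inferred()`, clamped linear
interpolation of the tabulated drift, absolute-value positivity) and scores
the match of the burst duration profile and of the envelope inverse CDF. The
profile part of the score uses log-durations over thresholds above the 20th
envelope percentile: near-floor thresholds carry durations orders of
magnitude larger than the rest and would otherwise dominate the normalized
error; the inverse-CDF part is what pins the amplitude scale, because the
passage inversion reproduces the profile almost by construction at any
candidate zeta. For empirical envelopes the effective time step should be
the envelope's own time scale of variation (about one oscillation cycle,
0.05 s for beta), with the envelope resampled accordingly; for synthetic
data it is the generator step.

`infer_drift_direct()` is the comparator: first-order differences of
consecutive envelope samples averaged in 300 equal-width state bins.
`compare_methods()` runs both without smoothing on simulated envelopes of
several durations and reports the sum of squared errors against the known
drift on each method's own valid grid points.

## Surrogates and BDDLS

`iaaft_surrogate()` alternates spectral-amplitude adjustment with
rank-matching to the original values and always ends on the rank step, so the
value multiset is exact while the spectrum is matched to within a reported
mismatch (convergence declared when the relative spectral mismatch changes by
less than 1e-6, or after 100 iterations). `gwr_surrogate()` ranks MODWT
coefficients by squared magnitude across all scales and positions, fixes the
largest ones covering the energy fraction `rho`, IAAFT-randomizes the rest
within each scale (fixed positions restored after every iteration), inverts
the transform, and finishes with a whole-series IAAFT pass rank-matched to
the data values. The final-level scaling coefficients (the slow trend) are
always kept, which is what lets GWR surrogates absorb slow nonstationarity.
`rho = 0` is exactly IAAFT; `rho = 1` returns the data. The wavelet is the
8-tap least-asymmetric Daubechies filter with depth `floor(log2 N) - 2` by
default; arbitrary lengths are handled by the MODWT's circular filtering, so
no power-of-two padding is needed. The exact per-scale versus global
alternation schedule of the published GWR algorithm is not fully specified in
the literature we follow; the order implemented here (per-scale constrained
IAAFT, inverse transform, then one global pass) satisfies the contracts that
matter downstream — exact value multiset, spectral mismatch well under 5%,
monotone approach to the data as `rho` grows — all of which are asserted in
the tests.

`bddls()` is the sum over the percentile grid of squared differences between
the data and surrogate-ensemble-mean burst duration profiles, divided by the
squared mean of the surrogate profile; the scaling makes it dimensionless,
invariant to amplitude rescaling, and decorrelated from overall duration
differences. Significance uses the classic surrogate rank test
(`bddls_rank_test()`): with 19 surrogates, the data statistic ranking first
has exact one-sided level 1/20, and each surrogate is scored against the mean
of the other 18 (leave-one-out) to form the null. Ensembles default to 19
realizations for exactly this reason.

The statistical battery follows the field's conventions: per-threshold
pooled-variance t-tests between five-segment profile estimates (df = 8) under
adaptive FDR control; the two-stage adaptive linear step-up estimator of the
number of true nulls (the lowest-slope variant is available via an argument —
which adaptive estimator the original analyses used is not recoverable, so
both are provided and the two-stage form is the default); a paired
cluster-based permutation test with bin-wise paired t statistics, a two-sided
p < 0.05 cluster-forming threshold, summed-t cluster mass and sign-flipping
null (exhaustive when 2^n fits the permutation budget — note that with five
paired segments the symmetric exhaustive null makes the smallest attainable
cluster p equal to 2/32, so the nominal 5% level is only attainable from
eight pairs upward); exact signed-rank and
Spearman tests; the one-sided upper-tail binomial test; and Barnard's
unconditional exact test with the pooled Wald statistic maximized over a
1001-point nuisance grid, one-sided by default (the sidedness of the
published worked example is not stated; the one-sided Wald variant reproduces
its p = 0.0551).

## Models and fitting

Envelope models are simulated with the exact OU updating equation (so no
time-step bias at all for the linear case) or Euler–Maruyama for polynomial
drifts (`dt = 1e-3 s` by default, matching typical LFP sampling; trajectories
start at the largest stable root of the drift, the first 10 s are discarded,
and |x| > 1e6 aborts with diagnostics). The Wilson–Cowan integrator uses
ring-buffer delayed states, delays rounded to integer multiples of dt (the
rounding is recorded), constant history before t = 0, and a burn-in of 10 s.
A zero delay reads the previous step's state, which is bit-identical to the
non-delayed explicit scheme — there is a single code path, and a test pins
this. For the linear variant the output spectrum has a closed form from the
drift matrix; the package evaluates both the continuous-time form and the
VAR(1) form of the Euler discretization (`wc_psd_linear()`), and uses the
latter wherever simulated output is the reference, because at `dt = 1e-3`
the discretization visibly sharpens broad spectral peaks.

Fitting minimizes the normalized feature cost (`feature_cost()`): each
feature contributes its squared error divided by the data feature's centered
sum of squares, averaged over features, so `R^2 = 1 - cost`. Envelope models
are fitted to the burst duration profile alone; Wilson–Cowan models to the
PSD and the profile jointly, with candidate parameter sets rejection-sampled
until the model PSD peak is within 1 Hz and 30% in magnitude of the data
peak. The optimizer is a generalized pattern search with the positive basis
2N poll, mesh doubling/halving, a 1e-5 mesh tolerance and a 600-call budget,
on per-coordinate scales (`pattern_search()`). Stochastic objectives use
common random numbers — fixed per-candidate simulation seeds — so each
candidate's objective is deterministic and the pattern search is
well-defined. Envelope-model objectives are evaluated from the analytic
percentile-mapped profile by default (deterministic, orders of magnitude
faster, accurate to a few percent); simulation-based evaluation is available
via `method = "simulate"`. Fits whose stationary envelope PDF has negative
R^2 against a supplied target PDF are rejected; this matters because the
percentile profile alone cannot pin the amplitude scale.

`select_minimal_model()` increases the polynomial degree from 1 (OU) until
the profile fit exceeds R^2 = 0.95; the BIC (Gaussian-residual form
`n log(RSS/n) + k log n`, `k` = drift coefficients + zeta; the published
convention is unstated, so this standard form is used) is reported for every
degree tried, and in the recovery experiments the minimal model also has the
lowest BIC. Random-start bounds are coefficients in [-50, 50] (leading
coefficient negative), zeta in (0, 5]; Wilson–Cowan weights in (0, 10], time
constants in [10, 50] ms (the lower end keeps the Euler step stable at
dt = 1 ms), slopes in (0, 10], sigmoid scale in (0, 5], delays in [0, 20] ms
— none of these bounds are stated in the source analyses, and all are
arguments.

## The synthetic-data generators

`fixture_suite()` regenerates, deterministically from one seed, the inputs
the toolkit is designed for: OU envelopes at theta in {0.5, 1, 2} with
zeta = 1 (the decay range used throughout the validation studies), a cubic
drift `mu(x) = 2.5 - 3x + 1.05x^2 - 0.14x^3` and a fifth-degree drift
`mu(x) = 2.2 - 3x + 1.35x^2 - 0.255x^3 + 0.02x^4 - 0.0006x^5`, both
monostable with a weak-attraction "shoulder" at elevated amplitude — chosen
(coefficients are this package's own, documented here and in the manifest)
so that the burst duration profile levels off at high percentiles, the
qualitative signature that no linear drift reproduces; a Rayleigh-like
quadratic-drift envelope; linear and delayed-sigmoid Wilson–Cowan models
oscillating near 20 and 15 Hz; an AR(1) control; and band-passed 1/f noise.
ARMA controls for surrogate calibration use an AR(2) with complex poles at
20 Hz (radius 0.98), i.e. a narrowband stochastic oscillation that is linear
by construction.

What the generators emulate — band-limited stochastic oscillations whose
envelope follows a one-dimensional Langevin equation with additive noise —
is exactly the model class the analytic results cover. What they do not
emulate: measurement noise and electrode artifacts, nonstationary drift of
the spectral peak, multiplicative (state-dependent) envelope noise, and
volume-conducted mixtures. Passing tests therefore demonstrate correctness
of the machinery and recoverability under the stated model class, not
robustness to everything real recordings contain.

## Numerical choices and problem sizes

* Filtering: 4th-order zero-phase Butterworth band-pass (the band, not the
  filter, is prescribed by the analysis convention); envelope smoothing is a
  centered 5 ms moving average with reflected edges; percentiles use linear
  interpolation between order statistics (`quantile` type 7).
* Strict inequality (`env > L`) defines supra-threshold samples; runs
  touching the recording edges are kept (they bias durations down by at most
  one burst each); percentiles with no qualifying burst are `NA`, never 0.
* The 100 ms minimum burst duration applies to data analysis and model
  fitting against data; every comparison against the analytic formulas uses
  a zero minimum, because the formulas model bare threshold crossings.
* Quadratures use an adaptive rule with the infinite limit handled by the
  integrator's own transformation (absolute tolerance 1e-10 s); the fast
  percentile-mapped profile path uses a single fine grid with tail
  cumulative sums, overflow-guarded by subtracting the log-density maximum.
* Welch PSD: 1 s Hann windows, 50% overlap, one-sided, segment means
  removed; the estimator is a package convention (the source analyses do not
  name one) and the integral-equals-variance check is part of the suite.
* erfc/erfinv delegate to `pnorm`/`qnorm`.
* Divergence guards abort envelope and neural-mass simulations at |x| > 1e6.
* Seeding: every stochastic function takes a `seed`; ensembles derive
  per-realization seeds as `(seed + 1000003 i) mod (2^31 - 1)` in double
  arithmetic, and simulations restore the caller's RNG state.

Validation problem sizes (the package's own choices, stated for
reproducibility): profile-versus-formula comparisons use five repeats of
1e4 s at dt = 1 ms per decay parameter; the A0 calibration uses 3e4 s per
decay parameter; passage-method recovery uses 1000 s envelopes with five
forward repeats of five times the data duration (the default forward
protocol is ten times); the method comparison uses
ten repeats at 250/500/1000 s; minimal-model recovery uses twenty 5e3 s
targets per generator; surrogate type-I calibration uses 200 replicate
8.2 s AR(2) series with 19 surrogates each. Agreement bands (5% for OU
profiles, 7% for the cubic) refer to the maximum relative deviation across
the 20th–95th percentile grid. Where a simulated feature is compared with
training data "within 2 SEM", the band is the quadrature-combined SEM of the
two estimates (across-segment SEM of the data feature and across-repeat SEM
of the simulated feature) — with very long forward simulations the
simulation SEM alone shrinks toward zero and would fail any estimator with
a finite O(dt) bias.

## Known limitations

* All burst-duration formulas are first order in dt: residual bias is O(dt)
  and visible (about 2% at dt = 1 ms for OU parameters of order one) —
  halving dt roughly halves it.
* The passage method needs the envelope to be well sampled at its own time
  scale; applying it at the raw sampling rate of a narrowband envelope
  overestimates the roughness the formula attributes to noise.
* BDDLS inherits the usual caveats of surrogate testing: it detects
  non-linear temporal structure relative to a stationary linear null, and
  slow nonstationarity must be absorbed by the GWR coefficient pinning
  (raise `rho`) rather than interpreted as non-linearity.
* Wilson–Cowan fits are not identifiable — many parameter sets produce the
  same two features — so fitted parameters are descriptive, not estimates of
  physiological quantities.
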