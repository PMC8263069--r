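Package: burstdyn
Title: Burst Duration Profiles and Envelope Dynamics of Neural Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises transient oscillatory bursts in band-limited neural
    time series (e.g. beta-band local field potentials). Computes average burst
    duration, amplitude and rate profiles across envelope-percentile thresholds;
    tests for non-linear temporal structure with Fourier, IAAFT and gradual
    wavelet reconstruction (GWR) surrogates via the burst duration distance to
    linear surrogates (BDDLS) statistic; simulates stochastic envelope models
    (Ornstein-Uhlenbeck and polynomial drift) and stochastic Wilson-Cowan
    neural mass models with delays; evaluates closed-form and quadrature
    approximations of average burst duration for time-discretized envelope
    models, including first-order discretization corrections; fits models to
    burst duration profiles by generalized pattern search with minimal-model
    selection; and inverts burst duration profiles into envelope drift
    functions (the passage method), with a direct finite-difference comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
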