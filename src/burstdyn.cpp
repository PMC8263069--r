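#include <Rcpp.h>
using namespace Rcpp;

// Per-threshold burst statistics in one pass per threshold.
// A burst is a maximal run of samples with env > L kept if its length (in
// samples) is >= min_samples. Runs touching either end of the recording are
// kept. Burst amplitude is the maximum envelope value inside the run.
// Returns a matrix with one row per threshold:
// n_bursts, sum_dur, sum_dur2, sum_amp, sum_amp2, n_supra (durations in samples).
// [[Rcpp::export]]
NumericMatrix burst_scan_cpp(NumericVector env, NumericVector thresholds,
                             int min_samples) {
  const int n = env.size(), m = thresholds.size();
  NumericMatrix out(m, 6);
  for (int j = 0; j < m; ++j) {
    const double L = thresholds[j];
    double nb = 0, sd1 = 0, sd2 = 0, sa1 = 0, sa2 = 0, nsup = 0;
    int run = 0;
    double amp = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (env[i] > L) {
        ++run;
        ++nsup;
        if (env[i] > amp) amp = env[i];
      } else if (run > 0) {
        if (run >= min_samples) {
          nb += 1; sd1 += run; sd2 += (double)run * run;
          sa1 += amp; sa2 += amp * amp;
        }
        run = 0; amp = R_NegInf;
      }
    }
    if (run > 0 && run >= min_samples) {  // edge run at the end is kept
      nb += 1; sd1 += run; sd2 += (double)run * run;
      sa1 += amp; sa2 += amp * amp;
    }
    out(j, 0) = nb;  out(j, 1) = sd1; out(j, 2) = sd2;
    out(j, 3) = sa1; out(j, 4) = sa2; out(j, 5) = nsup;
  }
  colnames(out) = CharacterVector::create("n_bursts", "sum_dur", "sum_dur2",
                                          "sum_amp", "sum_amp2", "n_supra");
  return out;
}

// Euler-Maruyama for dx = mu(x) dt + zeta dW with polynomial drift
// mu(x) = sum_i coeffs[i] x^i, keeping |x| at each step (reflecting envelope
// positivity). Uses R's RNG. Aborts if |x| exceeds the divergence guard.
// [[Rcpp::export]]
NumericVector sim_poly_cpp(NumericVector coeffs, double zeta, double dt,
                           int n, double x0, double guard = 1e6) {
  NumericVector x(n);
  const int p = coeffs.size();
  const double s = zeta * std::sqrt(dt);
  double xi = x0;
  for (int i = 0; i < n; ++i) {
    double mu = coeffs[p - 1];
    for (int k = p - 2; k >= 0; --k) mu = mu * xi + coeffs[k];
    xi = std::fabs(xi + mu * dt + s * norm_rand());
    if (xi > guard)
      stop("envelope simulation diverged (|x| > %g) at step %d", guard, i + 1);
    x[i] = xi;
  }
  return x;
}

// Euler-Maruyama with drift tabulated on a uniform grid, clamped linear
// interpolation outside [x_min, x_max], |.| positivity at each step.
// [[Rcpp::export]]
NumericVector sim_interp_cpp(NumericVector xg, NumericVector mu, double zeta,
                             double dt, int n, double x0, double guard = 1e6) {
  const int m = xg.size();
  const double x_min = xg[0], x_max = xg[m - 1];
  const double h = (x_max - x_min) / (m - 1);
  const double s = zeta * std::sqrt(dt);
  NumericVector x(n);
  double xi = x0;
  for (int i = 0; i < n; ++i) {
    double mui;
    if (xi <= x_min) mui = mu[0];
    else if (xi >= x_max) mui = mu[m - 1];
    else {
      const double u = (xi - x_min) / h;
      const int k = (int)u;
      const double w = u - k;
      mui = mu[k] * (1.0 - w) + mu[k + 1] * w;
    }
    xi = std::fabs(xi + mui * dt + s * norm_rand());
    if (xi > guard)
      stop("envelope simulation diverged (|x| > %g) at step %d", guard, i + 1);
    x[i] = xi;
  }
  return x;
}

// Stochastic Wilson-Cowan model, Euler-Maruyama with ring-buffer delayed
// states. activation = 0 for linear f(x) = beta * x, 1 for the sigmoid
// eta / (1 + exp(-beta (x - 1))). Delays are in integer steps; history before
// t = 0 is held constant at the initial state. Returns cbind(E, I).
// [[Rcpp::export]]
NumericMatrix sim_wc_cpp(int n, double dt, double wIE, double wEI, double wII,
                         double lamE, double lamI, double OmE, double OmI,
                         double zeta, int activation, double beta, double eta,
                         int dIE, int dEI, int dII,
                         double E0, double I0, double guard = 1e6) {
  NumericMatrix out(n, 2);
  const int maxd = std::max(dIE, std::max(dEI, dII));
  const int buf = maxd + 1;
  std::vector<double> Eh(buf, E0), Ih(buf, I0);
  const double sE = zeta * std::sqrt(dt), sI = zeta * std::sqrt(dt);
  double E = E0, I = I0;
  int head = 0;  // index of the current (time i-1) state in the buffers
  for (int i = 0; i < n; ++i) {
    // delayed states (constant-history initialization handles i < delay)
    const double Id_IE = Ih[(head - std::min(dIE, i) + buf) % buf];
    const double Ed_EI = Eh[(head - std::min(dEI, i) + buf) % buf];
    const double Id_II = Ih[(head - std::min(dII, i) + buf) % buf];
    const double aE = lamE - wIE * Id_IE;
    const double aI = -lamI + wEI * Ed_EI - wII * Id_II;
    double fE, fI;
    if (activation == 0) {
      fE = beta * aE; fI = beta * aI;
    } else {
      fE = eta / (1.0 + std::exp(-beta * (aE - 1.0)));
      fI = eta / (1.0 + std::exp(-beta * (aI - 1.0)));
    }
    const double En = E + dt * (-E + fE) / OmE + sE * norm_rand();
    const double In = I + dt * (-I + fI) / OmI + sI * norm_rand();
    if (std::fabs(En) > guard || std::fabs(In) > guard)
      stop("Wilson-Cowan simulation unstable (|state| > %g) at step %d",
           guard, i + 1);
    E = En; I = In;
    head = (head + 1) % buf;
    Eh[head] = E; Ih[head] = I;
    out(i, 0) = E; out(i, 1) = I;
  }
  colnames(out) = CharacterVector::create("E", "I");
  return out;
}

// First-order difference drift estimate binned by state value:
// mean of (x[i+1]-x[i])/dt within n_bins equal-width bins of x[i].
// Returns cbind(center, mu_hat, count); empty bins carry NaN.
// [[Rcpp::export]]
NumericMatrix direct_drift_cpp(NumericVector x, double dt, int n_bins) {
  const int n = x.size();
  double lo = x[0], hi = x[0];
  for (int i = 0; i < n; ++i) { if (x[i] < lo) lo = x[i]; if (x[i] > hi) hi = x[i]; }
  const double w = (hi - lo) / n_bins;
  NumericMatrix out(n_bins, 3);
  std::vector<double> s(n_bins, 0.0), c(n_bins, 0.0);
  for (int i = 0; i + 1 < n; ++i) {
    int k = (int)((x[i] - lo) / w);
    if (k == n_bins) k = n_bins - 1;
    s[k] += (x[i + 1] - x[i]) / dt;
    c[k] += 1.0;
  }
  for (int k = 0; k < n_bins; ++k) {
    out(k, 0) = lo + (k + 0.5) * w;
    out(k, 1) = c[k] > 0 ? s[k] / c[k] : NA_REAL;
    out(k, 2) = c[k];
  }
  colnames(out) = CharacterVector::create("x", "mu_hat", "n");
  return out;
}
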