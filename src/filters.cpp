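#include <Rcpp.h>
using namespace Rcpp;

// Causal exponential filtering of a multi-channel signal, trapezoid-consistent:
// y(t) = w * int_0^t x(t') exp(-(t - t')/tau) dt', with w = 1/tau (normalized)
// or w = 1 (unnormalized).  The recursion
//   y[n] = a y[n-1] + w (dt/2) (a x[n-1] + x[n]),  a = exp(-dt/tau)
// is algebraically identical to trapezoid quadrature of the integral because the
// exponential kernel factorizes across samples.  `init` is the filter state at
// the first sample (used to carry state across renditions); zero by default.
// [[Rcpp::export(name = ".expfilt_mat")]]
NumericMatrix expfilt_mat(NumericMatrix x, double dt, double tau,
                          bool normalized, NumericVector init) {
  int m = x.nrow(), n = x.ncol();
  NumericMatrix y(m, n);
  double a = std::exp(-dt / tau);
  double w = normalized ? 1.0 / tau : 1.0;
  double b = w * dt / 2.0;
  for (int i = 0; i < m; ++i) {
    y(i, 0) = (init.size() == 1) ? init[0] : init[i];
  }
  for (int k = 1; k < n; ++k) {
    for (int i = 0; i < m; ++i) {
      y(i, k) = a * y(i, k - 1) + b * (a * x(i, k - 1) + x(i, k));
    }
  }
  return y;
}

// Exact causal exponential rate estimate from spike times:
//   r(t) = (1/tau) sum_k exp(-(t - t_k)/tau) for t >= t_k.
// Spikes between grid points are decayed exactly to the next grid point, so the
// result does not depend on binning the spikes first.
// [[Rcpp::export(name = ".rate_from_spikes")]]
NumericVector rate_from_spikes(NumericVector spikes, NumericVector times,
                               double tau) {
  int n = times.size();
  NumericVector r(n);
  double a = std::exp(-(times[1] - times[0]) / tau);
  int k = 0, nspk = spikes.size();
  // spikes at or before the first grid point
  double acc = 0.0;
  while (k < nspk && spikes[k] <= times[0]) {
    acc += std::exp(-(times[0] - spikes[k]) / tau) / tau;
    ++k;
  }
  r[0] = acc;
  for (int i = 1; i < n; ++i) {
    double v = r[i - 1] * a;
    while (k < nspk && spikes[k] <= times[i]) {
      v += std::exp(-(times[i] - spikes[k]) / tau) / tau;
      ++k;
    }
    r[i] = v;
  }
  return r;
}
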