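#include <Rcpp.h>
using namespace Rcpp;

// Closed-loop rate dynamics for one rendition: the tutor integrates the
// motor error online while the error itself depends on the tutor's
// contribution to the student activity.  Explicit time stepping:
//   E_j(t)   <- exp(-dt/tau_t) E_j(t-dt) + (1 - exp(-dt/tau_t)) eps_j(t-dt)
//   g_j(t)    = theta - k E_j(t)            (matched)
//             = theta - rho tanh(k E_j(t) / rho)  (saturating)
//   s_j(t)    = drive_j(t) + w (g_j(t) - theta)   [drive includes W c + w
//               theta - x_inh]
//   yf_j(t)  <- exp(-dt/tau_out) yf_j(t-dt) + (dt/2)(exp(-dt/tau_out)
//               s_j(t-dt) + s_j(t))        (unnormalized output filter)
//   y_a(t)    = sum_j M_aj yf_j(t);  eps_j(t) = sum_a M_aj (y_a - ybar_a)
// Returns s, g, y, eps sampled on the grid.
// [[Rcpp::export(name = ".rate_closed_loop")]]
List rate_closed_loop(NumericMatrix drive, NumericMatrix M,
                      NumericMatrix Mt, NumericMatrix target, double dt,
                      double tau_out,
                      double tau_tutor, double kgain, double w,
                      double theta, double rho, bool saturating) {
  int ns = drive.nrow(), n = drive.ncol(), nch = M.nrow();
  NumericMatrix s(ns, n), g(ns, n), y(nch, n), eps(ns, n);
  std::vector<double> E(ns, 0.0), yf(ns, 0.0), s_prev(ns, 0.0);
  double at = std::exp(-dt / tau_tutor);
  double ao = std::exp(-dt / tau_out);

  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < ns; ++j) {
      if (t > 0) E[j] = at * E[j] + (1.0 - at) * eps(j, t - 1);
      double gj;
      if (saturating) {
        gj = theta - rho * std::tanh(kgain * E[j] / rho);
      } else {
        gj = theta - kgain * E[j];
      }
      g(j, t) = gj;
      double sj = drive(j, t) + w * (gj - theta);
      s(j, t) = sj;
      yf[j] = (t == 0) ? 0.0 : ao * yf[j] + 0.5 * dt * (ao * s_prev[j] + sj);
      s_prev[j] = sj;
    }
    for (int a = 0; a < nch; ++a) {
      double acc = 0.0;
      for (int j = 0; j < ns; ++j) acc += M(a, j) * yf[j];
      y(a, t) = acc;
    }
    // the tutor's error uses its own (possibly scrambled) map Mt
    for (int j = 0; j < ns; ++j) {
      double acc = 0.0;
      for (int a = 0; a < nch; ++a) {
        acc += Mt(a, j) * (y(a, t) - target(a, t));
      }
      eps(j, t) = acc;
    }
  }
  return List::create(_["s"] = s, _["g"] = g, _["y"] = y, _["eps"] = eps);
}
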