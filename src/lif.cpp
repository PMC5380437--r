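#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire student network with current-based AMPA/NMDA
// synapses, voltage-dependent NMDA gating, and global activity-dependent
// inhibition.  Per step (length dt, from t to t+dt):
//   1. input spikes with times in [t, t+dt) are applied: a conductor spike at
//      neuron i increments I_AMPA_j by W(i,j) for every student j; a tutor
//      spike for student j increments I_AMPA_j by (1-r) w_tutor and I_NMDA_j
//      by r w_tutor G(V_j);
//   2. synaptic currents and inhibition traces decay exponentially;
//   3. the membrane relaxes toward V_inf = V_R + R I - V_inh with the exact
//      exponential for inputs held constant over the step (exponential Euler);
//      during the refractory period V is clamped at V_R;
//   4. threshold crossings emit a spike at t+dt, reset V to V_R, start the
//      refractory clock and increment the inhibition trace S_j.
// Units: potentials mV, currents pA, resistance MOhm (1 MOhm * 1 pA = 1e-3 mV),
// times s.
// [[Rcpp::export(name = ".lif_simulate")]]
List lif_simulate(int n_steps, double dt,
                  NumericVector cond_t, IntegerVector cond_id,
                  NumericVector tut_t, IntegerVector tut_id,
                  NumericMatrix W,
                  List params, NumericVector i_ext, bool record_v) {
  int ns = W.ncol();
  int nc = W.nrow();
  double vr = params["v_reset"], vth = params["v_thresh"];
  double tau_m = params["tau_m"], tau_ref = params["tau_ref"];
  double r_in = params["r_in"];
  double tau_ampa = params["tau_ampa"], tau_nmda = params["tau_nmda"];
  double frac_nmda = params["frac_nmda"], w_tutor = params["w_tutor"];
  double g_inh = params["g_inh"], tau_inh = params["tau_inh"];
  double mg = params["mg"];

  const double mv_per_mohm_pa = 1e-3;
  double da = std::exp(-dt / tau_ampa);
  double dn = std::exp(-dt / tau_nmda);
  double ds = std::exp(-dt / tau_inh);
  double dm = std::exp(-dt / tau_m);

  std::vector<double> V(ns, vr), Ia(ns, 0.0), In(ns, 0.0), S(ns, 0.0);
  std::vector<double> refrac(ns, 0.0);
  std::vector<double> spk_t;
  std::vector<int> spk_id;
  NumericMatrix vtrace;
  if (record_v) vtrace = NumericMatrix(ns, n_steps);

  int kc = 0, nkc = cond_t.size();
  int kt = 0, nkt = tut_t.size();

  for (int step = 0; step < n_steps; ++step) {
    double t0 = step * dt, t1 = (step + 1) * dt;
    // 1. apply input spikes in [t0, t1)
    while (kc < nkc && cond_t[kc] < t1) {
      if (cond_t[kc] >= t0) {
        int i = cond_id[kc];
        for (int j = 0; j < ns; ++j) Ia[j] += W(i, j);
      }
      ++kc;
    }
    while (kt < nkt && tut_t[kt] < t1) {
      if (tut_t[kt] >= t0) {
        int j = tut_id[kt];
        double g = 1.0 / (1.0 + (mg / 3.57) * std::exp(-V[j] / 16.13));
        Ia[j] += (1.0 - frac_nmda) * w_tutor;
        In[j] += frac_nmda * w_tutor * g;
      }
      ++kt;
    }
    // 2. decay currents and inhibition
    double ssum = 0.0;
    for (int j = 0; j < ns; ++j) {
      Ia[j] *= da;
      In[j] *= dn;
      S[j] *= ds;
      ssum += S[j];
    }
    double v_inh = (g_inh / ns) * ssum;
    // 3. membrane update
    for (int j = 0; j < ns; ++j) {
      if (refrac[j] > 0.0) {
        refrac[j] -= dt;
        V[j] = vr;
      } else {
        double vinf = vr + r_in * (Ia[j] + In[j] + i_ext[j]) * mv_per_mohm_pa
          - v_inh;
        V[j] = vinf + (V[j] - vinf) * dm;
      }
      if (!std::isfinite(V[j])) {
        stop("simulation failure: non-finite membrane potential at t = %f s",
             t1);
      }
    }
    // 4. threshold test
    for (int j = 0; j < ns; ++j) {
      if (refrac[j] <= 0.0 && V[j] > vth) {
        spk_t.push_back(t1);
        spk_id.push_back(j + 1);
        V[j] = vr;
        refrac[j] = tau_ref;
        S[j] += 1.0;
      }
      if (record_v) vtrace(j, step) = V[j];
    }
  }

  List out = List::create(_["time"] = wrap(spk_t), _["neuron"] = wrap(spk_id));
  if (record_v) out["v"] = vtrace;
  return out;
}
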