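#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the all-to-all coupled dimensional network
//
//   C V_i' = k (V_i - V_R)(V_i - V_T) - W_i + I_app,i + g_syn,i s (E_r - V_i)
//   W_i'   = (eta_i (V_i - V_R) - W_i) / tau_W,i
//   s'     = -s / tau_syn   (+ s_jump/N at each presynaptic spike)
//
// The spike test runs after each full step: every neuron with V >= V_peak is
// reset, its adaptation incremented, and the shared gating variable s is
// incremented once per spike in the same step (simultaneous spikes all
// count). Time is in ms.
//
// [[Rcpp::export]]
List simulate_izh_network_cpp(NumericVector I_app, NumericVector g_syn,
                              NumericVector W_jump, NumericVector tau_W,
                              NumericVector eta,
                              double C, double k, double V_R, double V_T,
                              double V_peak, double V_reset, double E_r,
                              double tau_syn, double s_jump,
                              double dt, int n_steps, int trace_every,
                              NumericVector v0, NumericVector w0, double s0) {
  const int N = I_app.size();
  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> W(w0.begin(), w0.end());
  double s = s0;

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  const int n_tr = n_steps / trace_every + 1;
  NumericVector tr_time(n_tr), tr_V(n_tr), tr_W(n_tr), tr_s(n_tr);
  int tr = 0;

  double Vbar = 0.0, Wbar = 0.0;
  for (int i = 0; i < N; ++i) { Vbar += V[i]; Wbar += W[i]; }
  tr_time[tr] = 0.0; tr_V[tr] = Vbar / N; tr_W[tr] = Wbar / N; tr_s[tr] = s;
  ++tr;

  const double inv_C = 1.0 / C;
  for (int n = 0; n < n_steps; ++n) {
    const double s_now = s;
    int n_spikes = 0;
    for (int i = 0; i < N; ++i) {
      const double v = V[i];
      const double dV = (k * (v - V_R) * (v - V_T) - W[i] + I_app[i] +
                         g_syn[i] * s_now * (E_r - v)) * inv_C;
      const double dW = (eta[i] * (v - V_R) - W[i]) / tau_W[i];
      V[i] = v + dt * dV;
      W[i] += dt * dW;
      if (!std::isfinite(V[i]))
        stop("integration failure: neuron %d overflowed at t = %.3f ms "
             "(dt too large?)", i + 1, (n + 1) * dt);
      if (V[i] >= V_peak) {
        spike_id.push_back(i + 1);
        spike_t.push_back((n + 1) * dt);
        V[i] = V_reset;
        W[i] += W_jump[i];
        ++n_spikes;
      }
    }
    s += dt * (-s / tau_syn) + s_jump * (double)n_spikes / (double)N;

    if ((n + 1) % trace_every == 0) {
      Vbar = 0.0; Wbar = 0.0;
      for (int i = 0; i < N; ++i) { Vbar += V[i]; Wbar += W[i]; }
      tr_time[tr] = (n + 1) * dt;
      tr_V[tr] = Vbar / N; tr_W[tr] = Wbar / N; tr_s[tr] = s;
      ++tr;
    }
  }

  return List::create(
    _["spike_id"] = wrap(spike_id),
    _["spike_t"]  = wrap(spike_t),
    _["trace"] = DataFrame::create(
      _["time"] = tr_time[Range(0, tr - 1)],
      _["V_mean"] = tr_V[Range(0, tr - 1)],
      _["W_mean"] = tr_W[Range(0, tr - 1)],
      _["s"] = tr_s[Range(0, tr - 1)]),
    _["V_final"] = wrap(V), _["W_final"] = wrap(W), _["s_final"] = s);
}
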