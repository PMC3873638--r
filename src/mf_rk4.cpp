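#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 for the quasi-steady mean-field systems with the
// voltage-coupled adaptation term off (b = 0), the configuration used in
// every shipped analysis. Fixed stepping is deliberate: the vector field
// has square-root switching kinks at every grid node's firing onset, and
// adaptive error control rejects its way across each one.
//
// State layout: conditioned = false -> (w, s) with the rate integrated
// over the node grid (MFI when M = 1, MFII otherwise); conditioned = true
// -> (w_1..w_M, s), one adaptation equation per node (MFIII).
// sign = -1 integrates the time-reversed flow.

static inline void mf_deriv(const std::vector<double>& y,
                            std::vector<double>& dy,
                            const double* I, const double* g,
                            const double* wj, const double* a,
                            const double* w8, int M,
                            double alpha, double vp, double vr, double er,
                            double tau_s, double sj, bool conditioned,
                            int sign) {
  const double s = y[conditioned ? M : 1];
  double Rbar = 0.0, wjRbar = 0.0, abar = 0.0;
  if (conditioned) {
    for (int j = 0; j < M; ++j) {
      const double cc = 0.5 * (alpha + g[j] * s);
      const double H = I[j] - y[j] - cc * cc + g[j] * er * s;
      double R = 0.0;
      if (H > 0) {
        const double sH = std::sqrt(H);
        R = sH / (std::atan((vp - cc) / sH) - std::atan((vr - cc) / sH));
      }
      Rbar += w8[j] * R;
      dy[j] = sign * (wj[j] * R - a[j] * y[j]);
    }
    dy[M] = sign * (-s / tau_s + sj * Rbar);
  } else {
    const double w = y[0];
    for (int j = 0; j < M; ++j) {
      const double cc = 0.5 * (alpha + g[j] * s);
      const double H = I[j] - w - cc * cc + g[j] * er * s;
      double R = 0.0;
      if (H > 0) {
        const double sH = std::sqrt(H);
        R = sH / (std::atan((vp - cc) / sH) - std::atan((vr - cc) / sH));
      }
      Rbar += w8[j] * R;
      wjRbar += w8[j] * wj[j] * R;
      abar += w8[j] * a[j];
    }
    dy[0] = sign * (wjRbar - abar * w);
    dy[1] = sign * (-s / tau_s + sj * Rbar);
  }
}

// [[Rcpp::export]]
List mf_rk4_cpp(NumericVector y0, double h, int n_steps, int thin, int sign,
                NumericVector I, NumericVector g, NumericVector wj,
                NumericVector a, NumericVector w8,
                double alpha, double vp, double vr, double er,
                double tau_s, double sj, bool conditioned, double bound) {
  const int M = I.size();
  const int nd = y0.size();
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(nd), k2(nd), k3(nd), k4(nd), yt(nd);

  const int n_out = n_steps / thin + 1;
  NumericMatrix out(n_out, nd + 1);
  int row = 0;
  out(row, 0) = 0.0;
  for (int i = 0; i < nd; ++i) out(row, i + 1) = y[i];
  ++row;
  bool diverged = false;

  for (int n = 0; n < n_steps && !diverged; ++n) {
    mf_deriv(y, k1, I.begin(), g.begin(), wj.begin(), a.begin(), w8.begin(),
             M, alpha, vp, vr, er, tau_s, sj, conditioned, sign);
    for (int i = 0; i < nd; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
    mf_deriv(yt, k2, I.begin(), g.begin(), wj.begin(), a.begin(), w8.begin(),
             M, alpha, vp, vr, er, tau_s, sj, conditioned, sign);
    for (int i = 0; i < nd; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
    mf_deriv(yt, k3, I.begin(), g.begin(), wj.begin(), a.begin(), w8.begin(),
             M, alpha, vp, vr, er, tau_s, sj, conditioned, sign);
    for (int i = 0; i < nd; ++i) yt[i] = y[i] + h * k3[i];
    mf_deriv(yt, k4, I.begin(), g.begin(), wj.begin(), a.begin(), w8.begin(),
             M, alpha, vp, vr, er, tau_s, sj, conditioned, sign);
    for (int i = 0; i < nd; ++i) {
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i]) || std::fabs(y[i]) > bound) diverged = true;
    }
    if (!diverged && (n + 1) % thin == 0) {
      out(row, 0) = (n + 1) * h;
      for (int i = 0; i < nd; ++i) out(row, i + 1) = y[i];
      ++row;
    }
  }
  if (row < n_out) out = out(Range(0, std::max(row - 1, 0)), _);
  return List::create(_["out"] = out, _["diverged"] = diverged);
}
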