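// Forward-Euler cardiac cell / 1-D cable engine with a two-isoform Markov
// IKr component. The membrane model is the package's minimal ventricular
// surrogate: fast inward current (m^3 h), slowly inactivating plateau
// inward current, instantaneous inward-rectifier background K current, and
// the Markov IKr mixture. Voltage uses forward Euler with a coarse/fine
// time-step switch; gates use exact exponential (Rush-Larsen) updates;
// Markov states use RK4 at frozen voltage within each step (operator
// splitting). All voltage-dependent rates and gate targets are tabulated
// over a fine voltage grid and linearly interpolated.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct MarkovSpec {
  int ntr;
  std::vector<int> from, to;
  std::vector<double> alpha, beta; // effective (corrections folded in)
};

struct RateTable {
  double vmin, dv;
  int nv, ncol;
  std::vector<double> tab; // column-major: tab[c * nv + iv]
  inline double at(int c, double V, int iv, double frac) const {
    const double *col = &tab[(size_t)c * nv];
    return col[iv] + frac * (col[iv + 1] - col[iv]);
  }
};

inline double sig(double V, double v0, double k) {
  return 1.0 / (1.0 + std::exp((V - v0) / k));
}

// columns: [0..ntrA) isoform-a rates, [ntrA..ntrA+ntrB) isoform-b rates,
// then m_inf, h_inf, w_inf, s_inf, k1_inf, x_inf
RateTable build_table(const MarkovSpec &A, const MarkovSpec &B,
                      const NumericVector &sp,
                      double vmin, double vmax, double dv) {
  RateTable T;
  T.vmin = vmin; T.dv = dv;
  T.nv = (int)std::ceil((vmax - vmin) / dv) + 2;
  T.ncol = A.ntr + B.ntr + 6;
  T.tab.resize((size_t)T.ncol * T.nv);
  for (int iv = 0; iv < T.nv; ++iv) {
    double V = vmin + iv * dv;
    int c = 0;
    for (int k = 0; k < A.ntr; ++k, ++c)
      T.tab[(size_t)c * T.nv + iv] = A.alpha[k] * std::exp(A.beta[k] * V);
    for (int k = 0; k < B.ntr; ++k, ++c)
      T.tab[(size_t)c * T.nv + iv] = B.alpha[k] * std::exp(B.beta[k] * V);
    T.tab[(size_t)(c + 0) * T.nv + iv] = sig(V, sp["m_v0"], -sp["m_k"]);
    T.tab[(size_t)(c + 1) * T.nv + iv] = sig(V, sp["h_v0"], sp["h_k"]);
    T.tab[(size_t)(c + 2) * T.nv + iv] = sig(V, sp["w_v0"], sp["w_k"]);
    T.tab[(size_t)(c + 3) * T.nv + iv] = sig(V, sp["s_v0"], -sp["s_k"]);
    T.tab[(size_t)(c + 4) * T.nv + iv] = sig(V, sp["k1_v0"], sp["k1_k"]);
    T.tab[(size_t)(c + 5) * T.nv + iv] = sig(V, sp["x_v0"], -sp["x_k"]);
  }
  return T;
}

// RK4 advance of a 5-state Markov vector with fixed rates
inline void markov_deriv(const MarkovSpec &M, const double *r,
                         const double *p, double *dp) {
  for (int i = 0; i < 5; ++i) dp[i] = 0.0;
  for (int k = 0; k < M.ntr; ++k) {
    double flux = r[k] * p[M.from[k]];
    dp[M.from[k]] -= flux;
    dp[M.to[k]] += flux;
  }
}

inline void markov_rk4(const MarkovSpec &M, const double *r, double *p,
                       double dt) {
  double k1[5], k2[5], k3[5], k4[5], tmp[5];
  markov_deriv(M, r, p, k1);
  for (int i = 0; i < 5; ++i) tmp[i] = p[i] + 0.5 * dt * k1[i];
  markov_deriv(M, r, tmp, k2);
  for (int i = 0; i < 5; ++i) tmp[i] = p[i] + 0.5 * dt * k2[i];
  markov_deriv(M, r, tmp, k3);
  for (int i = 0; i < 5; ++i) tmp[i] = p[i] + dt * k3[i];
  markov_deriv(M, r, tmp, k4);
  for (int i = 0; i < 5; ++i)
    p[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

MarkovSpec as_spec(const NumericMatrix &tr) {
  MarkovSpec M;
  M.ntr = tr.nrow();
  M.from.resize(M.ntr); M.to.resize(M.ntr);
  M.alpha.resize(M.ntr); M.beta.resize(M.ntr);
  for (int k = 0; k < M.ntr; ++k) {
    M.from[k] = (int)tr(k, 0);
    M.to[k] = (int)tr(k, 1);
    M.alpha[k] = tr(k, 2);
    M.beta[k] = tr(k, 3);
    if (M.from[k] < 0 || M.from[k] > 4 || M.to[k] < 0 || M.to[k] > 4)
      stop("markov state index out of range");
  }
  return M;
}

} // namespace

// [[Rcpp::export]]
List sim_engine(NumericMatrix trans_a, NumericMatrix trans_b,
                NumericVector p0a, NumericVector p0b, double fraction_b,
                NumericVector surrogate,
                int n_cells, double D, double dx,
                double BCL, int n_beats,
                double dt_coarse, double dt_fine, double dvdt_switch,
                double stim_amp, double stim_dur, int n_stim_cells,
                double record_dt, bool record_all_beats,
                double gKr, double EK, double V0,
                int open_index) {
  if (n_cells < 1 || n_beats < 1) stop("sim_engine: bad sizes");
  if (dt_fine > dt_coarse) stop("sim_engine: dt_fine must be <= dt_coarse");
  if (D > 0.0 && n_cells > 1) {
    double dt_cfl = dx * dx / (2.0 * D);
    if (dt_coarse > dt_cfl)
      stop("sim_engine: diffusion unstable at dt_coarse = %f ms; use dt <= %f ms",
           dt_coarse, dt_cfl);
  }
  MarkovSpec A = as_spec(trans_a), B = as_spec(trans_b);
  RateTable T = build_table(A, B, surrogate, -210.0, 210.0, 0.005);
  const int colA = 0, colB = A.ntr, colG = A.ntr + B.ntr;

  const double g_fast = surrogate["g_fast"], E_fast = surrogate["E_fast"];
  const double tau_m = surrogate["tau_m"], tau_h = surrogate["tau_h"];
  const double g_plat = surrogate["g_plat"], E_plat = surrogate["E_plat"];
  const double tau_w = surrogate["tau_w"];
  const double g_k1 = surrogate["g_k1"], g_so = surrogate["g_so"];
  const double fa = 1.0 - fraction_b, fb = fraction_b;

  // state arrays
  std::vector<double> V(n_cells, V0), m(n_cells), h(n_cells), w(n_cells);
  std::vector<double> pa(5 * n_cells), pb(5 * n_cells);
  std::vector<double> dVdt(n_cells, 0.0), lastdV(n_cells, 0.0);
  {
    // gates at their targets for V0
    int iv = (int)((V0 - T.vmin) / T.dv);
    double frac = (V0 - (T.vmin + iv * T.dv)) / T.dv;
    for (int c = 0; c < n_cells; ++c) {
      m[c] = T.at(colG + 0, V0, iv, frac);
      h[c] = T.at(colG + 1, V0, iv, frac);
      w[c] = T.at(colG + 2, V0, iv, frac);
      for (int i = 0; i < 5; ++i) { pa[5 * c + i] = p0a[i]; pb[5 * c + i] = p0b[i]; }
    }
  }

  const double t_end = (double)n_beats * BCL;
  const double t_rec0 = record_all_beats ? 0.0 : (double)(n_beats - 1) * BCL;
  const int n_rec_max = (int)std::floor((t_end - t_rec0) / record_dt) + 2;
  NumericVector rec_t(n_rec_max);
  NumericMatrix rec_V(n_cells, n_rec_max);
  NumericVector rec_ikr(n_rec_max);
  NumericMatrix rec_occa(5, n_rec_max), rec_occb(5, n_rec_max);
  int n_rec = 0;
  double next_rec = t_rec0;

  std::vector<double> ra(A.ntr), rb(B.ntr), lap(n_cells, 0.0);
  double t = 0.0;
  long iter = 0;
  while (t < t_end - 1e-12) {
    double tb = t - BCL * std::floor(t / BCL);
    bool stim_on = tb < stim_dur;
    // step-size rule: fine during stimulus or fast voltage change
    double maxdv = 0.0;
    for (int c = 0; c < n_cells; ++c)
      if (std::fabs(lastdV[c]) > maxdv) maxdv = std::fabs(lastdV[c]);
    double dt = dt_coarse;
    if (dvdt_switch > 0.0 && (stim_on || maxdv > dvdt_switch)) dt = dt_fine;
    // do not step across a stimulus onset/offset or the end
    double t_next_edge = stim_on ? (t - tb + stim_dur)
                                 : (t - tb + BCL);
    if (t + dt > t_next_edge) dt = t_next_edge - t;
    if (t + dt > t_end) dt = t_end - t;
    if (dt <= 0.0) { t = t_next_edge; continue; }

    const double em = 1.0 - std::exp(-dt / tau_m);
    const double eh = 1.0 - std::exp(-dt / tau_h);
    const double ew = 1.0 - std::exp(-dt / tau_w);

    if (n_cells > 1 && D > 0.0) {
      lap[0] = (V[1] - V[0]) / (dx * dx);
      lap[n_cells - 1] = (V[n_cells - 2] - V[n_cells - 1]) / (dx * dx);
      for (int c = 1; c < n_cells - 1; ++c)
        lap[c] = (V[c - 1] - 2.0 * V[c] + V[c + 1]) / (dx * dx);
    }

    for (int c = 0; c < n_cells; ++c) {
      double Vc = V[c];
      if (std::fabs(Vc) > 200.0)
        stop("sim_engine: |V| = %f mV > 200 mV at t = %f ms, cell %d (numerical instability)",
             Vc, t, c + 1);
      int iv = (int)((Vc - T.vmin) / T.dv);
      double frac = (Vc - (T.vmin + iv * T.dv)) / T.dv;

      // Markov IKr states (operator splitting at frozen V)
      for (int k = 0; k < A.ntr; ++k) ra[k] = T.at(colA + k, Vc, iv, frac);
      for (int k = 0; k < B.ntr; ++k) rb[k] = T.at(colB + k, Vc, iv, frac);
      markov_rk4(A, ra.data(), &pa[5 * c], dt);
      markov_rk4(B, rb.data(), &pb[5 * c], dt);

      // gates (exact relaxation, constant tau)
      m[c] += (T.at(colG + 0, Vc, iv, frac) - m[c]) * em;
      h[c] += (T.at(colG + 1, Vc, iv, frac) - h[c]) * eh;
      w[c] += (T.at(colG + 2, Vc, iv, frac) - w[c]) * ew;

      double s_inf = T.at(colG + 3, Vc, iv, frac);
      double k1_inf = T.at(colG + 4, Vc, iv, frac);
      double x_inf = T.at(colG + 5, Vc, iv, frac);
      double i_fast = g_fast * m[c] * m[c] * m[c] * h[c] * (Vc - E_fast);
      double i_plat = g_plat * w[c] * s_inf * (Vc - E_plat);
      double i_k1 = g_k1 * k1_inf * (Vc - EK);
      double i_so = g_so * x_inf * (Vc - EK);
      double pO = fa * pa[5 * c + open_index] + fb * pb[5 * c + open_index];
      double i_kr = gKr * pO * (Vc - EK);
      double i_ion = i_fast + i_plat + i_k1 + i_so + i_kr;
      double stim = (stim_on && c < n_stim_cells) ? stim_amp : 0.0;
      dVdt[c] = (n_cells > 1 ? D * lap[c] : 0.0) - i_ion + stim;
      if (c == 0) rec_ikr[n_rec] = i_kr; // value for the *current* sample
    }
    // probability-conservation audit
    if ((iter++ & 0x3FF) == 0) {
      double sa = 0, sb = 0;
      for (int i = 0; i < 5; ++i) { sa += pa[i]; sb += pb[i]; }
      if (std::fabs(sa - 1.0) > 1e-6 || std::fabs(sb - 1.0) > 1e-6)
        stop("sim_engine: Markov probability leak (%g, %g) at t = %f ms",
             sa - 1.0, sb - 1.0, t);
    }
    // record on the exact grid: V interpolated within the step so that
    // different step sizes sample identical times
    if (t + dt >= next_rec - 1e-9 && n_rec < n_rec_max) {
      double frac_t = (next_rec - t) / dt;
      if (frac_t < 0.0) frac_t = 0.0;
      if (frac_t > 1.0) frac_t = 1.0;
      rec_t[n_rec] = next_rec;
      for (int c = 0; c < n_cells; ++c)
        rec_V(c, n_rec) = V[c] + frac_t * dt * dVdt[c];
      for (int i = 0; i < 5; ++i) {
        rec_occa(i, n_rec) = pa[i];
        rec_occb(i, n_rec) = pb[i];
      }
      ++n_rec;
      next_rec += record_dt;
    }
    for (int c = 0; c < n_cells; ++c) V[c] += dt * dVdt[c];
    for (int c = 0; c < n_cells; ++c) lastdV[c] = dVdt[c];
    t += dt;
  }

  return List::create(
    _["time"] = rec_t[Range(0, n_rec - 1)],
    _["V"] = rec_V(Range(0, n_cells - 1), Range(0, n_rec - 1)),
    _["ikr"] = rec_ikr[Range(0, n_rec - 1)],
    _["occ_a"] = rec_occa(Range(0, 4), Range(0, n_rec - 1)),
    _["occ_b"] = rec_occb(Range(0, 4), Range(0, n_rec - 1)));
}
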