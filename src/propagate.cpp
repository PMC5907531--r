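#include <Rcpp.h>
using namespace Rcpp;

// Repeated application of a one-step transition matrix E = expm(Q*dt):
// returns the n x (nsteps+1) matrix of state vectors including p0.
// [[Rcpp::export]]
NumericMatrix iterate_states(NumericMatrix E, NumericVector p0, int nsteps) {
  const int n = p0.size();
  if (E.nrow() != n || E.ncol() != n) stop("iterate_states: dimension mismatch");
  NumericMatrix out(n, nsteps + 1);
  std::vector<double> p(p0.begin(), p0.end()), q(n);
  for (int i = 0; i < n; ++i) out(i, 0) = p[i];
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += E(i, j) * p[j];
      q[i] = acc;
    }
    p = q;
    for (int i = 0; i < n; ++i) out(i, s) = p[i];
  }
  return out;
}

// RK4 advance of a state vector over nsteps of size dt with rates
// alpha*exp(beta*V) taken from a transition table (from,to,alpha,beta;
// 0-based states). This is the same stepping kernel the cell/fiber engine
// applies at frozen voltage within each time step.
// [[Rcpp::export]]
NumericVector markov_advance(NumericMatrix trans, NumericVector p0,
                             double V, double dt, int nsteps) {
  const int n = p0.size();
  const int ntr = trans.nrow();
  std::vector<double> r(ntr);
  std::vector<int> from(ntr), to(ntr);
  for (int k = 0; k < ntr; ++k) {
    from[k] = (int)trans(k, 0);
    to[k] = (int)trans(k, 1);
    if (from[k] < 0 || from[k] >= n || to[k] < 0 || to[k] >= n)
      stop("markov_advance: state index out of range");
    r[k] = trans(k, 2) * std::exp(trans(k, 3) * V);
  }
  std::vector<double> p(p0.begin(), p0.end());
  auto deriv = [&](const std::vector<double> &q, std::vector<double> &dq) {
    std::fill(dq.begin(), dq.end(), 0.0);
    for (int k = 0; k < ntr; ++k) {
      double flux = r[k] * q[from[k]];
      dq[from[k]] -= flux;
      dq[to[k]] += flux;
    }
  };
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int s = 0; s < nsteps; ++s) {
    deriv(p, k1);
    for (int i = 0; i < n; ++i) tmp[i] = p[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i < n; ++i) tmp[i] = p[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i < n; ++i) tmp[i] = p[i] + dt * k3[i];
    deriv(tmp, k4);
    for (int i = 0; i < n; ++i)
      p[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
  return NumericVector(p.begin(), p.end());
}

// Fine-step explicit-Euler integration of dp/dt = Q p over [0, duration],
// recording the state at the requested checkpoint times (each rounded to
// the nearest Euler step). Serves as the brute-force ODE oracle against
// the matrix-exponential path.
// [[Rcpp::export]]
NumericMatrix euler_states(NumericMatrix Q, NumericVector p0, double duration,
                           double dt, NumericVector times) {
  const int n = p0.size();
  if (Q.nrow() != n || Q.ncol() != n) stop("euler_states: dimension mismatch");
  const long nsteps = (long)std::llround(duration / dt);
  const int nt = times.size();
  std::vector<long> rec(nt);
  for (int t = 0; t < nt; ++t) {
    rec[t] = (long)std::llround(times[t] / dt);
    if (rec[t] < 0 || rec[t] > nsteps) stop("euler_states: checkpoint outside segment");
  }
  NumericMatrix out(n, nt);
  std::vector<double> p(p0.begin(), p0.end()), dp(n);
  int next = 0;
  for (long s = 0; s <= nsteps; ++s) {
    while (next < nt && rec[next] == s) {
      for (int i = 0; i < n; ++i) out(i, next) = p[i];
      ++next;
    }
    if (s == nsteps) break;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += Q(i, j) * p[j];
      dp[i] = acc;
    }
    for (int i = 0; i < n; ++i) p[i] += dt * dp[i];
  }
  return out;
}
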