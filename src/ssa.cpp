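#include <Rcpp.h>
using namespace Rcpp;

// Direct Gillespie simulation of the activity Markov chain on
// {0, 1/N, ..., 1}^P with balance-seeking jump rates
//   up_k   = N F'(F^{-1}(x_k)) (s_k - F^{-1}(x_k))_+
//   down_k = N F'(F^{-1}(x_k)) (s_k - F^{-1}(x_k))_-
// where s = W x is the synaptic input (variant 0), or with the classical
// activity-based rates up_k = N F(s_k), down_k = N x_k (variant 1).
// Rates at saturated coordinates are 0 (the interior is invariant for
// N >= N0, so these guards fire only in stress tests).
//
// The input vector s is updated incrementally per jump (s += +-1/N W[,k]),
// so each step costs O(P).  States are recorded at eval_times (value held
// just before the first jump after each time), together with the
// compensator integral (for the martingale decomposition) and the bracket
// integral (predictable quadratic variation), both exact between jumps.
//
// Uses R's RNG (unif_rand / exp_rand) so that set.seed() in R controls
// reproducibility.

static inline double flogis(double u, double gamma, double kappa) {
  return 1.0 / (1.0 + std::exp(-gamma * (u - kappa)));
}

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(NumericVector x0, int N, NumericMatrix W,
              double gamma, double kappa, double T,
              NumericVector eval_times, int variant,
              bool record_path, int max_jumps) {
  const int P = x0.size();
  const int nT = eval_times.size();
  NumericVector x = clone(x0);
  std::vector<double> s(P);
  for (int i = 0; i < P; ++i) {
    double acc = 0.0;
    for (int j = 0; j < P; ++j) acc += W(i, j) * x[j];
    s[i] = acc;
  }
  std::vector<double> up(P), down(P);
  NumericMatrix states(nT, P);
  NumericMatrix drift_int(nT, P);   // \int_0^t Q pi_k (X_s) ds
  NumericMatrix bracket(nT, P);     // <M_k>_t
  std::vector<double> cum_drift(P, 0.0), cum_brk(P, 0.0);
  std::vector<double> jt; std::vector<int> jc, jd;

  double t = 0.0;
  int it_next = 0, njump = 0;
  const double invN = 1.0 / N;
  bool overflow = false;

  while (true) {
    double total = 0.0;
    for (int k = 0; k < P; ++k) {
      double u_, d_;
      if (x[k] <= 0.0 || x[k] >= 1.0) { u_ = 0.0; d_ = 0.0; }
      else if (variant == 0) {
        double Finv = kappa + std::log(x[k] / (1.0 - x[k])) / gamma;
        double fp = gamma * x[k] * (1.0 - x[k]);   // F'(F^{-1}(x)) closed form
        double diff = s[k] - Finv;
        u_ = diff > 0 ? N * fp * diff : 0.0;
        d_ = diff < 0 ? -N * fp * diff : 0.0;
      } else {
        u_ = N * flogis(s[k], gamma, kappa);
        d_ = N * x[k];
      }
      if (x[k] >= 1.0) u_ = 0.0;
      if (x[k] <= 0.0) d_ = 0.0;
      up[k] = u_; down[k] = d_;
      total += u_ + d_;
    }
    double dt = (total > 0.0) ? exp_rand() / total : R_PosInf;
    double t_jump = t + dt;
    // record eval times passed before this jump
    while (it_next < nT && eval_times[it_next] < t_jump &&
           eval_times[it_next] <= T) {
      double tau = eval_times[it_next] - t;
      for (int k = 0; k < P; ++k) {
        states(it_next, k) = x[k];
        drift_int(it_next, k) = cum_drift[k] + tau * (up[k] - down[k]) * invN;
        bracket(it_next, k) = cum_brk[k] + tau * (up[k] + down[k]) * invN * invN;
      }
      ++it_next;
    }
    if (it_next >= nT || t_jump > T) break;
    // advance integrals to the jump time
    for (int k = 0; k < P; ++k) {
      cum_drift[k] += dt * (up[k] - down[k]) * invN;
      cum_brk[k] += dt * (up[k] + down[k]) * invN * invN;
    }
    t = t_jump;
    // categorical choice among 2P rates
    double r = unif_rand() * total, acc = 0.0;
    int kk = -1, dir = 0;
    for (int k = 0; k < P; ++k) {
      acc += up[k];
      if (r < acc) { kk = k; dir = +1; break; }
      acc += down[k];
      if (r < acc) { kk = k; dir = -1; break; }
    }
    if (kk < 0) { kk = P - 1; dir = down[kk] > 0 ? -1 : +1; }
    x[kk] += dir * invN;
    for (int i = 0; i < P; ++i) s[i] += dir * invN * W(i, kk);
    if (record_path) {
      jt.push_back(t); jc.push_back(kk + 1); jd.push_back(dir);
    }
    if (++njump >= max_jumps) { overflow = true; break; }
  }
  List path = R_NilValue;
  if (record_path)
    path = List::create(_["time"] = wrap(jt), _["coord"] = wrap(jc),
                        _["dir"] = wrap(jd));
  return List::create(_["states"] = states, _["drift_int"] = drift_int,
                      _["bracket"] = bracket, _["n_jumps"] = njump,
                      _["overflow"] = overflow, _["path"] = path);
}
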