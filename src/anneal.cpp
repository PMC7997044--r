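// Simulated-annealing minimization of the penalized group-model objective
//   H_lambda(s | C) = E(s | C) + lambda * K(s)
// over partitions s of the N sites, by single-site Metropolis-Hastings moves
// with incremental (n_k, c_k) bookkeeping.  Randomness comes from R's RNG so
// set.seed() gives bit-identical trajectories.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct GroupState {
  const NumericMatrix &C;   // evidence matrix: unit diagonal, banded zeros
  int N;
  std::vector<int> lab;     // 0-based domain index per site
  std::vector<double> n;    // domain sizes
  std::vector<double> c;    // intra-domain correlation sums (incl. diagonal)
  double nlogn;             // sum_k n_k log n_k  (for K(s))
  double E;                 // total energy
  double lambda;

  GroupState(const NumericMatrix &C_, const IntegerVector &init, double lambda_)
      : C(C_), N(C_.nrow()), lab(N), lambda(lambda_) {
    int K = 0;
    for (int i = 0; i < N; ++i) {
      lab[i] = init[i] - 1;
      if (lab[i] + 1 > K) K = lab[i] + 1;
    }
    n.assign(K, 0.0);
    c.assign(K, 0.0);
    for (int i = 0; i < N; ++i) n[lab[i]] += 1.0;
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        if (lab[i] == lab[j]) c[lab[i]] += C(i, j);
    nlogn = 0.0;
    E = 0.0;
    for (int k = 0; k < K; ++k) {
      nlogn += n[k] * std::log(n[k]);
      E += eterm(n[k], c[k]);
    }
  }

  static double eterm(double nk, double ck) {
    if (nk <= 1.0 || ck <= nk) return 0.0;  // singleton or g_hat clamped at 0
    double n2 = nk * nk;
    double d = n2 - ck;
    if (d < 1e-12) d = 1e-12;               // guarded upstream by the C clamp
    return 0.5 * (std::log(ck / nk) + (nk - 1.0) * std::log(d / (n2 - nk)));
  }

  int K() const { return (int)n.size(); }

  double genK(double nlogn_) const {
    // K(s) = exp(log N - (1/N) sum n_k log n_k)
    return std::exp(std::log((double)N) - nlogn_ / (double)N);
  }

  double H() const { return E + lambda * genK(nlogn); }

  // sum of C(i, j) over current members j of domain k (includes i itself if
  // i is a member)
  double link(int i, int k) const {
    double s = 0.0;
    for (int j = 0; j < N; ++j)
      if (lab[j] == k) s += C(i, j);
    return s;
  }

  // delete domain k (must be empty): swap with the last domain
  void drop_domain(int k) {
    int last = K() - 1;
    if (k != last) {
      n[k] = n[last];
      c[k] = c[last];
      for (int i = 0; i < N; ++i)
        if (lab[i] == last) lab[i] = k;
    }
    n.pop_back();
    c.pop_back();
  }
};

inline double xlogx(double x) { return x > 0.0 ? x * std::log(x) : 0.0; }

inline double C_diag(const GroupState &st, int i) { return st.C(i, i); }

// One systematic-scan Metropolis-Hastings sweep at temperature T.
// Proposals: uniform over {existing labels != current} + one fresh label;
// acceptance min(1, exp(-dH/T) * K(s)/K(s')) (Hastings factor for the
// asymmetric proposal counts when K changes).  Returns accepted move count.
int sweep(GroupState &st, double T, bool hastings,
          double &bestH, std::vector<int> *bestLab) {
  int N = st.N;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  for (int i = N - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  int accepted = 0;
  for (int t = 0; t < N; ++t) {
    int i = order[t];
    int K = st.K();
    int cur = st.lab[i];
    // draw target among K options: K-1 other labels + fresh
    int m = (int)std::floor(unif_rand() * K);
    if (m >= K) m = K - 1;
    int target;          // -1 = fresh label
    if (m < cur) target = m;
    else if (m < K - 1) target = m + 1;
    else target = -1;

    bool cur_singleton = (st.n[cur] == 1.0);
    if (target == -1 && cur_singleton) { ++accepted; continue; }  // no-op

    int Kprop = (target == -1) ? K + 1 : (cur_singleton ? K - 1 : K);

    double li_cur = st.link(i, cur);          // includes C(i,i) = 1
    double n_cur_new = st.n[cur] - 1.0;
    double c_cur_new = st.c[cur] - 2.0 * li_cur + C_diag(st, i);
    double n_tgt_old = (target == -1) ? 0.0 : st.n[target];
    double c_tgt_old = (target == -1) ? 0.0 : st.c[target];
    double li_tgt = (target == -1) ? 0.0 : st.link(i, target);
    double n_tgt_new = n_tgt_old + 1.0;
    double c_tgt_new = c_tgt_old + 2.0 * li_tgt + C_diag(st, i);

    double dE = GroupState::eterm(n_cur_new, c_cur_new) -
                GroupState::eterm(st.n[cur], st.c[cur]) +
                GroupState::eterm(n_tgt_new, c_tgt_new) -
                GroupState::eterm(n_tgt_old, c_tgt_old);
    double nlogn_new = st.nlogn - xlogx(st.n[cur]) + xlogx(n_cur_new) -
                       xlogx(n_tgt_old) + xlogx(n_tgt_new);
    double dH = dE + st.lambda * (st.genK(nlogn_new) - st.genK(st.nlogn));

    double logacc = -dH / T;
    if (hastings) logacc += std::log((double)K) - std::log((double)Kprop);
    if (logacc >= 0.0 || unif_rand() < std::exp(logacc)) {
      // apply the move
      st.E += dE;
      st.nlogn = nlogn_new;
      st.n[cur] = n_cur_new;
      st.c[cur] = c_cur_new;
      int tgt = target;
      if (tgt == -1) {
        st.n.push_back(0.0);
        st.c.push_back(0.0);
        tgt = st.K() - 1;
        st.n[tgt] = 1.0;
        st.c[tgt] = C_diag(st, i);
      } else {
        st.n[tgt] = n_tgt_new;
        st.c[tgt] = c_tgt_new;
      }
      st.lab[i] = tgt;
      if (st.n[cur] == 0.0) st.drop_domain(cur);
      ++accepted;
      double h = st.H();
      if (h < bestH - 1e-12) {
        bestH = h;
        if (bestLab) *bestLab = st.lab;
      }
    }
  }
  return accepted;
}

}  // namespace

// [[Rcpp::export]]
List mcd_sweep_cpp(NumericMatrix C, IntegerVector labels, double lambda,
                   double T, int nsweeps, bool hastings) {
  GroupState st(C, labels, lambda);
  double bestH = st.H();
  int acc = 0;
  for (int s = 0; s < nsweeps; ++s) acc += sweep(st, T, hastings, bestH, nullptr);
  IntegerVector out(st.N);
  for (int i = 0; i < st.N; ++i) out[i] = st.lab[i] + 1;
  return List::create(_["labels"] = out, _["accepted"] = acc,
                      _["H"] = st.H(), _["E"] = st.E,
                      _["genK"] = st.genK(st.nlogn));
}

// [[Rcpp::export]]
List mcd_anneal_cpp(NumericMatrix C, IntegerVector labels, double lambda,
                    double T0, double alpha, int sweeps_per_T, double Tmin,
                    bool hastings) {
  GroupState st(C, labels, lambda);
  std::vector<int> bestLab = st.lab;
  double bestH = st.H();
  std::vector<double> trace;
  for (double T = T0; T >= Tmin; T *= alpha) {
    for (int s = 0; s < sweeps_per_T; ++s)
      sweep(st, T, hastings, bestH, &bestLab);
    trace.push_back(bestH);
  }
  IntegerVector out(st.N);
  for (int i = 0; i < st.N; ++i) out[i] = bestLab[i] + 1;
  IntegerVector fin(st.N);
  for (int i = 0; i < st.N; ++i) fin[i] = st.lab[i] + 1;
  return List::create(_["labels"] = out, _["best_H"] = bestH,
                      _["final_labels"] = fin, _["final_H"] = st.H(),
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
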