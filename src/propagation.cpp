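#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// Synchronous saturating-linear propagation.
// All indices 0-based. Clamped nodes hold their value at every step; basal
// nodes are initialised but free; everything else starts at 0.
static void propagate_raw(int n,
                          const std::vector<int>& from,
                          const std::vector<int>& to,
                          const double* w,
                          const std::vector<int>& cidx,
                          const std::vector<double>& cval,
                          const std::vector<int>& bidx,
                          const std::vector<double>& bval,
                          int steps,
                          std::vector<double>& cur,
                          std::vector<double>& nxt) {
  const int n_e = (int) from.size();
  std::fill(cur.begin(), cur.end(), 0.0);
  for (size_t i = 0; i < bidx.size(); ++i) cur[bidx[i]] = bval[i];
  for (size_t i = 0; i < cidx.size(); ++i) cur[cidx[i]] = cval[i];
  for (int s = 0; s < steps; ++s) {
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (int e = 0; e < n_e; ++e) nxt[to[e]] += w[e] * cur[from[e]];
    for (int i = 0; i < n; ++i) nxt[i] = clamp1(nxt[i]);
    for (size_t i = 0; i < cidx.size(); ++i) nxt[cidx[i]] = cval[i];
    cur.swap(nxt);
  }
}

// [[Rcpp::export]]
NumericVector propagate_core(int n_nodes,
                             IntegerVector from, IntegerVector to,
                             NumericVector weights,
                             IntegerVector clamp_idx, NumericVector clamp_val,
                             IntegerVector basal_idx, NumericVector basal_val,
                             int steps) {
  std::vector<int> f(from.begin(), from.end());
  std::vector<int> t(to.begin(), to.end());
  std::vector<int> ci(clamp_idx.begin(), clamp_idx.end());
  std::vector<double> cv(clamp_val.begin(), clamp_val.end());
  std::vector<int> bi(basal_idx.begin(), basal_idx.end());
  std::vector<double> bv(basal_val.begin(), basal_val.end());
  std::vector<double> cur(n_nodes), nxt(n_nodes);
  propagate_raw(n_nodes, f, t, REAL(weights), ci, cv, bi, bv, steps, cur, nxt);
  return NumericVector(cur.begin(), cur.end());
}

struct FlatRule {
  std::vector<int> stim_idx;
  std::vector<double> stim_val;
  std::vector<int> resp_idx;
  std::vector<double> resp_sign;
};

static std::vector<FlatRule> unpack_rules(List rules) {
  std::vector<FlatRule> out(rules.size());
  for (R_xlen_t r = 0; r < rules.size(); ++r) {
    List rl = rules[r];
    IntegerVector si = rl["stim_idx"];
    NumericVector sv = rl["stim_val"];
    IntegerVector ri = rl["resp_idx"];
    NumericVector rs = rl["resp_sign"];
    out[r].stim_idx.assign(si.begin(), si.end());
    out[r].stim_val.assign(sv.begin(), sv.end());
    out[r].resp_idx.assign(ri.begin(), ri.end());
    out[r].resp_sign.assign(rs.begin(), rs.end());
  }
  return out;
}

// Fraction of rules complied: a rule is complied when strictly more than
// fraction f of its response proteins show the expected sign with
// |activity| >= eps after propagating the rule's own stimulus.
static double accuracy_raw(int n,
                           const std::vector<int>& from,
                           const std::vector<int>& to,
                           const double* w,
                           const std::vector<FlatRule>& rules,
                           double f, double eps, int steps,
                           std::vector<double>& cur,
                           std::vector<double>& nxt) {
  const std::vector<int> no_b;
  const std::vector<double> no_bv;
  int complied = 0;
  for (size_t r = 0; r < rules.size(); ++r) {
    const FlatRule& rl = rules[r];
    propagate_raw(n, from, to, w, rl.stim_idx, rl.stim_val, no_b, no_bv,
                  steps, cur, nxt);
    int ok = 0;
    const int n_resp = (int) rl.resp_idx.size();
    for (int i = 0; i < n_resp; ++i) {
      double a = cur[rl.resp_idx[i]];
      if (std::fabs(a) >= eps && a * rl.resp_sign[i] > 0) ++ok;
    }
    if (ok > f * n_resp) ++complied;
  }
  return rules.empty() ? 0.0 : (double) complied / (double) rules.size();
}

// [[Rcpp::export]]
double accuracy_core(int n_nodes,
                     IntegerVector from, IntegerVector to,
                     NumericVector weights,
                     List rules, double f, double eps, int steps) {
  std::vector<int> fe(from.begin(), from.end());
  std::vector<int> te(to.begin(), to.end());
  std::vector<FlatRule> fr = unpack_rules(rules);
  std::vector<double> cur(n_nodes), nxt(n_nodes);
  return accuracy_raw(n_nodes, fe, te, REAL(weights), fr, f, eps, steps,
                      cur, nxt);
}

// Simulated annealing over edge weights with geometric cooling.
// prior_sign: 0 = free in [-1,1], +1 = [0,1], -1 = [-1,0].
// Uses the R RNG so that set.seed() on the R side fixes the run.
// [[Rcpp::export]]
List anneal_core(int n_nodes,
                 IntegerVector from, IntegerVector to,
                 IntegerVector prior_sign,
                 List rules, double f, double eps, int steps,
                 int iterations, double t_init, double cooling) {
  const int n_e = from.size();
  std::vector<int> fe(from.begin(), from.end());
  std::vector<int> te(to.begin(), to.end());
  std::vector<FlatRule> fr = unpack_rules(rules);
  std::vector<double> cur(n_nodes), nxt(n_nodes);

  std::vector<double> w(n_e), best_w(n_e);
  for (int e = 0; e < n_e; ++e) {
    double lo = (prior_sign[e] > 0) ? 0.0 : -1.0;
    double hi = (prior_sign[e] < 0) ? 0.0 : 1.0;
    w[e] = R::runif(lo, hi);
  }
  double acc = accuracy_raw(n_nodes, fe, te, w.data(), fr, f, eps, steps,
                            cur, nxt);
  best_w = w;
  double best_acc = acc;
  double temp = t_init;

  for (int it = 0; it < iterations; ++it) {
    int e = (int) std::floor(R::runif(0.0, 1.0) * n_e);
    if (e >= n_e) e = n_e - 1;
    double lo = (prior_sign[e] > 0) ? 0.0 : -1.0;
    double hi = (prior_sign[e] < 0) ? 0.0 : 1.0;
    double old = w[e];
    w[e] = R::runif(lo, hi);
    double acc_new = accuracy_raw(n_nodes, fe, te, w.data(), fr, f, eps,
                                  steps, cur, nxt);
    bool accept = acc_new >= acc;
    if (!accept && temp > 0) {
      accept = R::runif(0.0, 1.0) < std::exp((acc_new - acc) / temp);
    }
    if (accept) {
      acc = acc_new;
      if (acc > best_acc) { best_acc = acc; best_w = w; }
    } else {
      w[e] = old;
    }
    temp *= cooling;
  }
  return List::create(_["weights"] = NumericVector(best_w.begin(), best_w.end()),
                      _["accuracy"] = best_acc);
}
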