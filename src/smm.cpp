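#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Net repeat-count change after Poisson(theta) single steps, each +1/-1
// with probability 1/2, follows a symmetric Skellam law:
// P(net = k) = exp(-theta) * I_|k|(theta), I the modified Bessel function
// of the first kind. R's bessel_i with expo = 2 returns the
// exponentially-scaled value exp(-x) * I_nu(x), which is what we need.
static double smm_prob(double theta, int k) {
  if (k < 0) k = -k;
  if (theta <= 0.0) return k == 0 ? 1.0 : 0.0;
  if (theta <= 20.0) {
    // exp(-theta) * I_k(theta) by the ascending series; converges fast
    // and avoids special-function call overhead on short branches
    double half = 0.5 * theta;
    double term = 1.0;
    for (int i = 1; i <= k; ++i) term *= half / i;
    double sum = term;
    double h2 = half * half;
    for (int m = 1; m < 200; ++m) {
      term *= h2 / (m * (double)(k + m));
      sum += term;
      if (term < sum * 1e-16) break;
    }
    return sum * std::exp(-theta);
  }
  double v = R::bessel_i(theta, (double)k, 2.0);
  if (v < 0.0 || !R_FINITE(v)) v = 0.0; // underflow guard at extreme orders
  return v;
}

// net changes beyond theta + 6*sqrt(theta) + 4 carry negligible mass;
// probabilities there are treated as exactly zero
static int smm_kmax(double theta, int cap) {
  int k = (int)std::ceil(theta + 6.0 * std::sqrt(theta) + 4.0);
  return std::min(k, cap);
}

// [[Rcpp::export]]
NumericVector smm_probs_cpp(double theta, int kmax) {
  NumericVector out(kmax + 1);
  for (int k = 0; k <= kmax; ++k) out[k] = smm_prob(theta, k);
  return out;
}

// Felsenstein pruning over a truncated integer repeat window, one locus
// at a time. Edges must be ordered so that every child's subtree is
// complete before the edge is applied (parent times ascending suffices).
// Node ids are 1-based; tips are 1..n_tip. Missing tip calls get a flat
// partial. Root prior is uniform over the window.
//
// [[Rcpp::export]]
double smm_tree_loglik_cpp(IntegerVector edge_parent,
                           IntegerVector edge_child,
                           NumericVector edge_theta,
                           IntegerMatrix tips,
                           int n_node,
                           IntegerVector win_lo,
                           IntegerVector win_hi) {
  const int n_edge = edge_parent.size();
  const int n_tip = tips.nrow();
  const int n_loci = tips.ncol();
  double loglik = 0.0;

  int wmax = 1;
  for (int l = 0; l < n_loci; ++l) {
    int w = win_hi[l] - win_lo[l] + 1;
    if (w > wmax) wmax = w;
  }
  // transition probabilities per edge, shared across loci, truncated at
  // the edge's own support
  std::vector< std::vector<double> > eprob(n_edge);
  std::vector<int> ekmax(n_edge);
  for (int e = 0; e < n_edge; ++e) {
    int km = smm_kmax(edge_theta[e], wmax - 1);
    ekmax[e] = km;
    eprob[e].resize(km + 1);
    for (int k = 0; k <= km; ++k) eprob[e][k] = smm_prob(edge_theta[e], k);
  }

  // full symmetric kernels, contiguous, and zero-padded partials so the
  // convolution is a plain dot product
  int kpad = 0;
  for (int e = 0; e < n_edge; ++e) if (ekmax[e] > kpad) kpad = ekmax[e];
  std::vector< std::vector<double> > ekern(n_edge);
  for (int e = 0; e < n_edge; ++e) {
    const int km = ekmax[e];
    ekern[e].assign(2 * km + 1, 0.0);
    for (int d = -km; d <= km; ++d)
      ekern[e][d + km] = eprob[e][d < 0 ? -d : d];
  }
  const int Wp = wmax + 2 * kpad;
  std::vector<double> partial, child_msg(wmax);
  std::vector<int> nkids(n_node);

  for (int l = 0; l < n_loci; ++l) {
    const int lo = win_lo[l];
    const int W = win_hi[l] - lo + 1;
    partial.assign((size_t)n_node * Wp, 0.0);
    for (int v = 0; v < n_node; ++v) {
      double* pv = &partial[(size_t)v * Wp + kpad];
      for (int s = 0; s < W; ++s) pv[s] = 1.0;
    }
    for (int v = 0; v < n_tip; ++v) {
      int obs = tips(v, l);
      if (obs == NA_INTEGER) continue; // flat partial for missing
      double* pv = &partial[(size_t)v * Wp + kpad];
      for (int s = 0; s < W; ++s) pv[s] = 0.0;
      int idx = obs - lo;
      if (idx < 0 || idx >= W)
        stop("observed repeat outside pruning window");
      pv[idx] = 1.0;
    }
    std::fill(nkids.begin(), nkids.end(), 0);
    int root = -1;
    for (int e = 0; e < n_edge; ++e) {
      const int par = edge_parent[e] - 1;
      const int chi = edge_child[e] - 1;
      const int km = ekmax[e];
      const double* kern = ekern[e].data();
      const double* pc = &partial[(size_t)chi * Wp + kpad];
      for (int s = 0; s < W; ++s) {
        double acc = 0.0;
        const double* src = pc + s - km;
        for (int d = 0; d <= 2 * km; ++d) acc += kern[d] * src[d];
        child_msg[s] = acc;
      }
      double* pp = &partial[(size_t)par * Wp + kpad];
      for (int s = 0; s < W; ++s) pp[s] *= child_msg[s];
      if (++nkids[par] == 2) {
        // node complete: rescale to guard against underflow
        double sum = 0.0;
        for (int s = 0; s < W; ++s) sum += pp[s];
        if (sum <= 0.0) return R_NegInf;
        for (int s = 0; s < W; ++s) pp[s] /= sum;
        loglik += std::log(sum);
      }
      root = par;
    }
    if (n_edge == 0) root = 0;
    // uniform root prior over the window
    double acc = 0.0;
    const double* pr0 = &partial[(size_t)root * Wp + kpad];
    for (int s = 0; s < W; ++s) acc += pr0[s];
    acc /= W;
    if (acc <= 0.0) return R_NegInf;
    loglik += std::log(acc);
  }
  return loglik;
}

// integral of 1/N(z) over [t0, t1]: N(z) = N0*exp(-r z) below beta,
// N_a at and above
static double inv_size_integral_c(double t0, double t1, double N0,
                                  double Na, double beta, double r) {
  if (t1 <= t0) return 0.0;
  double acc = 0.0;
  double lo = t0;
  double hi = std::min(t1, beta);
  if (hi > lo) {
    acc += (r == 0.0) ? (hi - lo) / N0
                      : (std::exp(r * hi) - std::exp(r * lo)) / (N0 * r);
    lo = hi;
  }
  if (t1 > beta) {
    double lo2 = std::max(t0, beta);
    acc += (t1 - lo2) / Na;
  }
  return acc;
}

// Structured-coalescent log density of a genealogy under the splitting,
// constant-then-growing demography. Unit ids are 1-based population-tree
// node ids; weights gives each unit's share of the total size. merge_*
// give the root-ward unit merges in increasing time order.
//
// [[Rcpp::export]]
double coal_log_prior_cpp(IntegerVector parent, NumericVector node_time,
                          IntegerVector tip_unit, int n_tip,
                          NumericVector weights,
                          NumericVector merge_time, IntegerVector merge_node,
                          IntegerVector merge_a, IntegerVector merge_b,
                          double N0, double Na, double beta, double r) {
  const int n_node = parent.size();
  const int n_units = weights.size();
  const int n_merge = merge_time.size();
  if (n_tip <= 1) return 0.0;

  std::vector<int> merged_into(n_units + 1, 0);
  std::vector<double> k_of(n_units + 1, 0.0);
  std::vector<int> unit_of(n_node, 0);
  for (int v = 0; v < n_tip; ++v) {
    unit_of[v] = tip_unit[v];
    k_of[tip_unit[v]] += 1.0;
  }
  // children of each internal node
  std::vector<int> kid1(n_node, -1), kid2(n_node, -1);
  for (int v = 0; v < n_node; ++v) {
    int p = parent[v];
    if (p == NA_INTEGER) continue;
    if (kid1[p - 1] < 0) kid1[p - 1] = v; else kid2[p - 1] = v;
  }
  // internal nodes sorted by time
  std::vector<int> internal;
  internal.reserve(n_node - n_tip);
  for (int v = n_tip; v < n_node; ++v) internal.push_back(v);
  std::sort(internal.begin(), internal.end(),
            [&](int a, int b) { return node_time[a] < node_time[b]; });

  double logp = 0.0;
  double t = 0.0;
  size_t ci = 0, mi = 0;
  while (ci < internal.size()) {
    double t_coal = node_time[internal[ci]];
    double t_merge = (mi < (size_t)n_merge) ? merge_time[mi] : R_PosInf;
    double t_next = std::min(t_coal, t_merge);
    if (t_next > t) {
      double lam = inv_size_integral_c(t, t_next, N0, Na, beta, r);
      for (int u = 1; u <= n_units; ++u) {
        if (k_of[u] >= 2.0) {
          logp -= k_of[u] * (k_of[u] - 1.0) / 2.0 / weights[u - 1] * lam;
        }
      }
    }
    if (t_merge <= t_coal) {
      int a = merge_a[mi], b = merge_b[mi], node = merge_node[mi];
      while (merged_into[a] != 0) a = merged_into[a];
      while (merged_into[b] != 0) b = merged_into[b];
      merged_into[a] = node;
      merged_into[b] = node;
      k_of[node] = k_of[a] + k_of[b];
      k_of[a] = 0.0; k_of[b] = 0.0;
      ++mi;
      t = t_merge;
    } else {
      int v = internal[ci];
      int c1 = kid1[v], c2 = kid2[v];
      if (c1 < 0 || c2 < 0) return R_NegInf; // non-binary
      int u1 = unit_of[c1], u2 = unit_of[c2];
      if (u1 == 0 || u2 == 0) return R_NegInf; // child older than parent
      while (merged_into[u1] != 0) u1 = merged_into[u1];
      while (merged_into[u2] != 0) u2 = merged_into[u2];
      if (u1 != u2) return R_NegInf;
      double w = weights[u1 - 1];
      double Nt = (t_coal < beta) ? N0 * std::exp(-r * t_coal) : Na;
      logp -= std::log(w * Nt);
      k_of[u1] -= 1.0;
      unit_of[v] = u1;
      ++ci;
      t = t_coal;
    }
  }
  return logp;
}
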