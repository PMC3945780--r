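// Random survival forest core: log-rank split search, recursive tree
// growth with Nelson-Aalen terminal cumulative hazards, and ensemble /
// out-of-bag prediction. Trees are returned to R as plain lists so the
// R-level API can inspect structure.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeBuilder {
  std::vector<int> var;               // -1 for terminal
  std::vector<double> split;
  std::vector<int> left, right;       // 0-based child ids, -1 if terminal
  std::vector<std::vector<double>> chf;  // terminal CHF on the global grid
  int grid_len;
};

// Node-local event-time table: distinct event times ascending with total
// deaths d and at-risk counts Y.
struct EventTable {
  std::vector<double> t;
  std::vector<double> d, Y;
};

EventTable node_event_table(const std::vector<int>& idx,
                            const NumericVector& time,
                            const IntegerVector& status) {
  EventTable tab;
  std::vector<double> evt;
  for (int i : idx) if (status[i] == 1) evt.push_back(time[i]);
  std::sort(evt.begin(), evt.end());
  evt.erase(std::unique(evt.begin(), evt.end()), evt.end());
  tab.t = evt;
  size_t m = evt.size();
  tab.d.assign(m, 0.0);
  tab.Y.assign(m, 0.0);
  for (int i : idx) {
    double ti = time[i];
    // Y_l counts t_i >= t_l
    size_t pos = std::upper_bound(evt.begin(), evt.end(), ti) - evt.begin();
    for (size_t l = 0; l < pos; ++l) tab.Y[l] += 1.0;
    if (status[i] == 1) {
      size_t l = std::lower_bound(evt.begin(), evt.end(), ti) - evt.begin();
      tab.d[l] += 1.0;
    }
  }
  return tab;
}

// Standardized two-sample log-rank statistic |O-E|/sqrt(V) for the left
// group described by dL/YL against the node totals.
double logrank_stat(const EventTable& tab, const std::vector<double>& dL,
                    const std::vector<double>& YL) {
  double O = 0.0, E = 0.0, V = 0.0;
  for (size_t l = 0; l < tab.t.size(); ++l) {
    double Y = tab.Y[l], d = tab.d[l], yl = YL[l];
    if (Y <= 0) continue;
    O += dL[l];
    E += d * yl / Y;
    if (Y > 1)
      V += d * (yl / Y) * (1.0 - yl / Y) * (Y - d) / (Y - 1.0);
  }
  if (V <= 1e-12) return -1.0;
  return std::fabs(O - E) / std::sqrt(V);
}

void terminal_chf(TreeBuilder& tb, int node, const std::vector<int>& idx,
                  const NumericVector& time, const IntegerVector& status,
                  const NumericVector& grid) {
  EventTable tab = node_event_table(idx, time, status);
  std::vector<double> H(tb.grid_len, 0.0);
  size_t l = 0;
  double acc = 0.0;
  for (int g = 0; g < tb.grid_len; ++g) {
    while (l < tab.t.size() && tab.t[l] <= grid[g]) {
      acc += tab.d[l] / tab.Y[l];
      ++l;
    }
    H[g] = acc;
  }
  tb.chf[node] = H;
}

void grow_node(TreeBuilder& tb, int node, std::vector<int>& idx,
               const NumericMatrix& X, const NumericVector& time,
               const IntegerVector& status, const NumericVector& grid,
               int mtry, int min_node_events, std::mt19937& rng) {
  int p = X.ncol();
  EventTable tab = node_event_table(idx, time, status);
  if ((int)tab.t.size() < min_node_events) {
    terminal_chf(tb, node, idx, time, status, grid);
    return;
  }
  // draw mtry candidate covariates without replacement
  std::vector<int> cand(p);
  for (int j = 0; j < p; ++j) cand[j] = j;
  for (int j = 0; j < mtry; ++j) {
    std::uniform_int_distribution<int> U(j, p - 1);
    std::swap(cand[j], cand[U(rng)]);
  }
  double best_stat = 0.0, best_split = 0.0;
  int best_var = -1;
  size_t n_node = idx.size(), m = tab.t.size();
  std::vector<int> ord(idx);
  for (int c = 0; c < mtry; ++c) {
    int v = cand[c];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, v) < X(b, v);
    });
    std::vector<double> dL(m, 0.0), YL(m, 0.0);
    for (size_t i = 0; i + 1 < n_node; ++i) {
      int r = ord[i];
      double ti = time[r];
      size_t pos = std::upper_bound(tab.t.begin(), tab.t.end(), ti) -
                   tab.t.begin();
      for (size_t l = 0; l < pos; ++l) YL[l] += 1.0;
      if (status[r] == 1) {
        size_t l = std::lower_bound(tab.t.begin(), tab.t.end(), ti) -
                   tab.t.begin();
        dL[l] += 1.0;
      }
      double x0 = X(r, v), x1 = X(ord[i + 1], v);
      if (x1 <= x0) continue;  // not a boundary between distinct values
      double stat = logrank_stat(tab, dL, YL);
      if (stat > best_stat) {
        best_stat = stat;
        best_var = v;
        best_split = 0.5 * (x0 + x1);
      }
    }
  }
  if (best_var < 0) {
    terminal_chf(tb, node, idx, time, status, grid);
    return;
  }
  std::vector<int> li, ri;
  for (int r : idx) {
    if (X(r, best_var) <= best_split) li.push_back(r);
    else ri.push_back(r);
  }
  int lid = tb.var.size(), rid = lid + 1;
  tb.var.push_back(-1); tb.split.push_back(0);
  tb.left.push_back(-1); tb.right.push_back(-1);
  tb.chf.push_back(std::vector<double>());
  tb.var.push_back(-1); tb.split.push_back(0);
  tb.left.push_back(-1); tb.right.push_back(-1);
  tb.chf.push_back(std::vector<double>());
  tb.var[node] = best_var;
  tb.split[node] = best_split;
  tb.left[node] = lid;
  tb.right[node] = rid;
  grow_node(tb, lid, li, X, time, status, grid, mtry, min_node_events, rng);
  grow_node(tb, rid, ri, X, time, status, grid, mtry, min_node_events, rng);
}

List build_tree(const NumericMatrix& X, const NumericVector& time,
                const IntegerVector& status, const NumericVector& grid,
                const std::vector<int>& inbag0, int mtry,
                int min_node_events, std::mt19937& rng) {
  TreeBuilder tb;
  tb.grid_len = grid.size();
  tb.var.push_back(-1); tb.split.push_back(0);
  tb.left.push_back(-1); tb.right.push_back(-1);
  tb.chf.push_back(std::vector<double>());
  std::vector<int> idx(inbag0);
  grow_node(tb, 0, idx, X, time, status, grid, mtry, min_node_events, rng);
  int nn = tb.var.size();
  NumericMatrix chf(nn, tb.grid_len);
  for (int i = 0; i < nn; ++i)
    if (!tb.chf[i].empty())
      for (int g = 0; g < tb.grid_len; ++g) chf(i, g) = tb.chf[i][g];
  IntegerVector inbag1(inbag0.size());
  for (size_t i = 0; i < inbag0.size(); ++i) inbag1[i] = inbag0[i] + 1;
  return List::create(_["var"] = IntegerVector(tb.var.begin(), tb.var.end()),
                      _["split"] = NumericVector(tb.split.begin(),
                                                 tb.split.end()),
                      _["left"] = IntegerVector(tb.left.begin(),
                                                tb.left.end()),
                      _["right"] = IntegerVector(tb.right.begin(),
                                                 tb.right.end()),
                      _["chf"] = chf,
                      _["inbag"] = inbag1);
}

// Drop case row r of X down a tree; return terminal node id.
inline int drop_case(const IntegerVector& var, const NumericVector& split,
                     const IntegerVector& left, const IntegerVector& right,
                     const NumericMatrix& X, int r) {
  int node = 0;
  while (var[node] >= 0)
    node = (X(r, var[node]) <= split[node]) ? left[node] : right[node];
  return node;
}

}  // namespace

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, NumericVector time, IntegerVector status,
                   NumericVector grid, IntegerVector inbag, int mtry,
                   int min_node_events, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::vector<int> ib(inbag.size());
  for (int i = 0; i < inbag.size(); ++i) ib[i] = inbag[i] - 1;
  return build_tree(X, time, status, grid, ib, mtry, min_node_events, rng);
}

// [[Rcpp::export]]
List fit_forest_cpp(NumericMatrix X, NumericVector time, IntegerVector status,
                    NumericVector grid, int ntree, int mtry,
                    int min_node_events, double sample_fraction, int seed) {
  int n = X.nrow();
  int m = (int)std::lround(sample_fraction * n);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::mt19937 rng((unsigned)seed + 0x9E3779B9u * (unsigned)(t + 1));
    std::vector<int> perm(n);
    std::vector<int> ib;
    bool ok = false;
    for (int attempt = 0; attempt < 100 && !ok; ++attempt) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = 0; i < m; ++i) {
        std::uniform_int_distribution<int> U(i, n - 1);
        std::swap(perm[i], perm[U(rng)]);
      }
      ib.assign(perm.begin(), perm.begin() + m);
      for (int i : ib) if (status[i] == 1) { ok = true; break; }
    }
    if (!ok) stop("no in-bag resample with an event after 100 attempts");
    std::sort(ib.begin(), ib.end());
    trees[t] = build_tree(X, time, status, grid, ib, mtry, min_node_events,
                          rng);
  }
  return trees;
}

// Ensemble cumulative hazard for each row of X: mean terminal CHF over the
// given trees (all trees, or only those where the case is out of bag).
// [[Rcpp::export]]
NumericMatrix ensemble_chf_cpp(List trees, NumericMatrix X, int grid_len,
                               bool oob_only) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix out(n, grid_len);
  std::vector<int> cnt(n, 0);
  std::vector<bool> inbag;
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    NumericVector split = tr["split"];
    NumericMatrix chf = tr["chf"];
    if (oob_only) {
      inbag.assign(n, false);
      IntegerVector ib = tr["inbag"];
      for (int i = 0; i < ib.size(); ++i) inbag[ib[i] - 1] = true;
    }
    for (int r = 0; r < n; ++r) {
      if (oob_only && inbag[r]) continue;
      int node = drop_case(var, split, left, right, X, r);
      for (int g = 0; g < grid_len; ++g) out(r, g) += chf(node, g);
      cnt[r] += 1;
    }
  }
  for (int r = 0; r < n; ++r) {
    if (cnt[r] == 0) {
      for (int g = 0; g < grid_len; ++g) out(r, g) = NA_REAL;
    } else {
      for (int g = 0; g < grid_len; ++g) out(r, g) /= cnt[r];
    }
  }
  return out;
}

// Harrell's concordance of risk scores against right-censored outcomes.
// Usable pairs: t_i < t_j with event at t_i, or tied times with exactly one
// event. Score ties count 1/2. Returns NA if no usable pair exists.
// [[Rcpp::export]]
double harrell_c_cpp(NumericVector risk, NumericVector time,
                     IntegerVector status) {
  int n = risk.size();
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      bool usable = (time[i] < time[j] && status[i] == 1) ||
                    (time[i] == time[j] && i < j &&
                     status[i] + status[j] == 1);
      if (!usable) continue;
      double ri, rj;  // ri belongs to the case failing earlier
      if (time[i] == time[j]) {
        ri = (status[i] == 1) ? risk[i] : risk[j];
        rj = (status[i] == 1) ? risk[j] : risk[i];
      } else {
        ri = risk[i]; rj = risk[j];
      }
      den += 1.0;
      if (ri > rj) num += 1.0;
      else if (ri == rj) num += 0.5;
    }
  }
  if (den == 0.0) return NA_REAL;
  return num / den;
}

// Score U_j and Fisher information I_j of every column at theta_j = 0:
// risk-set sums as cumulative sums over rows pre-sorted by decreasing time
// (ord, 1-based), with kmap sending each subject to its cumulative-sum
// position (Breslow ties). ev flags event rows. Hot loop of the boosting
// engine.
// [[Rcpp::export]]
List score_info_cpp(NumericMatrix X, IntegerVector ord, IntegerVector kmap,
                    NumericVector w, IntegerVector ev_rows) {
  int n = X.nrow(), p = X.ncol(), ne = ev_rows.size();
  NumericVector U(p), I(p);
  std::vector<double> cw(n), c1(n), c2(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += w[ord[i] - 1];
    cw[i] = acc;
  }
  for (int j = 0; j < p; ++j) {
    double a1 = 0.0, a2 = 0.0;
    for (int i = 0; i < n; ++i) {
      int r = ord[i] - 1;
      double x = X(r, j), xw = x * w[r];
      a1 += xw;
      a2 += x * xw;
      c1[i] = a1;
      c2[i] = a2;
    }
    double u = 0.0, inf = 0.0;
    for (int e = 0; e < ne; ++e) {
      int r = ev_rows[e] - 1;
      int k = kmap[r] - 1;
      double s0 = cw[k], r1 = c1[k] / s0;
      u += X(r, j) - r1;
      inf += c2[k] / s0 - r1 * r1;
    }
    U[j] = u;
    I[j] = inf > 0 ? inf : 0.0;
  }
  return List::create(_["U"] = U, _["I"] = I);
}
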