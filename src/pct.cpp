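#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// FNV-1a 32-bit over the little-endian bytes of a sequence of 32-bit words.
// Fixed, platform-independent; all fingerprint identifiers flow through it.
// ---------------------------------------------------------------------------
static uint32_t fnv1a(const uint32_t *v, int n) {
  uint32_t h = 2166136261u;
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 32; s += 8) {
      h ^= (v[i] >> s) & 0xffu;
      h *= 16777619u;
    }
  }
  return h;
}

// [[Rcpp::export]]
double cpp_fnv1a(NumericVector words) {
  int n = words.size();
  std::vector<uint32_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = (uint32_t)((int64_t)words[i] & 0xffffffffLL);
  return (double)fnv1a(v.data(), n);
}

// ---------------------------------------------------------------------------
// ECFP neighbourhood iterations. `init` holds the iteration-0 atom
// identifiers (uint32 stored in doubles); edges is an m x 2 matrix of 1-based
// atom indices; `orders` codes bond orders (1, 2, 3; 4 = aromatic). Returns a
// list of per-iteration identifier vectors (length natoms each), iterations
// 0..radius.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_ecfp_iterations(int natoms, NumericVector init, IntegerMatrix edges,
                         IntegerVector orders, int radius) {
  std::vector<std::vector<std::pair<int, int>>> adj(natoms); // (order, nbr)
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1, o = orders[e];
    adj[a].push_back(std::make_pair(o, b));
    adj[b].push_back(std::make_pair(o, a));
  }
  std::vector<uint32_t> prev(natoms), cur(natoms);
  for (int i = 0; i < natoms; ++i)
    prev[i] = (uint32_t)((int64_t)init[i] & 0xffffffffLL);

  List out(radius + 1);
  out[0] = NumericVector(init.begin(), init.end());
  std::vector<uint32_t> buf;
  for (int r = 1; r <= radius; ++r) {
    for (int i = 0; i < natoms; ++i) {
      // sorted (order, neighbour id) pairs make the hash invariant to
      // atom input order
      std::vector<std::pair<uint32_t, uint32_t>> nb;
      nb.reserve(adj[i].size());
      for (size_t j = 0; j < adj[i].size(); ++j)
        nb.push_back(std::make_pair((uint32_t)adj[i][j].first,
                                    prev[adj[i][j].second]));
      std::sort(nb.begin(), nb.end());
      buf.clear();
      buf.push_back((uint32_t)r);
      buf.push_back(prev[i]);
      for (size_t j = 0; j < nb.size(); ++j) {
        buf.push_back(nb[j].first);
        buf.push_back(nb[j].second);
      }
      cur[i] = fnv1a(buf.data(), (int)buf.size());
    }
    NumericVector ids(natoms);
    for (int i = 0; i < natoms; ++i) ids[i] = (double)cur[i];
    out[r] = ids;
    prev = cur;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multi-target predictive clustering trees.
//
// Split heuristic: normalized variance reduction summed over the two targets.
// Variances are population variances (divide by n); each target's variance is
// divided by scale^2 (scale = full-training-set sd) so RFP and EGFP
// contribute comparably.
// ---------------------------------------------------------------------------

struct SplitStats {
  double red;   // variance reduction; -Inf if inadmissible
};

// weighted (by membership) node variance: sum over targets of pop-var/scale^2
static double node_variance(const std::vector<int> &rows, const double *y0,
                            const double *y1, double s0, double s1) {
  double n = (double)rows.size();
  double a0 = 0, q0 = 0, a1 = 0, q1 = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    double v0 = y0[rows[i]], v1 = y1[rows[i]];
    a0 += v0; q0 += v0 * v0;
    a1 += v1; q1 += v1 * v1;
  }
  double var0 = q0 / n - (a0 / n) * (a0 / n);
  double var1 = q1 / n - (a1 / n) * (a1 / n);
  if (var0 < 0) var0 = 0;
  if (var1 < 0) var1 = 0;
  return var0 / (s0 * s0) + var1 / (s1 * s1);
}

// variance reduction of splitting `rows` on each bit; -Inf where a branch is
// empty or smaller than min_leaf
static void eval_all_bits(const int *X, int nX, int p,
                          const std::vector<int> &rows, const double *y0,
                          const double *y1, double s0, double s1, int min_leaf,
                          double Vtot, std::vector<double> &red) {
  double n = (double)rows.size();
  red.assign(p, R_NegInf);
  double t0 = 0, tq0 = 0, t1 = 0, tq1 = 0; // node totals
  for (size_t i = 0; i < rows.size(); ++i) {
    double v0 = y0[rows[i]], v1 = y1[rows[i]];
    t0 += v0; tq0 += v0 * v0; t1 += v1; tq1 += v1 * v1;
  }
  for (int b = 0; b < p; ++b) {
    const int *col = X + (size_t)b * nX;
    double n1 = 0, a0 = 0, q0 = 0, a1 = 0, q1 = 0;
    for (size_t i = 0; i < rows.size(); ++i) {
      if (col[rows[i]]) {
        double v0 = y0[rows[i]], v1 = y1[rows[i]];
        n1 += 1; a0 += v0; q0 += v0 * v0; a1 += v1; q1 += v1 * v1;
      }
    }
    double n0 = n - n1;
    if (n1 < min_leaf || n0 < min_leaf) continue;
    double var10 = q0 / n1 - (a0 / n1) * (a0 / n1);
    double var11 = q1 / n1 - (a1 / n1) * (a1 / n1);
    double var00 = (tq0 - q0) / n0 - ((t0 - a0) / n0) * ((t0 - a0) / n0);
    double var01 = (tq1 - q1) / n0 - ((t1 - a1) / n0) * ((t1 - a1) / n0);
    if (var10 < 0) var10 = 0;
    if (var11 < 0) var11 = 0;
    if (var00 < 0) var00 = 0;
    if (var01 < 0) var01 = 0;
    double V1 = var10 / (s0 * s0) + var11 / (s1 * s1);
    double V0 = var00 / (s0 * s0) + var01 / (s1 * s1);
    red[b] = Vtot - (n1 / n) * V1 - (n0 / n) * V0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_eval_all_splits(IntegerMatrix X, NumericMatrix Y,
                                  IntegerVector rows, NumericVector scale,
                                  int min_leaf) {
  int p = X.ncol(), nX = X.nrow();
  std::vector<int> rr(rows.size());
  for (int i = 0; i < rows.size(); ++i) rr[i] = rows[i] - 1;
  const double *y0 = &Y(0, 0), *y1 = &Y(0, 1);
  double Vtot = node_variance(rr, y0, y1, scale[0], scale[1]);
  std::vector<double> red;
  eval_all_bits(X.begin(), nX, p, rr, y0, y1, scale[0], scale[1], min_leaf,
                Vtot, red);
  return NumericVector(red.begin(), red.end());
}

struct TreeBuild {
  std::vector<int> split, left, right, n;
  std::vector<double> p0, p1;
};

static int grow_node(const int *X, int nX, int p, std::vector<int> &rows,
                     const double *y0, const double *y1, double s0, double s1,
                     int min_leaf, int max_depth, int depth, TreeBuild &tb) {
  double n = (double)rows.size();
  double a0 = 0, a1 = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    a0 += y0[rows[i]];
    a1 += y1[rows[i]];
  }
  int me = (int)tb.split.size();
  tb.split.push_back(-1);
  tb.left.push_back(0);
  tb.right.push_back(0);
  tb.n.push_back((int)n);
  tb.p0.push_back(a0 / n);
  tb.p1.push_back(a1 / n);

  double Vtot = node_variance(rows, y0, y1, s0, s1);
  bool pure = Vtot <= 1e-12;
  bool depth_ok = (max_depth < 0) || (depth < max_depth);
  if (n < 2 * (double)min_leaf || pure || !depth_ok) return me;

  std::vector<double> red;
  eval_all_bits(X, nX, p, rows, y0, y1, s0, s1, min_leaf, Vtot, red);
  int best = -1;
  double best_red = R_NegInf;
  for (int b = 0; b < p; ++b)
    if (red[b] > best_red) { best_red = red[b]; best = b; } // ties -> lowest bit
  // a float-negative reduction means nothing is gained: stop
  if (best < 0 || best_red < -1e-12) return me;

  const int *col = X + (size_t)best * nX;
  std::vector<int> r0, r1;
  for (size_t i = 0; i < rows.size(); ++i)
    (col[rows[i]] ? r1 : r0).push_back(rows[i]);
  rows.clear();
  rows.shrink_to_fit();
  tb.split[me] = best;
  int l = grow_node(X, nX, p, r0, y0, y1, s0, s1, min_leaf, max_depth,
                    depth + 1, tb);
  int r = grow_node(X, nX, p, r1, y0, y1, s0, s1, min_leaf, max_depth,
                    depth + 1, tb);
  tb.left[me] = l + 1;  // 1-based node ids; 0 = none
  tb.right[me] = r + 1;
  return me;
}

// [[Rcpp::export]]
List cpp_grow_tree(IntegerMatrix X, NumericMatrix Y, IntegerVector rows,
                   NumericVector scale, int min_leaf, int max_depth) {
  std::vector<int> rr(rows.size());
  for (int i = 0; i < rows.size(); ++i) rr[i] = rows[i] - 1;
  TreeBuild tb;
  grow_node(X.begin(), X.nrow(), X.ncol(), rr, &Y(0, 0), &Y(0, 1), scale[0],
            scale[1], min_leaf, max_depth, 0, tb);
  NumericMatrix pred((int)tb.p0.size(), 2);
  for (size_t i = 0; i < tb.p0.size(); ++i) {
    pred(i, 0) = tb.p0[i];
    pred(i, 1) = tb.p1[i];
  }
  return List::create(_["split"] = IntegerVector(tb.split.begin(), tb.split.end()),
                      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
                      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
                      _["n"] = IntegerVector(tb.n.begin(), tb.n.end()),
                      _["pred"] = pred);
}

static void route(const IntegerVector &split, const IntegerVector &left,
                  const IntegerVector &right, const NumericMatrix &pred,
                  const int *X, int nX, int row, double *out0, double *out1) {
  int node = 0;
  while (split[node] >= 0) {
    const int *col = X + (size_t)split[node] * nX;
    node = (col[row] ? right[node] : left[node]) - 1;
  }
  *out0 = pred(node, 0);
  *out1 = pred(node, 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_tree(List tree, IntegerMatrix X) {
  IntegerVector split = tree["split"], left = tree["left"], right = tree["right"];
  NumericMatrix pred = tree["pred"];
  int n = X.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i)
    route(split, left, right, pred, X.begin(), n, i, &out(i, 0), &out(i, 1));
  return out;
}

// per-compound mean and population sd of per-tree predictions
// [[Rcpp::export]]
List cpp_predict_forest(List trees, IntegerMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix mean(n, 2), sd(n, 2);
  std::vector<double> s0(n, 0), s1(n, 0), q0(n, 0), q1(n, 0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector split = tr["split"], left = tr["left"], right = tr["right"];
    NumericMatrix pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      double a, b;
      route(split, left, right, pred, X.begin(), n, i, &a, &b);
      s0[i] += a; q0[i] += a * a;
      s1[i] += b; q1[i] += b * b;
    }
  }
  for (int i = 0; i < n; ++i) {
    double m0 = s0[i] / T, m1 = s1[i] / T;
    double v0 = q0[i] / T - m0 * m0, v1 = q1[i] / T - m1 * m1;
    mean(i, 0) = m0; mean(i, 1) = m1;
    sd(i, 0) = v0 > 0 ? std::sqrt(v0) : 0.0;
    sd(i, 1) = v1 > 0 ? std::sqrt(v1) : 0.0;
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
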