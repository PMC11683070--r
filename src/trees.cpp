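#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Exact greedy regression tree on gradient/hessian statistics.
// Least-squares CART is the special case g = -y, h = 1, lambda = alpha = 0
// (leaf value G/H reduces to the node mean of y); the gradient-boosting
// tree uses second-order statistics with L1 (alpha) and L2 (lambda)
// regularisation on leaf weights, as in XGBoost.

static inline double soft_thresh(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

static inline double node_score(double G, double H, double lambda,
                                double alpha) {
  double t = soft_thresh(G, alpha);
  return t * t / (H + lambda);
}

static inline double leaf_weight(double G, double H, double lambda,
                                 double alpha) {
  return -soft_thresh(G, alpha) / (H + lambda);
}

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  int add_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    threshold.push_back(0.0); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

static void grow(TreeBuf &tb, int node, const NumericMatrix &X,
                 const NumericVector &g, const NumericVector &h,
                 std::vector<int> &rows, int depth, int max_depth,
                 double min_child_weight, double lambda, double alpha) {
  const int n = (int)rows.size();
  const int p = X.ncol();
  double G = 0.0, H = 0.0;
  for (int i = 0; i < n; ++i) { G += g[rows[i]]; H += h[rows[i]]; }
  tb.value[node] = leaf_weight(G, H, lambda, alpha);
  if (depth >= max_depth || n < 2) return;

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  double parent = node_score(G, H, lambda, alpha);
  std::vector<int> ord(rows);
  for (int f = 0; f < p; ++f) {
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      GL += g[ord[i]]; HL += h[ord[i]];
      double xv = X(ord[i], f), xn = X(ord[i + 1], f);
      if (xv == xn) continue;                 // not a valid cut point
      double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double gain = node_score(GL, HL, lambda, alpha) +
                    node_score(GR, HR, lambda, alpha) - parent;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_thr = 0.5 * (xv + xn);
      }
    }
  }
  if (best_f < 0) return;

  std::vector<int> lrows, rrows;
  for (int i = 0; i < n; ++i) {
    if (X(rows[i], best_f) < best_thr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  if (lrows.empty() || rrows.empty()) return;  // numeric ties; keep leaf
  tb.feature[node] = best_f;
  tb.threshold[node] = best_thr;
  int l = tb.add_node(), r = tb.add_node();
  tb.left[node] = l; tb.right[node] = r;
  grow(tb, l, X, g, h, lrows, depth + 1, max_depth, min_child_weight,
       lambda, alpha);
  grow(tb, r, X, g, h, rrows, depth + 1, max_depth, min_child_weight,
       lambda, alpha);
}

// [[Rcpp::export(name = ".cpp_build_tree")]]
List cpp_build_tree(NumericMatrix X, NumericVector g, NumericVector h,
                    IntegerVector rows, int max_depth,
                    double min_child_weight, double lambda, double alpha) {
  TreeBuf tb;
  tb.add_node();
  std::vector<int> rv(rows.begin(), rows.end());  // 0-based row subset
  grow(tb, 0, X, g, h, rv, 0, max_depth, min_child_weight, lambda, alpha);
  return List::create(_["feature"] = wrap(tb.feature),
                      _["threshold"] = wrap(tb.threshold),
                      _["left"] = wrap(tb.left),
                      _["right"] = wrap(tb.right),
                      _["value"] = wrap(tb.value));
}

static inline double tree_predict_row(const IntegerVector &feature,
                                      const NumericVector &threshold,
                                      const IntegerVector &left,
                                      const IntegerVector &right,
                                      const NumericVector &value,
                                      const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) < threshold[node]) ? left[node]
                                                     : right[node];
  return value[node];
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tree_predict_row(feature, threshold, left, right, value, X, i);
  return out;
}

// Interventional Shapley values for a single tree, exact.
//
// For one foreground row x and one background row z, recursion over the
// tree partitions the leaves by the set A of features that must take x's
// value (coalition members) and the set B that must take z's value.  A
// leaf with value v reachable under (A, B) contributes to the Shapley
// value of each feature j the classical coalition weight:
//   j in A:  +v * (a-1)! b! / (a+b)!
//   j in B:  -v * a! (b-1)! / (a+b)!
// with a = |A|, b = |B|.  Averaging over background rows yields the
// interventional attribution; summing attributions gives f(x) - mean f(z)
// exactly (additivity).

// [[Rcpp::export(name = ".cpp_tree_shap")]]
NumericMatrix cpp_tree_shap(List tree, NumericMatrix Xfg, NumericMatrix Xbg) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int nf = Xfg.nrow(), nb = Xbg.nrow(), p = Xfg.ncol();

  // factorials (as doubles); tree depth caps |A| + |B| well below 64
  std::vector<double> fact(64);
  fact[0] = 1.0;
  for (int k = 1; k < 64; ++k) fact[k] = fact[k - 1] * k;

  NumericMatrix phi(nf, p);
  std::vector<int> A, B;
  A.reserve(64); B.reserve(64);

  for (int i = 0; i < nf; ++i) {
    for (int zi = 0; zi < nb; ++zi) {
      // explicit recursion via lambda
      std::function<void(int)> rec = [&](int node) {
        int f = feature[node];
        if (f < 0) {
          int a = (int)A.size(), b = (int)B.size();
          if (a + b == 0) return;
          double v = value[node];
          double inv_tot = 1.0 / fact[a + b];
          if (a > 0) {
            double w = fact[a - 1] * fact[b] * inv_tot;
            double add = v * w;
            for (int j : A) phi(i, j) += add;
          }
          if (b > 0) {
            double w = fact[a] * fact[b - 1] * inv_tot;
            double sub = v * w;
            for (int j : B) phi(i, j) -= sub;
          }
          return;
        }
        bool xl = Xfg(i, f) < threshold[node];
        bool zl = Xbg(zi, f) < threshold[node];
        bool inA = std::find(A.begin(), A.end(), f) != A.end();
        bool inB = std::find(B.begin(), B.end(), f) != B.end();
        if (inA) { rec(xl ? left[node] : right[node]); return; }
        if (inB) { rec(zl ? left[node] : right[node]); return; }
        if (xl == zl) { rec(xl ? left[node] : right[node]); return; }
        A.push_back(f);
        rec(xl ? left[node] : right[node]);
        A.pop_back();
        B.push_back(f);
        rec(zl ? left[node] : right[node]);
        B.pop_back();
      };
      rec(0);
    }
  }
  // average over background rows
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) /= nb;
  return phi;
}
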