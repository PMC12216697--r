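// Seeded regression random forest: bootstrap resampling + CART trees with
// random feature subsets at each node, in-bag bookkeeping for out-of-bag
// prediction. Draws from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& y;
  int mtry;
  int min_node;
  // flat node arrays for the tree under construction
  std::vector<int> var;        // split feature (0-based), -1 for leaf
  std::vector<double> thresh;  // split threshold (go left if x <= thresh)
  std::vector<int> left, right;
  std::vector<double> value;   // node mean (prediction at leaves)

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& y_,
              int mtry_, int min_node_)
    : X(X_), y(y_), mtry(mtry_), min_node(min_node_) {}

  int new_node(double mean) {
    var.push_back(-1);
    thresh.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(mean);
    return (int)var.size() - 1;
  }

  // rows: indices into X/y for this node (may repeat under bootstrap)
  int grow(std::vector<int>& rows) {
    const int n = (int)rows.size();
    double sum = 0.0;
    for (int r : rows) sum += y[r];
    const double mean = sum / n;
    int node = new_node(mean);
    if (n <= min_node) return node;

    bool constant = true;
    for (int r : rows) {
      if (y[r] != y[rows[0]]) { constant = false; break; }
    }
    if (constant) return node;

    const int p = X.ncol();
    const int m = std::min(mtry, p);
    // partial Fisher-Yates over feature indices using R's RNG
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    for (int j = 0; j < m; ++j) {
      int k = j + (int)std::floor(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feat[j], feat[k]);
    }

    double best_gain = 0.0;
    int best_var = -1;
    double best_thresh = 0.0;
    const double sse_parent_term = sum * sum / n;

    std::vector<int> ord(rows);
    for (int jj = 0; jj < m; ++jj) {
      const int j = feat[jj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, j) < X(b, j);
      });
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += y[ord[i]];
        const double xi = X(ord[i], j), xn = X(ord[i + 1], j);
        if (xi == xn) continue;  // no split between ties
        const int nl = i + 1, nr = n - nl;
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr - sse_parent_term;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_var = j;
          best_thresh = xi + (xn - xi) / 2.0;
        }
      }
    }
    if (best_var < 0) return node;

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    for (int r : rows) {
      if (X(r, best_var) <= best_thresh) lrows.push_back(r);
      else rrows.push_back(r);
    }
    if (lrows.empty() || rrows.empty()) return node;

    var[node] = best_var;
    thresh[node] = best_thresh;
    int l = grow(lrows);
    int r = grow(rrows);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

inline double predict_tree(const IntegerVector& var, const NumericVector& thresh,
                           const IntegerVector& left, const IntegerVector& right,
                           const NumericVector& value, int root,
                           const NumericMatrix& X, int row) {
  int node = root;
  while (var[node] >= 0) {
    node = (X(row, var[node]) <= thresh[node]) ? left[node] : right[node];
  }
  return value[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_node) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y dimensions disagree");
  if (n < 1) stop("empty training set");
  RNGScope scope;

  std::vector<double> yv(y.begin(), y.end());
  std::vector<int> all_var, all_left, all_right;
  std::vector<double> all_thresh, all_value;
  IntegerVector roots(n_trees);
  IntegerMatrix inbag(n, n_trees);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)std::floor(unif_rand() * n);
      if (k >= n) k = n - 1;
      rows[i] = k;
      inbag(k, t) += 1;
    }
    TreeBuilder tb(X, yv, mtry, min_node);
    tb.grow(rows);
    const int off = (int)all_var.size();
    roots[t] = off;
    for (size_t i = 0; i < tb.var.size(); ++i) {
      all_var.push_back(tb.var[i]);
      all_thresh.push_back(tb.thresh[i]);
      all_left.push_back(tb.left[i] < 0 ? -1 : tb.left[i] + off);
      all_right.push_back(tb.right[i] < 0 ? -1 : tb.right[i] + off);
      all_value.push_back(tb.value[i]);
    }
  }

  return List::create(
    _["var"] = wrap(all_var), _["thresh"] = wrap(all_thresh),
    _["left"] = wrap(all_left), _["right"] = wrap(all_right),
    _["value"] = wrap(all_value), _["roots"] = roots,
    _["inbag"] = inbag, _["n_trees"] = n_trees, _["p"] = X.ncol());
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List forest, NumericMatrix X) {
  IntegerVector var = forest["var"], left = forest["left"],
                right = forest["right"], roots = forest["roots"];
  NumericVector thresh = forest["thresh"], value = forest["value"];
  const int n_trees = roots.size();
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < n_trees; ++t)
      s += predict_tree(var, thresh, left, right, value, roots[t], X, i);
    out[i] = s / n_trees;
  }
  return out;
}

// Out-of-bag prediction: mean over trees whose bootstrap missed the row.
// Rows in-bag for every tree yield NA.
// [[Rcpp::export]]
NumericVector cpp_rf_predict_oob(List forest, NumericMatrix X) {
  IntegerVector var = forest["var"], left = forest["left"],
                right = forest["right"], roots = forest["roots"];
  NumericVector thresh = forest["thresh"], value = forest["value"];
  IntegerMatrix inbag = forest["inbag"];
  const int n_trees = roots.size();
  const int n = X.nrow();
  if (inbag.nrow() != n) stop("X must be the training matrix for OOB prediction");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    int k = 0;
    for (int t = 0; t < n_trees; ++t) {
      if (inbag(i, t) == 0) {
        s += predict_tree(var, thresh, left, right, value, roots[t], X, i);
        ++k;
      }
    }
    out[i] = (k > 0) ? s / k : NA_REAL;
  }
  return out;
}
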