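#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Tree-ensemble importance scoring for one target gene.
//
// Regression trees are grown on bootstrap samples of the tissues; at each
// node `mtry` candidate regulators are drawn and the split maximising the
// sum-of-squares reduction is taken. The importance credited to a regulator
// for a split is the per-sample variance reduction
//   (SS(node) - SS(left) - SS(right)) / n
// where n is the number of (bootstrap) samples in the tree, i.e. the
// fraction-weighted population-variance reduction. Importances are summed
// over splits and averaged over trees. Ties between equally good splits are
// resolved in favour of the candidate drawn first, so results are fully
// determined by `seed`.

namespace {

struct SplitResult {
  double reduction = 0.0;  // SS(parent) - SS(left) - SS(right)
  int feature = -1;
  double threshold = 0.0;
  bool found = false;
};

// Best split for one candidate feature over the samples in `idx`.
// x/y are full columns; idx indexes into them (bootstrap indices allowed,
// duplicates included).
SplitResult best_split_for_feature(const double* x, const double* y,
                                   const std::vector<int>& idx,
                                   std::vector<int>& scratch) {
  SplitResult res;
  const int m = static_cast<int>(idx.size());
  scratch = idx;
  std::sort(scratch.begin(), scratch.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  double total_sum = 0.0, total_ss = 0.0;
  for (int i = 0; i < m; ++i) {
    total_sum += y[scratch[i]];
    total_ss += y[scratch[i]] * y[scratch[i]];
  }
  const double parent_ss =
      total_ss - total_sum * total_sum / static_cast<double>(m);

  double left_sum = 0.0, left_ss = 0.0;
  for (int i = 0; i < m - 1; ++i) {
    const double yi = y[scratch[i]];
    left_sum += yi;
    left_ss += yi * yi;
    const double xa = x[scratch[i]], xb = x[scratch[i + 1]];
    if (xa == xb) continue;  // cannot split between equal values
    const int nl = i + 1, nr = m - nl;
    const double right_sum = total_sum - left_sum;
    const double right_ss = total_ss - left_ss;
    const double child_ss =
        (left_ss - left_sum * left_sum / nl) +
        (right_ss - right_sum * right_sum / nr);
    const double red = parent_ss - child_ss;
    if (!res.found || red > res.reduction) {
      res.found = true;
      res.reduction = red;
      res.threshold = (xa + xb) / 2.0;
    }
  }
  return res;
}

struct TreeGrower {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry;
  int max_depth;  // 0 = unlimited
  int n_total;    // samples in this tree (denominator for importance)
  std::mt19937& rng;
  std::vector<double>& importance;  // accumulated, length p
  std::vector<int> feat_pool;
  std::vector<int> scratch;

  TreeGrower(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
             int max_depth_, int n_total_, std::mt19937& rng_,
             std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), n_total(n_total_),
        rng(rng_), importance(imp) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  void grow(std::vector<int>& idx, int depth) {
    const int m = static_cast<int>(idx.size());
    if (m < 2) return;
    if (max_depth > 0 && depth >= max_depth) return;

    // constant response => pure node
    bool y_const = true;
    for (int i = 1; i < m; ++i)
      if (y[idx[i]] != y[idx[0]]) { y_const = false; break; }
    if (y_const) return;

    // draw mtry candidate features without replacement (partial Fisher-Yates)
    const int p = X.ncol();
    const int k = std::min(mtry, p);
    for (int i = 0; i < k; ++i) {
      std::uniform_int_distribution<int> pick(i, p - 1);
      std::swap(feat_pool[i], feat_pool[pick(rng)]);
    }

    SplitResult best;
    for (int i = 0; i < k; ++i) {
      const int j = feat_pool[i];
      SplitResult cand = best_split_for_feature(&X(0, j), &y[0], idx, scratch);
      if (cand.found && (!best.found || cand.reduction > best.reduction)) {
        best = cand;
        best.feature = j;
      }
    }
    if (!best.found || best.reduction <= 0.0) return;

    importance[best.feature] += best.reduction / static_cast<double>(n_total);

    std::vector<int> left, right;
    left.reserve(m);
    right.reserve(m);
    const double* xj = &X(0, best.feature);
    for (int i = 0; i < m; ++i) {
      if (xj[idx[i]] <= best.threshold) left.push_back(idx[i]);
      else right.push_back(idx[i]);
    }
    if (left.empty() || right.empty()) return;  // defensive; cannot happen
    grow(left, depth + 1);
    grow(right, depth + 1);
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".forest_importance_cpp")]]
NumericVector forest_importance_cpp(NumericMatrix X, NumericVector y,
                                    int n_trees, int mtry, int max_depth,
                                    bool bootstrap, int seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (mtry < 1) stop("mtry must be >= 1");

  std::vector<double> importance(p, 0.0);
  std::mt19937 rng(static_cast<unsigned int>(seed));

  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    if (bootstrap) {
      std::uniform_int_distribution<int> pick(0, n - 1);
      for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    TreeGrower grower(X, y, mtry, max_depth, n, rng, importance);
    grower.grow(idx, 0);
  }

  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = importance[j] / n_trees;
  return out;
}
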