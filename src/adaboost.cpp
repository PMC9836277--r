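// Boosted depth-limited decision trees (discrete AdaBoost / SAMME with two
// classes) with per-feature Gini impurity-decrease bookkeeping.  Written in
// C++ because the stump search scans every (feature, threshold) pair of a
// samples x features matrix at every boosting round.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct SplitResult {
  int feature = -1;          // 0-based; -1 means no impurity-reducing split
  double threshold = 0.0;    // go left if x <= threshold
  double decrease = 0.0;     // weighted impurity decrease of this split
};

inline double gini2(double w1, double wtot) {
  if (wtot <= 0.0) return 0.0;
  double p1 = w1 / wtot;
  return 2.0 * p1 * (1.0 - p1);
}

// Best weighted-Gini split over the member set, scanning each feature's
// precomputed global sort order.  member[i] != 0 marks node membership.
SplitResult best_split(const NumericMatrix& X,
                       const IntegerVector& y,
                       const std::vector<double>& w,
                       const std::vector<int>& order,  // p blocks of n
                       const std::vector<char>& member,
                       int n, int p) {
  double w_tot = 0.0, w1_tot = 0.0;
  for (int i = 0; i < n; ++i) {
    if (member[i]) { w_tot += w[i]; w1_tot += w[i] * y[i]; }
  }
  SplitResult best;
  if (w_tot <= 0.0) return best;
  const double parent = w_tot * gini2(w1_tot, w_tot);
  for (int j = 0; j < p; ++j) {
    const int* ord = &order[(size_t)j * n];
    const double* xj = &X(0, j);
    double wl = 0.0, wl1 = 0.0;
    double prev = std::numeric_limits<double>::quiet_NaN();
    for (int t = 0; t < n; ++t) {
      int i = ord[t];
      if (!member[i]) continue;
      double x = xj[i];
      if (!ISNAN(prev) && x > prev && wl > 0.0 && wl < w_tot) {
        double wr = w_tot - wl;
        double dec = parent - wl * gini2(wl1, wl) - wr * gini2(w1_tot - wl1, wr);
        if (dec > best.decrease + 1e-15) {
          best.decrease = dec;
          best.feature = j;
          best.threshold = 0.5 * (prev + x);
        }
      }
      wl += w[i];
      wl1 += w[i] * y[i];
      prev = x;
    }
  }
  return best;
}

struct TreeNode {
  int feature = -1;      // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int pred = 0;
};

void grow(const NumericMatrix& X, const IntegerVector& y,
          const std::vector<double>& w, const std::vector<int>& order,
          std::vector<char>& member, int n, int p, int depth, int max_depth,
          std::vector<TreeNode>& nodes, int node_id,
          std::vector<double>& decrease) {
  // leaf prediction: weighted majority (tie -> 0)
  double w_tot = 0.0, w1 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (member[i]) { w_tot += w[i]; w1 += w[i] * y[i]; }
  }
  nodes[node_id].pred = (w1 > 0.5 * w_tot) ? 1 : 0;
  if (depth >= max_depth) return;
  SplitResult s = best_split(X, y, w, order, member, n, p);
  if (s.feature < 0) return;
  decrease[s.feature] += s.decrease;
  nodes[node_id].feature = s.feature;
  nodes[node_id].threshold = s.threshold;
  std::vector<char> left_member(n, 0), right_member(n, 0);
  for (int i = 0; i < n; ++i) {
    if (!member[i]) continue;
    if (X(i, s.feature) <= s.threshold) left_member[i] = 1;
    else right_member[i] = 1;
  }
  nodes[node_id].left = (int)nodes.size();
  nodes.push_back(TreeNode());
  grow(X, y, w, order, left_member, n, p, depth + 1, max_depth,
       nodes, nodes[node_id].left, decrease);
  nodes[node_id].right = (int)nodes.size();
  nodes.push_back(TreeNode());
  grow(X, y, w, order, right_member, n, p, depth + 1, max_depth,
       nodes, nodes[node_id].right, decrease);
}

int predict_one(const std::vector<TreeNode>& nodes, const NumericMatrix& X,
                int i) {
  int id = 0;
  while (nodes[id].feature >= 0) {
    id = (X(i, nodes[id].feature) <= nodes[id].threshold)
         ? nodes[id].left : nodes[id].right;
  }
  return nodes[id].pred;
}

}  // namespace

// [[Rcpp::export(name = ".adaboost_fit_cpp")]]
List adaboost_fit_cpp(NumericMatrix X, IntegerVector y,
                      int n_estimators, int max_depth) {
  const int n = X.nrow(), p = X.ncol();
  if (n_estimators < 1) stop("n_estimators must be >= 1");
  if (max_depth < 1) stop("max_depth must be >= 1");

  // global per-feature sort orders (stable, ties by row index)
  std::vector<int> order((size_t)p * n);
  {
    std::vector<int> idx(n);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) idx[i] = i;
      const double* xj = &X(0, j);
      std::stable_sort(idx.begin(), idx.end(),
                       [&](int a, int b) { return xj[a] < xj[b]; });
      std::copy(idx.begin(), idx.end(), order.begin() + (size_t)j * n);
    }
  }

  std::vector<double> w(n, 1.0 / n);
  NumericVector score_sum(p);
  NumericVector alphas;
  NumericVector errors;
  double alpha_total = 0.0;
  int n_trees = 0;

  for (int round_i = 0; round_i < n_estimators; ++round_i) {
    std::vector<TreeNode> nodes(1);
    std::vector<double> decrease(p, 0.0);
    std::vector<char> member(n, 1);
    grow(X, y, w, order, member, n, p, 0, max_depth, nodes, 0, decrease);

    if (nodes.size() == 1) break;  // no impurity-reducing split exists

    double err = 0.0;
    std::vector<char> miss(n, 0);
    for (int i = 0; i < n; ++i) {
      if (predict_one(nodes, X, i) != y[i]) { miss[i] = 1; err += w[i]; }
    }

    if (err <= 1e-12) {
      // perfect weak learner: keep it with unit weight and stop
      for (int j = 0; j < p; ++j) score_sum[j] += decrease[j];
      alpha_total += 1.0;
      alphas.push_back(1.0);
      errors.push_back(err);
      ++n_trees;
      break;
    }
    if (err >= 0.5) break;  // weak learner no better than chance: discard

    double alpha = std::log((1.0 - err) / err);
    for (int j = 0; j < p; ++j) score_sum[j] += alpha * decrease[j];
    alpha_total += alpha;
    alphas.push_back(alpha);
    errors.push_back(err);
    ++n_trees;

    double w_sum = 0.0;
    for (int i = 0; i < n; ++i) {
      if (miss[i]) w[i] *= std::exp(alpha);
      w_sum += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= w_sum;
  }

  NumericVector scores(p);
  if (alpha_total > 0.0) {
    for (int j = 0; j < p; ++j) scores[j] = score_sum[j] / alpha_total;
  }
  return List::create(_["scores"] = scores,
                      _["alphas"] = alphas,
                      _["errors"] = errors,
                      _["n_trees"] = n_trees);
}
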