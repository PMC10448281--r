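// Greedy binary CART trees (Gini for classification, variance for
// regression) and a logistic-loss gradient-boosting ensemble built on the
// regression trees. Kept minimal on purpose: exact greedy splits, no
// pruning, deterministic tie-breaking (lowest feature index, first
// threshold wins), impurity-decrease feature importances.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  // flat node arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right, n_node;
  std::vector<double> value;  // leaf: prediction; internal: node mean/p
};

struct Builder {
  const NumericMatrix &X;
  const std::vector<double> &y;   // class 0/1 or regression target
  const std::vector<double> &h;   // per-sample hessian (empty -> mean leaf)
  bool classif;
  int max_depth, min_leaf;
  Tree tree;
  std::vector<double> importance;  // per feature, gain * n_node

  Builder(const NumericMatrix &X_, const std::vector<double> &y_,
          const std::vector<double> &h_, bool classif_, int max_depth_,
          int min_leaf_)
      : X(X_), y(y_), h(h_), classif(classif_), max_depth(max_depth_),
        min_leaf(min_leaf_), importance(X_.ncol(), 0.0) {}

  double impurity(double sum, double sumsq, double n) const {
    if (classif) {
      double p = sum / n;
      return 1.0 - p * p - (1.0 - p) * (1.0 - p);  // Gini
    }
    double m = sum / n;
    return sumsq / n - m * m;  // variance
  }

  double leaf_value(const std::vector<int> &idx) const {
    double s = 0.0;
    for (int i : idx) s += y[i];
    if (h.empty()) return s / idx.size();
    double hs = 0.0;
    for (int i : idx) hs += h[i];
    double v = s / std::max(hs, 1e-12);
    // Newton leaf step for logistic loss; clip for near-pure nodes
    return std::max(-8.0, std::min(8.0, v));
  }

  int build(std::vector<int> &idx, int depth) {
    const int n = (int)idx.size();
    double sum = 0.0, sumsq = 0.0;
    for (int i : idx) { sum += y[i]; sumsq += y[i] * y[i]; }
    const double imp = impurity(sum, sumsq, n);

    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(NA_REAL);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.n_node.push_back(n);
    tree.value.push_back(leaf_value(idx));

    if (depth >= max_depth || n < 2 * min_leaf || imp <= 1e-15) return node;

    int best_f = -1, best_i = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<int> ord(idx);

    for (int f = 0; f < X.ncol(); ++f) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b;  // stable under duplicate values
      });
      double ls = 0.0, lss = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        double yi = y[ord[i]];
        ls += yi; lss += yi * yi;
        if (X(ord[i], f) == X(ord[i + 1], f)) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double gain = imp - ((double)nl / n) * impurity(ls, lss, nl) -
                      ((double)nr / n) * impurity(sum - ls, sumsq - lss, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_i = i;
          best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> lidx, ridx;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
    importance[best_f] += best_gain * n;

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(lidx, depth + 1);
    tree.right[node] = build(ridx, depth + 1);
    return node;
  }
};

List tree_as_list(const Tree &t) {
  return List::create(
      _["feature"] = wrap(t.feature), _["threshold"] = wrap(t.threshold),
      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
      _["n_node"] = wrap(t.n_node), _["value"] = wrap(t.value));
}

Tree tree_from_list(List l) {
  Tree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<double>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.n_node = as<std::vector<int>>(l["n_node"]);
  t.value = as<std::vector<double>>(l["value"]);
  return t;
}

double tree_predict_row(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  return t.value[node];
}

}  // namespace

// [[Rcpp::export(name = ".cart_fit")]]
List cart_fit(NumericMatrix X, NumericVector y, bool classif, int max_depth,
              int min_leaf) {
  std::vector<double> yy = as<std::vector<double>>(y);
  std::vector<double> h;  // empty: mean leaves
  Builder b(X, yy, h, classif, max_depth, min_leaf);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  b.build(idx, 0);
  return List::create(_["tree"] = tree_as_list(b.tree),
                      _["importance"] = wrap(b.importance));
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List fit, NumericMatrix X) {
  Tree t = tree_from_list(fit["tree"]);
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = tree_predict_row(t, X, i);
  return out;
}

// [[Rcpp::export(name = ".gbm_fit")]]
List gbm_fit(NumericMatrix X, NumericVector y, int n_rounds,
             double learning_rate, int max_depth, int min_leaf) {
  const int n = X.nrow();
  double ybar = mean(y);
  double p0 = std::max(1e-6, std::min(1.0 - 1e-6, ybar));
  double F0 = std::log(p0 / (1.0 - p0));
  std::vector<double> F(n, F0), r(n), h(n);
  std::vector<double> importance(X.ncol(), 0.0);
  List trees(n_rounds);

  std::vector<int> idx0(n);
  for (int i = 0; i < n; ++i) idx0[i] = i;

  for (int m = 0; m < n_rounds; ++m) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - p;          // negative gradient of logistic loss
      h[i] = p * (1.0 - p);     // hessian, used for Newton leaf values
    }
    Builder b(X, r, h, false, max_depth, min_leaf);
    std::vector<int> idx(idx0);
    b.build(idx, 0);
    for (int i = 0; i < n; ++i)
      F[i] += learning_rate * tree_predict_row(b.tree, X, i);
    for (int f = 0; f < X.ncol(); ++f) importance[f] += b.importance[f];
    trees[m] = tree_as_list(b.tree);
  }
  return List::create(_["F0"] = F0, _["learning_rate"] = learning_rate,
                      _["trees"] = trees, _["importance"] = wrap(importance));
}

// [[Rcpp::export(name = ".gbm_predict")]]
NumericVector gbm_predict(List fit, NumericMatrix X) {
  double F0 = fit["F0"];
  double lr = fit["learning_rate"];
  List trees = fit["trees"];
  NumericVector out(X.nrow(), F0);
  for (int m = 0; m < trees.size(); ++m) {
    Tree t = tree_from_list(trees[m]);
    for (int i = 0; i < X.nrow(); ++i) out[i] += lr * tree_predict_row(t, X, i);
  }
  for (int i = 0; i < X.nrow(); ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
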