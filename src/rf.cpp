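// Random forest for binary classification: CART trees on the Gini
// criterion, bootstrap resampling, mtry feature subsampling and impurity
// importance. Uses R's RNG so forests are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> pred;      // P(class 1) in node
};

int rand_int(int n) {
  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// grow one node (recursively); idx holds the bootstrap row indices
int grow(const NumericMatrix &X, const IntegerVector &y, std::vector<int> &idx,
         int lo, int hi, int mtry, int min_node, TreeNodes &T,
         std::vector<double> &importance, std::vector<int> &feat_pool) {
  int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  int node = (int)T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back((double)pos / n);
  if (n < 2 * min_node || pos == 0 || pos == n) return node;

  int p = X.ncol();
  double neg = n - pos;
  double parent_score = (double)pos * pos / n + neg * neg / n;
  double best_gain = 0.0;
  int best_f = -1;
  double best_thr = 0.0;

  // partial Fisher-Yates draw of mtry distinct features
  for (int j = 0; j < mtry; ++j) {
    int k = j + rand_int(p - j);
    std::swap(feat_pool[j], feat_pool[k]);
  }
  std::vector<std::pair<double, int> > vals(n);
  for (int j = 0; j < mtry; ++j) {
    int f = feat_pool[j];
    for (int i = 0; i < n; ++i) {
      int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    double posL = 0.0, negL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      if (vals[i].second) posL += 1.0; else negL += 1.0;
      if (vals[i].first == vals[i + 1].first) continue;
      double nL = i + 1.0, nR = n - nL;
      if (nL < min_node || nR < min_node) continue;
      double posR = pos - posL, negR = neg - negL;
      double score = (posL * posL + negL * negL) / nL +
                     (posR * posR + negR * negR) / nR;
      double gain = score - parent_score;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node; // numeric ties; keep leaf

  importance[best_f] += best_gain;
  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  int l = grow(X, y, idx, lo, mid, mtry, min_node, T, importance, feat_pool);
  int r = grow(X, y, idx, mid, hi, mtry, min_node, T, importance, feat_pool);
  T.left[node] = l;
  T.right[node] = r;
  return node;
}

NumericMatrix pack(const TreeNodes &T) {
  int m = (int)T.feature.size();
  NumericMatrix out(m, 5);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = T.feature[i];
    out(i, 1) = T.threshold[i];
    out(i, 2) = T.left[i];
    out(i, 3) = T.right[i];
    out(i, 4) = T.pred[i];
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int num_trees, int mtry,
                  int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (min_node < 1) min_node = 1;
  List forest(num_trees);
  std::vector<double> importance(p, 0.0);
  std::vector<int> feat_pool(p);
  std::vector<int> idx(n);
  for (int t = 0; t < num_trees; ++t) {
    for (int i = 0; i < p; ++i) feat_pool[i] = i;
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n); // bootstrap
    TreeNodes T;
    grow(X, y, idx, 0, n, mtry, min_node, T, importance, feat_pool);
    forest[t] = pack(T);
  }
  NumericVector imp(p);
  for (int i = 0; i < p; ++i) imp[i] = importance[i] / num_trees;
  return List::create(_["forest"] = forest, _["importance"] = imp,
                      _["num_trees"] = num_trees, _["mtry"] = mtry,
                      _["min_node"] = min_node);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List fit, NumericMatrix X) {
  List forest = fit["forest"];
  int n = X.nrow(), nt = forest.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix T = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)T(node, 0) >= 0) {
        int f = (int)T(node, 0);
        node = (X(i, f) <= T(node, 1)) ? (int)T(node, 2) : (int)T(node, 3);
      }
      out[i] += T(node, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
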