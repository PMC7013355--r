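#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <random>
using namespace Rcpp;

// Entropy-split random forest for binary voxel classification.
// Each internal node draws a fresh random candidate set (feature indices x
// quantile thresholds) and keeps the split maximizing the information gain
// I = H(parent) - sum |child|/|parent| * H(child), entropies in bits.
// Leaves store the empirical class histogram; the ensemble posterior is the
// plain average of the reached leaves' positive-class frequencies.

static inline double h2(double p) {
  double h = 0.0;
  if (p > 0) h -= p * std::log2(p);
  if (p < 1) h -= (1 - p) * std::log2(1 - p);
  return h;
}

struct TreeBuf {
  std::vector<int> feature, left, right, n_node;
  std::vector<double> threshold, p_pos, gain;
  int add() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    n_node.push_back(0); threshold.push_back(NA_REAL);
    p_pos.push_back(0.0); gain.push_back(NA_REAL);
    return (int)feature.size() - 1;
  }
};

static void grow(TreeBuf &T, int node, std::vector<int> &idx,
                 const NumericMatrix &X, const IntegerVector &y,
                 int depth, int max_depth, int n_feat, int n_thresh,
                 int min_leaf, std::mt19937 &rng) {
  const int n = (int)idx.size();
  int npos = 0;
  for (int i : idx) npos += y[i];
  T.n_node[node] = n;
  T.p_pos[node] = n ? (double)npos / n : 0.0;
  if (depth >= max_depth || npos == 0 || npos == n || n < 2 * min_leaf) return;

  const double Hp = h2(T.p_pos[node]);
  const int d = X.ncol();
  std::vector<int> feats(d);
  for (int f = 0; f < d; ++f) feats[f] = f;
  std::shuffle(feats.begin(), feats.end(), rng);

  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<double> vals(n);
  for (int fi = 0; fi < n_feat && fi < d; ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) vals[i] = X(idx[i], f);
    std::vector<double> sv(vals);
    std::sort(sv.begin(), sv.end());
    if (sv.front() == sv.back()) continue;
    for (int t = 0; t < n_thresh; ++t) {
      // quantile thresholds strictly inside the node's value range
      double q = (t + 1.0) / (n_thresh + 1.0);
      double thr = sv[(size_t)std::min((double)n - 1, std::floor(q * n))];
      if (thr <= sv.front()) continue; // empty left child
      int nl = 0, pl = 0;
      for (int i = 0; i < n; ++i)
        if (vals[i] < thr) { ++nl; pl += y[idx[i]]; }
      int nr = n - nl, pr = npos - pl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double I = Hp - ((double)nl / n) * h2((double)pl / nl)
                    - ((double)nr / n) * h2((double)pr / nr);
      if (I > best_gain + 1e-12) { best_gain = I; best_f = f; best_thr = thr; }
    }
  }
  if (best_f < 0) return;

  std::vector<int> il, ir;
  il.reserve(n); ir.reserve(n);
  for (int i : idx)
    if (X(i, best_f) < best_thr) il.push_back(i); else ir.push_back(i);
  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  T.gain[node] = best_gain;
  int L = T.add(), R = T.add();
  T.left[node] = L; T.right[node] = R;
  grow(T, L, il, X, y, depth + 1, max_depth, n_feat, n_thresh, min_leaf, rng);
  grow(T, R, ir, X, y, depth + 1, max_depth, n_feat, n_thresh, min_leaf, rng);
}

// [[Rcpp::export]]
List train_forest_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                      int max_depth, int n_feat, int n_thresh, int min_leaf,
                      int seed) {
  std::mt19937 rng((unsigned)seed);
  List trees(n_trees);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  for (int t = 0; t < n_trees; ++t) {
    TreeBuf T;
    int root = T.add();
    std::vector<int> id(idx);
    grow(T, root, id, X, y, 0, max_depth, n_feat, n_thresh, min_leaf, rng);
    trees[t] = List::create(
      _["feature"] = IntegerVector(T.feature.begin(), T.feature.end()),
      _["threshold"] = NumericVector(T.threshold.begin(), T.threshold.end()),
      _["left"] = IntegerVector(T.left.begin(), T.left.end()),
      _["right"] = IntegerVector(T.right.begin(), T.right.end()),
      _["p_pos"] = NumericVector(T.p_pos.begin(), T.p_pos.end()),
      _["n_node"] = IntegerVector(T.n_node.begin(), T.n_node.end()),
      _["gain"] = NumericVector(T.gain.begin(), T.gain.end()));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], p_pos = tr["p_pos"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) < threshold[node] ? left[node] : right[node];
      out[i] += p_pos[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
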