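// Minimal extremely randomized trees (binary classification) for the
// Monte Carlo combination search: at every node, each of mtry candidate
// features receives one uniformly drawn cut point between its node-local
// min and max; the candidate with the largest Gini decrease splits the
// node. No bootstrap (each tree sees the full training set); leaves store
// the class-1 fraction and predictions average over trees. Gini importance
// is accumulated per feature.

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> leaf;   // class-1 fraction
};

double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

int grow(Tree &tree, const NumericMatrix &X, const IntegerVector &y,
         std::vector<int> &idx, int lo, int hi, int mtry, int min_split,
         std::mt19937 &rng, std::vector<double> &imp) {
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  int node = tree.feat.size();
  tree.feat.push_back(-1);
  tree.thr.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.leaf.push_back((double)n1 / n);
  if (n < min_split || n1 == 0 || n1 == n) return node;

  int p = X.ncol();
  double parent = gini(n1, n);
  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = mtry < p ? mtry : p;
  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  for (int t = 0; t < m; ++t) {
    std::uniform_int_distribution<int> pick(t, p - 1);
    std::swap(feats[t], feats[pick(rng)]);
    int f = feats[t];
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = lo; i < hi; ++i) {
      double v = X(idx[i], f);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    if (!(mx > mn)) continue;
    std::uniform_real_distribution<double> cut(mn, mx);
    double thr = cut(rng);
    int nl = 0, nl1 = 0;
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], f) <= thr) { ++nl; nl1 += y[idx[i]]; }
    }
    if (nl == 0 || nl == n) continue;
    int nr = n - nl, nr1 = n1 - nl1;
    double gain = parent - ((double)nl / n) * gini(nl1, nl)
                         - ((double)nr / n) * gini(nr1, nr);
    if (gain > best_gain) { best_gain = gain; best_f = f; best_thr = thr; }
  }
  if (best_f < 0) return node;

  // partition idx[lo,hi) in place
  int i = lo, j = hi - 1;
  while (i <= j) {
    if (X(idx[i], best_f) <= best_thr) ++i;
    else std::swap(idx[i], idx[j--]);
  }
  imp[best_f] += best_gain * n;
  tree.feat[node] = best_f;
  tree.thr[node] = best_thr;
  int l = grow(tree, X, y, idx, lo, i, mtry, min_split, rng, imp);
  tree.left[node] = l;
  int r = grow(tree, X, y, idx, i, hi, mtry, min_split, rng, imp);
  tree.right[node] = r;
  return node;
}

double predict_one(const Tree &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree.feat[node] >= 0) {
    node = X(row, tree.feat[node]) <= tree.thr[node] ? tree.left[node]
                                                     : tree.right[node];
  }
  return tree.leaf[node];
}

} // namespace

// [[Rcpp::export(.et_fit_predict)]]
List et_fit_predict(NumericMatrix Xtr, IntegerVector ytr, NumericMatrix Xte,
                    int num_trees, int mtry, int min_split, int seed) {
  int ntr = Xtr.nrow(), nte = Xte.nrow(), p = Xtr.ncol();
  if (ytr.size() != ntr) stop("y length mismatch");
  if (mtry < 1) mtry = 1;
  std::mt19937 rng((unsigned)seed);
  NumericVector prob(nte, 0.0);
  std::vector<double> imp(p, 0.0);
  std::vector<int> idx(ntr);
  for (int b = 0; b < num_trees; ++b) {
    for (int i = 0; i < ntr; ++i) idx[i] = i;
    Tree tree;
    grow(tree, Xtr, ytr, idx, 0, ntr, mtry, min_split, rng, imp);
    for (int i = 0; i < nte; ++i) prob[i] += predict_one(tree, Xte, i);
  }
  for (int i = 0; i < nte; ++i) prob[i] /= num_trees;
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / num_trees;
  return List::create(_["prob"] = prob, _["importance"] = importance);
}
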