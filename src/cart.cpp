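#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Classification tree grown by recursive binary splitting on the Gini
// criterion, with a fresh random feature subset of size mtry drawn at every
// node (random-forest style). Randomness comes from R's RNG stream via
// unif_rand(), so set.seed() on the R side makes growth reproducible.

struct Tree {
  const NumericMatrix& X;
  const IntegerVector& y;  // classes 0..nclass-1
  int nclass, mtry, max_depth, min_node;
  std::vector<int> feat, left, right, pred;
  std::vector<double> thr;

  Tree(const NumericMatrix& X_, const IntegerVector& y_, int nclass_,
       int mtry_, int max_depth_, int min_node_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), max_depth(max_depth_),
        min_node(min_node_) {}

  int grow(std::vector<int>& idx, int depth) {
    std::vector<int> cnt(nclass, 0);
    for (size_t i = 0; i < idx.size(); ++i) cnt[y[idx[i]]]++;
    int maj = 0;
    for (int k = 1; k < nclass; ++k) if (cnt[k] > cnt[maj]) maj = k;

    int node = (int)feat.size();
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); pred.push_back(maj);

    int n = (int)idx.size();
    if (cnt[maj] == n || depth >= max_depth || n < min_node) return node;

    int p = X.ncol();
    std::vector<int> fidx(p);
    for (int j = 0; j < p; ++j) fidx[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(fidx[j], fidx[k]);
    }

    double parent_imp = 0.0;
    for (int k = 0; k < nclass; ++k)
      parent_imp += (double)cnt[k] * cnt[k];
    parent_imp = (double)n - parent_imp / n;  // n * gini

    int best_f = -1; double best_thr = 0.0, best_gain = 1e-10;
    std::vector<std::pair<double,int> > vals(n);
    std::vector<int> lcnt(nclass);
    for (int j = 0; j < m; ++j) {
      int f = fidx[j];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;
      std::fill(lcnt.begin(), lcnt.end(), 0);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        lcnt[vals[i].second]++; nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        int nr = n - nl;
        double sl = 0.0, sr = 0.0;
        for (int k = 0; k < nclass; ++k) {
          double rc = (double)(cnt[k] - lcnt[k]);
          sl += (double)lcnt[k] * lcnt[k];
          sr += rc * rc;
        }
        double child_imp = ((double)nl - sl / nl) + ((double)nr - sr / nr);
        double gain = parent_imp - child_imp;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> li, ri;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    if (li.empty() || ri.empty()) return node;
    feat[node] = best_f;
    thr[node] = best_thr;
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, int nclass, int mtry,
                   int max_depth, int min_node) {
  Tree t(X, y, nclass, mtry, max_depth, min_node);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  t.grow(idx, 0);
  return List::create(_["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["pred"] = wrap(t.pred));
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feat"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector thr = tree["thr"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = pred[node];
  }
  return out;
}

// Vote counts over an ensemble; rows = observations, cols = classes.
// [[Rcpp::export]]
IntegerMatrix cpp_forest_votes(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < trees.size(); ++t) {
    List tree = trees[t];
    IntegerVector feat = tree["feat"], left = tree["left"],
                  right = tree["right"], pred = tree["pred"];
    NumericVector thr = tree["thr"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      votes(i, pred[node])++;
    }
  }
  return votes;
}
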