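// Bagged classification forest with Gini splitting.
// Mirrors the classic randomForest contract: ntree bootstrap trees grown to
// purity (nodesize 1), mtry features tried per node, class probabilities as
// vote fractions, importance as the per-tree mean of total Gini decrease.
// Self-contained 64-bit RNG so results are identical across platforms.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Forest {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left iff x <= threshold
  std::vector<int> left, right;  // node indices local to the tree
  std::vector<int> pred;         // leaf class, -1 for internal
  std::vector<int> offsets;      // first node of each tree
};

// Gini "deviance" of a node: n - sum(counts^2)/n  (= n * gini impurity)
double gini_dev(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double ss = 0.0;
  for (int c : counts) ss += static_cast<double>(c) * c;
  return n - ss / n;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int nclass, mtry;
  SplitMix& rng;
  Forest& forest;
  std::vector<double>& importance;
  int tree_base;

  int build(std::vector<int>& idx) {
    int n = static_cast<int>(idx.size());
    std::vector<int> counts(nclass, 0);
    for (int i : idx) counts[y[i]]++;
    int node = static_cast<int>(forest.feature.size()) - tree_base;
    forest.feature.push_back(-1);
    forest.threshold.push_back(0.0);
    forest.left.push_back(-1);
    forest.right.push_back(-1);
    forest.pred.push_back(-1);

    int maj = 0;
    for (int c = 1; c < nclass; ++c) if (counts[c] > counts[maj]) maj = c;
    bool pure = counts[maj] == n;
    if (pure || n < 2) {
      forest.pred[tree_base + node] = maj;
      return node;
    }

    double parent_dev = gini_dev(counts, n);
    int p = X.ncol();
    // partial Fisher-Yates for mtry distinct features
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int ntry = std::min(mtry, p);
    for (int j = 0; j < ntry; ++j)
      std::swap(feats[j], feats[j + rng.unif_int(p - j)]);

    double best_dec = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int t = 0; t < ntry; ++t) {
      int f = feats[t];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      std::vector<int> lc(nclass, 0);
      std::vector<int> rc(counts);
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second]++;
        rc[vals[i].second]--;
        if (vals[i].first < vals[i + 1].first) {
          double dec = parent_dev - gini_dev(lc, i + 1) -
                       gini_dev(rc, n - i - 1);
          if (dec > best_dec) {
            best_dec = dec;
            best_f = f;
            best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
          }
        }
      }
    }
    if (best_f < 0) { // no informative split among the sampled features
      forest.pred[tree_base + node] = maj;
      return node;
    }

    importance[best_f] += best_dec;
    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    forest.feature[tree_base + node] = best_f;
    forest.threshold[tree_base + node] = best_thr;
    int l = build(lidx);
    int r = build(ridx);
    forest.left[tree_base + node] = l;
    forest.right[tree_base + node] = r;
    return node;
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, double seed) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need >= 2 training samples");
  SplitMix rng(static_cast<uint64_t>(seed));
  Forest forest;
  std::vector<double> importance(p, 0.0);
  for (int t = 0; t < ntree; ++t) {
    forest.offsets.push_back(static_cast<int>(forest.feature.size()));
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rng.unif_int(n);
    TreeBuilder tb{X, y, nclass, mtry, rng, forest, importance,
                   forest.offsets.back()};
    tb.build(boot);
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(
    _["feature"] = wrap(forest.feature),
    _["threshold"] = wrap(forest.threshold),
    _["left"] = wrap(forest.left),
    _["right"] = wrap(forest.right),
    _["pred"] = wrap(forest.pred),
    _["offsets"] = wrap(forest.offsets),
    _["importance"] = imp,
    _["nclass"] = nclass,
    _["ntree"] = ntree);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List model, NumericMatrix X) {
  IntegerVector feature = model["feature"];
  NumericVector threshold = model["threshold"];
  IntegerVector left = model["left"], right = model["right"];
  IntegerVector pred = model["pred"], offsets = model["offsets"];
  int nclass = model["nclass"], ntree = model["ntree"];
  int n = X.nrow();
  NumericMatrix votes(n, nclass);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < ntree; ++t) {
      int base = offsets[t];
      int node = 0;
      while (feature[base + node] >= 0) {
        node = (X(i, feature[base + node]) <= threshold[base + node])
                   ? left[base + node]
                   : right[base + node];
      }
      votes(i, pred[base + node]) += 1.0;
    }
    for (int c = 0; c < nclass; ++c) votes(i, c) /= ntree;
  }
  return votes;
}
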