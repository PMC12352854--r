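// Bagged randomized regression trees (extra-trees style splits).
//
// This is the package's tree-ensemble regression backend: bootstrap-bagged
// trees whose splits pick, at each node, `mtry` random features and one
// uniformly random threshold per feature, keeping the candidate with the
// largest variance reduction. Randomized thresholds keep fitting O(mtry * n)
// per node, which matters because the imputers fit one ensemble per
// predicted horizon step. A self-contained xorshift RNG makes fits
// bit-reproducible for a fixed seed, independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // child node ids
  std::vector<double> value;    // leaf prediction
};

struct Node {
  int id;
  std::vector<int> rows;
  int depth;
};

void grow(Tree &tree, const double *xp, int nrow, int ncol,
          const double *yp, std::vector<int> rows, int mtry, int min_node,
          int max_depth, XorShift &rng) {
  std::vector<Node> stack;
  tree.feature.push_back(-1); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.value.push_back(0.0);
  stack.push_back(Node{0, std::move(rows), 0});

  const int p = ncol;
  while (!stack.empty()) {
    Node node = std::move(stack.back());
    stack.pop_back();
    const std::vector<int> &r = node.rows;
    const int n = static_cast<int>(r.size());

    double sum = 0.0, sum2 = 0.0;
    for (int i : r) { sum += yp[i]; sum2 += yp[i] * yp[i]; }
    const double mean = sum / n;
    const double sse = sum2 - sum * mean;

    bool make_leaf = (n < 2 * min_node) || (node.depth >= max_depth) ||
                     (sse <= 1e-12);
    int best_f = -1;
    double best_thr = 0.0, best_score = -1.0;

    if (!make_leaf) {
      for (int t = 0; t < mtry; ++t) {
        int f = rng.below(p);
        const double *col = xp + static_cast<size_t>(f) * nrow;
        double lo = col[r[0]], hi = lo;
        for (int i : r) {
          double v = col[i];
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (hi <= lo) continue;
        double thr = lo + rng.unif() * (hi - lo);
        double lsum = 0.0, lsum2 = 0.0;
        int ln = 0;
        for (int i : r) {
          if (col[i] <= thr) { lsum += yp[i]; lsum2 += yp[i] * yp[i]; ++ln; }
        }
        if (ln < min_node || (n - ln) < min_node) continue;
        double rsum = sum - lsum, rsum2 = sum2 - lsum2;
        double lsse = lsum2 - lsum * lsum / ln;
        double rsse = rsum2 - rsum * rsum / (n - ln);
        double score = sse - lsse - rsse;
        if (score > best_score) {
          best_score = score; best_f = f; best_thr = thr;
        }
      }
      if (best_f < 0) make_leaf = true;
    }

    if (make_leaf) {
      tree.feature[node.id] = -1;
      tree.value[node.id] = mean;
      continue;
    }

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    const double *bcol = xp + static_cast<size_t>(best_f) * nrow;
    for (int i : r) {
      if (bcol[i] <= best_thr) lrows.push_back(i);
      else rrows.push_back(i);
    }

    int lid = static_cast<int>(tree.feature.size());
    tree.feature.push_back(-1); tree.threshold.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.value.push_back(0.0);
    int rid = static_cast<int>(tree.feature.size());
    tree.feature.push_back(-1); tree.threshold.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.value.push_back(0.0);

    tree.feature[node.id] = best_f;
    tree.threshold[node.id] = best_thr;
    tree.left[node.id] = lid;
    tree.right[node.id] = rid;
    stack.push_back(Node{lid, std::move(lrows), node.depth + 1});
    stack.push_back(Node{rid, std::move(rrows), node.depth + 1});
  }
}

List tree_to_list(const Tree &t) {
  return List::create(Named("feature") = wrap(t.feature),
                      Named("threshold") = wrap(t.threshold),
                      Named("left") = wrap(t.left),
                      Named("right") = wrap(t.right),
                      Named("value") = wrap(t.value));
}

} // namespace

// [[Rcpp::export]]
List forest_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int min_node, int max_depth, bool bootstrap,
                    double seed) {
  const int n = X.nrow();
  if (n == 0 || y.size() != n) stop("forest_fit_cpp: bad training data");
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = rng.below(n);
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    Tree t;
    grow(t, REAL(X), n, X.ncol(), REAL(y), std::move(rows), mtry, min_node,
         max_depth, rng);
    trees[b] = tree_to_list(t);
  }
  return trees;
}

namespace {

double tree_predict_row(const Tree &t, const double *xp, int nrow, int i) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (xp[static_cast<size_t>(t.feature[node]) * nrow + i] <=
            t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

} // namespace

// Gradient boosting with squared loss: each round fits a randomized tree to
// the current residuals and the ensemble advances by `learning_rate` times
// the tree's prediction. The package's analog of an XGBoost-style backend.
// [[Rcpp::export]]
List boost_fit_cpp(NumericMatrix X, NumericVector y, int n_rounds,
                   double learning_rate, int mtry, int min_node,
                   int max_depth, double seed) {
  const int n = X.nrow();
  if (n == 0 || y.size() != n) stop("boost_fit_cpp: bad training data");
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - base;

  List trees(n_rounds);
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  for (int b = 0; b < n_rounds; ++b) {
    Tree t;
    grow(t, REAL(X), n, X.ncol(), resid.data(), all_rows, mtry, min_node,
         max_depth, rng);
    for (int i = 0; i < n; ++i) {
      resid[i] -= learning_rate * tree_predict_row(t, REAL(X), n, i);
    }
    trees[b] = tree_to_list(t);
  }
  return List::create(Named("base") = base,
                      Named("learning_rate") = learning_rate,
                      Named("trees") = trees);
}

// [[Rcpp::export]]
NumericVector boost_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  double base = as<double>(model["base"]);
  double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  NumericVector out(n, base);
  const double *xp = REAL(X);
  for (int b = 0; b < trees.size(); ++b) {
    List tree = trees[b];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    NumericVector value = tree["value"];
    const int *fp = INTEGER(feature);
    const double *tp = REAL(threshold);
    const int *lp = INTEGER(left), *rp = INTEGER(right);
    const double *vp = REAL(value);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (fp[node] >= 0) {
        node = (xp[static_cast<size_t>(fp[node]) * n + i] <= tp[node])
                 ? lp[node] : rp[node];
      }
      out[i] += lr * vp[node];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tree = trees[b];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    NumericVector value = tree["value"];
    const double *xp = REAL(X);
    const int *fp = INTEGER(feature);
    const double *tp = REAL(threshold);
    const int *lp = INTEGER(left), *rp = INTEGER(right);
    const double *vp = REAL(value);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (fp[node] >= 0) {
        node = (xp[static_cast<size_t>(fp[node]) * n + i] <= tp[node])
                 ? lp[node] : rp[node];
      }
      out[i] += vp[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
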