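// Regression random forest: bagged CART trees with variance-reduction splits
// and per-node random feature subsampling (mtry). Self-contained so that the
// ensemble is deterministic given (data, n_trees, mtry, min_split, seed) on
// any platform: all randomness comes from one std::mt19937 stream per forest,
// never from R's RNG.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNodes {
  // parallel arrays; var = -1 marks a leaf
  std::vector<int> var;
  std::vector<double> split;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> pred;

  int add_node() {
    var.push_back(-1);
    split.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0.0);
    return static_cast<int>(var.size()) - 1;
  }
};

struct WorkItem {
  int node;
  int lo;  // segment [lo, hi) of the bootstrap index vector
  int hi;
};

// Best split of one node over `mtry` randomly chosen features.
// Returns true iff a variance-reducing split exists among the candidates.
bool best_split(const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int lo, int hi, int mtry,
                std::mt19937& rng, std::vector<int>& feat_pool,
                int& out_var, double& out_split) {
  const int n = hi - lo;
  const int p = X.ncol();

  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[idx[i]];

  // partial Fisher-Yates: first mtry entries of feat_pool are the candidates
  for (int k = 0; k < mtry; ++k) {
    std::uniform_int_distribution<int> pick(k, p - 1);
    std::swap(feat_pool[k], feat_pool[pick(rng)]);
  }

  double best_score = -1.0;  // sum of child SSE reductions, must be > 0
  out_var = -1;

  std::vector<std::pair<double, double>> xy(n);
  const double parent_sse_base = sum * sum / n;  // constant shift, use gain form

  for (int k = 0; k < mtry; ++k) {
    const int f = feat_pool[k];
    for (int i = 0; i < n; ++i) {
      const int row = idx[lo + i];
      xy[i] = {X(row, f), y[row]};
    }
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;  // constant feature

    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += xy[i].second;
      if (xy[i].first == xy[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      // maximising between-child score == minimising child SSE
      const double score =
          lsum * lsum / nl + (sum - lsum) * (sum - lsum) / nr;
      if (score > best_score + 1e-12 && score > parent_sse_base) {
        best_score = score;
        out_var = f;
        out_split = 0.5 * (xy[i].first + xy[i + 1].first);
      }
    }
  }
  return out_var >= 0;
}

void grow_tree(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int min_split, int mtry,
               std::mt19937& rng, TreeNodes& tree) {
  const int p = X.ncol();
  std::vector<int> feat_pool(p);
  for (int f = 0; f < p; ++f) feat_pool[f] = f;

  std::vector<WorkItem> stack;
  const int root = tree.add_node();
  stack.push_back({root, 0, static_cast<int>(idx.size())});

  while (!stack.empty()) {
    const WorkItem w = stack.back();
    stack.pop_back();
    const int n = w.hi - w.lo;

    double sum = 0.0, sumsq = 0.0;
    for (int i = w.lo; i < w.hi; ++i) {
      sum += y[idx[i]];
      sumsq += y[idx[i]] * y[idx[i]];
    }
    const double mean = sum / n;
    tree.pred[w.node] = mean;

    const double sse = sumsq - sum * mean;
    if (n < min_split || sse <= 1e-12) continue;  // leaf

    int var;
    double split;
    if (!best_split(X, y, idx, w.lo, w.hi, mtry, rng, feat_pool, var, split))
      continue;  // no informative candidate feature: leaf

    // in-place partition of the segment
    int mid = w.lo;
    for (int i = w.lo; i < w.hi; ++i)
      if (X(idx[i], var) <= split) std::swap(idx[i], idx[mid++]);

    tree.var[w.node] = var;
    tree.split[w.node] = split;
    const int l = tree.add_node();
    const int r = tree.add_node();
    tree.left[w.node] = l;
    tree.right[w.node] = r;
    stack.push_back({l, w.lo, mid});
    stack.push_back({r, mid, w.hi});
  }
}

double tree_predict_row(const List& tree, const NumericMatrix& X, int row) {
  const IntegerVector var = tree["var"];
  const NumericVector split = tree["split"];
  const IntegerVector left = tree["left"];
  const IntegerVector right = tree["right"];
  const NumericVector pred = tree["pred"];
  int node = 0;
  while (var[node] >= 0)
    node = (X(row, var[node]) <= split[node]) ? left[node] : right[node];
  return pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_split, int seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (n < 1 || p < 1) stop("empty training data");
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, ncol(X)]");

  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_int_distribution<int> draw(0, n - 1);

  List trees(n_trees);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_n(n, 0);
  std::vector<int> inbag(n);
  std::vector<int> idx;
  idx.reserve(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      const int r = draw(rng);
      idx.push_back(r);
      inbag[r]++;
    }

    TreeNodes tn;
    grow_tree(X, y, idx, min_split, mtry, rng, tn);
    List tree = List::create(
        Named("var") = wrap(tn.var), Named("split") = wrap(tn.split),
        Named("left") = wrap(tn.left), Named("right") = wrap(tn.right),
        Named("pred") = wrap(tn.pred));
    trees[t] = tree;

    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        oob_sum[i] += tree_predict_row(tree, X, i);
        oob_n[i]++;
      }
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  double sse = 0.0;
  int n_oob = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_n[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_n[i];
      const double e = oob_pred[i] - y[i];
      sse += e * e;
      n_oob++;
    }
  }
  const double oob_rmse = (n_oob > 0) ? std::sqrt(sse / n_oob) : NA_REAL;

  return List::create(Named("trees") = trees, Named("oob_pred") = oob_pred,
                      Named("oob_rmse") = oob_rmse,
                      Named("n_oob") = n_oob);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int nt = trees.size();
  if (nt < 1) stop("empty forest");
  NumericVector out(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    List tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
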