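// Regression random forest recording per-split improvements, the primitive
// behind gradient-forest turnover functions. One forest per SNP: bootstrap
// per tree, mtry candidate predictors per node, variance-reduction splits,
// out-of-bag predictions for R2. Split records (predictor, split value,
// impurity decrease) are returned for cumulative-importance aggregation.
//
// Split search uses presorted predictor orders: each node keeps, per
// eligible predictor, its bootstrap rows in predictor-sorted order, so the
// best split is found by a linear scan and children are built by a stable
// partition (no per-node sorting).
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitRec {
  int var;
  double value;
  double improvement;
};

struct Node {
  int var = -1;        // -1: leaf
  double value = 0.0;  // split value or leaf mean
  int left = -1, right = -1;
};

// per-node data: for each eligible predictor (dense index), the node's
// bootstrap rows sorted by that predictor
typedef std::vector<std::vector<int>> FeatLists;

struct Forest {
  const double* const* xcol;  // p column pointers
  const double* y;
  const std::vector<int>& cand;  // eligible predictor columns
  int mtry, min_node;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<SplitRec>& splits;
  std::vector<int> pool;  // scratch for mtry sampling (dense cand indices)

  Forest(const double* const* xcol, const double* y,
         const std::vector<int>& cand, int mtry, int min_node,
         std::mt19937& rng, std::vector<SplitRec>& splits)
    : xcol(xcol), y(y), cand(cand), mtry(mtry), min_node(min_node),
      rng(rng), splits(splits), pool(cand.size()) {}

  int build(FeatLists& fl) {
    const std::vector<int>& rows = fl[0];
    int n = (int)rows.size();
    double sum = 0.0, sumsq = 0.0;
    for (int r : rows) { sum += y[r]; sumsq += y[r] * y[r]; }
    double ss = sumsq - sum * sum / n;
    int me = (int)nodes.size();
    nodes.push_back(Node());
    if (n <= min_node || ss <= 1e-12) {
      nodes[me].value = sum / n;
      return me;
    }
    int nf = (int)cand.size();
    for (int k = 0; k < nf; ++k) pool[k] = k;
    int m = std::min(mtry, nf);
    double best_gain = 1e-12, best_val = 0.0;
    int best_f = -1;
    for (int t = 0; t < m; ++t) {
      std::uniform_int_distribution<int> pick(t, nf - 1);
      std::swap(pool[t], pool[pick(rng)]);
      int fd = pool[t];                 // dense index into fl / cand
      const double* x = xcol[cand[fd]];
      const std::vector<int>& sr = fl[fd];
      double ls = 0.0, lq = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        double v = y[sr[k]];
        ls += v; lq += v * v;
        double xa = x[sr[k]], xb = x[sr[k + 1]];
        if (xa == xb) continue;
        int nl = k + 1, nr = n - nl;
        double rs = sum - ls, rq = sumsq - lq;
        double gain = ss - (lq - ls * ls / nl) - (rq - rs * rs / nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = fd;
          best_val = 0.5 * (xa + xb);
        }
      }
    }
    if (best_f < 0) {
      nodes[me].value = sum / n;
      return me;
    }
    int col = cand[best_f];
    splits.push_back({col, best_val, best_gain});
    const double* xs = xcol[col];
    FeatLists left(nf), right(nf);
    for (int fd = 0; fd < nf; ++fd) {
      left[fd].reserve(n / 2);
      right[fd].reserve(n / 2);
      for (int r : fl[fd]) {
        if (xs[r] <= best_val) left[fd].push_back(r);
        else right[fd].push_back(r);
      }
    }
    { FeatLists drop; drop.swap(fl); }  // free before recursing
    nodes[me].var = col;
    nodes[me].value = best_val;
    int l = build(left);
    int r = build(right);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  double predict(int node, int row) const {
    while (nodes[node].var >= 0)
      node = (xcol[nodes[node].var][row] <= nodes[node].value)
               ? nodes[node].left : nodes[node].right;
    return nodes[node].value;
  }
};

}  // namespace

// [[Rcpp::export(name = ".fit_snp_forest")]]
List fit_snp_forest(NumericMatrix X, NumericVector y, IntegerVector candidates,
                    int n_trees, int mtry, int min_node, int seed) {
  int n = X.nrow();
  if (y.size() != n) stop("X/y dimension mismatch");
  int p = X.ncol();
  std::vector<const double*> xcol(p);
  for (int j = 0; j < p; ++j) xcol[j] = &X(0, j);
  std::vector<int> cand(candidates.begin(), candidates.end());
  int nf = (int)cand.size();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  // global row order per eligible predictor
  std::vector<std::vector<int>> global_order(nf);
  for (int fd = 0; fd < nf; ++fd) {
    std::vector<int>& o = global_order[fd];
    o.resize(n);
    for (int r = 0; r < n; ++r) o[r] = r;
    const double* x = xcol[cand[fd]];
    std::stable_sort(o.begin(), o.end(),
                     [x](int a, int b) { return x[a] < x[b]; });
  }

  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<SplitRec> splits;
  std::vector<int> count(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(count.begin(), count.end(), 0);
    for (int k = 0; k < n; ++k) count[boot(rng)] += 1;
    FeatLists fl(nf);
    for (int fd = 0; fd < nf; ++fd) {
      fl[fd].reserve(n);
      for (int r : global_order[fd])
        for (int c = 0; c < count[r]; ++c) fl[fd].push_back(r);
    }
    Forest f(xcol.data(), REAL(y), cand, mtry, min_node, rng, splits);
    f.nodes.reserve(2 * n / std::max(1, min_node));
    int root = f.build(fl);
    for (int r = 0; r < n; ++r) {
      if (count[r] == 0) {
        oob_sum[r] += f.predict(root, r);
        oob_cnt[r] += 1;
      }
    }
  }

  int ns = (int)splits.size();
  IntegerVector sv(ns);
  NumericVector sval(ns), simp(ns);
  for (int k = 0; k < ns; ++k) {
    sv[k] = splits[k].var + 1;  // 1-based for R
    sval[k] = splits[k].value;
    simp[k] = splits[k].improvement;
  }
  NumericVector oob(n);
  for (int r = 0; r < n; ++r)
    oob[r] = oob_cnt[r] > 0 ? oob_sum[r] / oob_cnt[r] : NA_REAL;
  return List::create(_["oob_pred"] = oob, _["split_var"] = sv,
                      _["split_value"] = sval, _["split_improvement"] = simp);
}
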