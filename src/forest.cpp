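// Compact random forest for binary classification, used as the importance
// backend of the Boruta selector. Trees are depth-limited CART (Gini
// splits, bootstrap resampling, mtry feature subsampling). Two importance
// measures: the Z-score of out-of-bag permutation importance (the
// conventional Boruta input) and mean decrease in Gini impurity.
// Deterministic for a fixed seed (own mt19937, independent of R's RNG).
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TNode {
  int feat = -1;       // -1: leaf
  double cut = 0.0;
  int left = -1, right = -1;
  int pred = 0;        // majority class at the node
};

double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 1.0 - p * p - (1.0 - p) * (1.0 - p);
}

struct BuildItem {
  std::vector<int> rows;
  int depth;
  int node_id;
};

} // namespace

// [[Rcpp::export]]
NumericVector rf_importance_cpp(NumericMatrix X, IntegerVector y,
                                int ntree, int mtry, int max_depth,
                                int min_node, int seed, bool permutation) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  NumericVector out(p);
  std::vector<double> imp_sum(p, 0.0), imp_sumsq(p, 0.0), gini_sum(p, 0.0);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> row_pick(0, n - 1);
  std::vector<int> feat_idx(p);
  for (int j = 0; j < p; ++j) feat_idx[j] = j;
  const double *xbase = &X[0];

  std::vector<char> inbag(n);
  std::vector<TNode> tree;
  std::vector<char> used(p);
  std::vector<int> oob, perm;
  std::vector<std::pair<double, int>> vals;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    BuildItem root;
    root.rows.resize(n);
    for (int i = 0; i < n; ++i) {
      int r = row_pick(rng);
      root.rows[i] = r;
      inbag[r] = 1;
    }
    root.depth = 0;
    tree.clear();
    tree.push_back(TNode());
    root.node_id = 0;
    std::fill(used.begin(), used.end(), 0);

    std::vector<BuildItem> stack;
    stack.push_back(std::move(root));
    while (!stack.empty()) {
      BuildItem nd = std::move(stack.back());
      stack.pop_back();
      const int sz = (int)nd.rows.size();
      int n1 = 0;
      for (int i : nd.rows) n1 += y[i];
      tree[nd.node_id].pred = (2 * n1 > sz) ? 1 : 0;
      if (sz < 2 * min_node || n1 == 0 || n1 == sz || nd.depth >= max_depth)
        continue;
      const double imp_parent = gini(n1, sz);

      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> pick(j, p - 1);
        std::swap(feat_idx[j], feat_idx[pick(rng)]);
      }
      double best_gain = 0.0;
      int best_feat = -1;
      double best_cut = 0.0;
      vals.resize(sz);
      for (int j = 0; j < mtry; ++j) {
        const int f = feat_idx[j];
        const double *col = xbase + (size_t)f * n;
        for (int k = 0; k < sz; ++k) {
          const int r = nd.rows[k];
          vals[k] = {col[r], y[r]};
        }
        std::sort(vals.begin(), vals.end());
        int left1 = 0;
        for (int k = 0; k < sz - 1; ++k) {
          left1 += vals[k].second;
          if (vals[k].first == vals[k + 1].first) continue;
          const int nl = k + 1, nr = sz - nl;
          if (nl < min_node || nr < min_node) continue;
          const double g = imp_parent -
            ((double)nl / sz) * gini(left1, nl) -
            ((double)nr / sz) * gini(n1 - left1, nr);
          if (g > best_gain + 1e-12) {
            best_gain = g;
            best_feat = f;
            best_cut = 0.5 * (vals[k].first + vals[k + 1].first);
          }
        }
      }
      if (best_feat < 0) continue;
      gini_sum[best_feat] += best_gain * sz;
      used[best_feat] = 1;

      BuildItem left, right;
      left.depth = right.depth = nd.depth + 1;
      for (int i : nd.rows) {
        const double v = xbase[(size_t)best_feat * n + i];
        if (v <= best_cut) left.rows.push_back(i);
        else right.rows.push_back(i);
      }
      const int left_id = (int)tree.size();
      tree.push_back(TNode());
      const int right_id = (int)tree.size();
      tree.push_back(TNode());
      tree[nd.node_id].feat = best_feat;
      tree[nd.node_id].cut = best_cut;
      tree[nd.node_id].left = left_id;
      tree[nd.node_id].right = right_id;
      left.node_id = left_id;
      right.node_id = right_id;
      stack.push_back(std::move(left));
      stack.push_back(std::move(right));
    }

    if (!permutation) continue;
    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    const int n_oob = (int)oob.size();
    if (n_oob < 2) continue;

    // predict row r, reading feature pf from row pr instead (pf = -1: none)
    auto predict_row = [&](int r, int pf, int pr) {
      int id = 0;
      while (tree[id].feat >= 0) {
        const int f = tree[id].feat;
        const int src = (f == pf) ? pr : r;
        const double v = xbase[(size_t)f * n + src];
        id = (v <= tree[id].cut) ? tree[id].left : tree[id].right;
      }
      return tree[id].pred;
    };
    int base_correct = 0;
    for (int r : oob) base_correct += (predict_row(r, -1, 0) == y[r]);

    perm = oob;
    for (int f = 0; f < p; ++f) {
      if (!used[f]) continue;
      std::shuffle(perm.begin(), perm.end(), rng);
      int correct = 0;
      for (int k = 0; k < n_oob; ++k)
        correct += (predict_row(oob[k], f, perm[k]) == y[oob[k]]);
      const double raw = (double)(base_correct - correct) / n_oob;
      imp_sum[f] += raw;
      imp_sumsq[f] += raw * raw;
    }
  }

  if (permutation) {
    for (int f = 0; f < p; ++f) {
      const double mean = imp_sum[f] / ntree;
      const double var = imp_sumsq[f] / ntree - mean * mean;
      const double sd = std::sqrt(std::max(var, 0.0) / ntree);
      out[f] = (sd > 0) ? mean / sd : 0.0;
    }
  } else {
    for (int f = 0; f < p; ++f) out[f] = gini_sum[f] / ntree;
  }
  return out;
}
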