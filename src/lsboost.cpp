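// Least-squares gradient boosting with exact greedy best-first regression
// trees. Determinism contract: split search scans features in ascending
// index and thresholds in ascending value, keeping the first strictly best
// candidate, so ties resolve to the lowest feature index then the lowest
// threshold; best-first growth breaks equal-gain leaves by creation order.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Split {
  int feature = -1;          // -1: no valid split
  double threshold = 0.0;
  double gain = 0.0;         // SSE reduction
};

struct TreeNodes {
  std::vector<int> feature;  // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value; // node mean of residuals
};

// best split of the rows currently in `node`, given presorted feature orders
static Split best_split(const NumericMatrix& X,
                        const std::vector<double>& r,
                        const std::vector<int>& node_of,
                        int node, int n_node, double sum_node,
                        const std::vector<std::vector<int>>& order,
                        int leaf_min) {
  const int p = X.ncol();
  Split best;
  const double parent = sum_node * sum_node / n_node;
  for (int j = 0; j < p; ++j) {
    const std::vector<int>& ord = order[j];
    int k = 0;
    double s = 0.0;
    double prev_val = 0.0;
    bool have_prev = false;
    for (size_t ii = 0; ii < ord.size(); ++ii) {
      int i = ord[ii];
      if (node_of[i] != node) continue;
      double v = X(i, j);
      if (have_prev && v > prev_val && k >= leaf_min && (n_node - k) >= leaf_min) {
        double gain = s * s / k +
                      (sum_node - s) * (sum_node - s) / (n_node - k) - parent;
        if (gain > best.gain + 1e-12) {
          best.gain = gain;
          best.feature = j;
          best.threshold = 0.5 * (prev_val + v);
        }
      }
      s += r[i];
      ++k;
      prev_val = v;
      have_prev = true;
    }
  }
  return best;
}

// [[Rcpp::export]]
List lsboost_fit_cpp(NumericMatrix X, NumericVector y,
                     int n_trees, double rho, int leaf_min, int max_splits) {
  const int n = X.nrow(), p = X.ncol();
  // presort feature orders once (stable -> deterministic)
  std::vector<std::vector<int>> order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    std::stable_sort(order[j].begin(), order[j].end(),
                     [&](int a, int b) { return X(a, j) < X(b, j); });
  }

  double f0 = 0.0;
  for (int i = 0; i < n; ++i) f0 += y[i];
  f0 /= n;

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - f0;

  NumericVector importance(p);
  NumericVector train_mse(n_trees);
  List trees(n_trees);

  std::vector<int> node_of(n);
  for (int m = 0; m < n_trees; ++m) {
    TreeNodes t;
    std::fill(node_of.begin(), node_of.end(), 0);
    double sum0 = 0.0;
    for (int i = 0; i < n; ++i) sum0 += r[i];
    t.feature.push_back(-1);
    t.threshold.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.value.push_back(sum0 / n);

    // candidate best split per open leaf
    std::vector<int> leaf_id(1, 0);
    std::vector<int> leaf_n(1, n);
    std::vector<double> leaf_sum(1, sum0);
    std::vector<Split> leaf_split(1);
    leaf_split[0] = best_split(X, r, node_of, 0, n, sum0, order, leaf_min);

    int splits_done = 0;
    while (splits_done < max_splits) {
      int pick = -1;
      double best_gain = 1e-12;
      for (size_t q = 0; q < leaf_id.size(); ++q)
        if (leaf_split[q].feature >= 0 && leaf_split[q].gain > best_gain) {
          best_gain = leaf_split[q].gain;
          pick = (int)q;
        }
      if (pick < 0) break;

      int node = leaf_id[pick];
      Split sp = leaf_split[pick];
      int lid = (int)t.feature.size();
      int rid = lid + 1;
      // partition rows and child stats
      int nl = 0;
      double sl = 0.0;
      for (int i = 0; i < n; ++i)
        if (node_of[i] == node) {
          if (X(i, sp.feature) <= sp.threshold) {
            node_of[i] = lid; ++nl; sl += r[i];
          } else {
            node_of[i] = rid;
          }
        }
      int nr = leaf_n[pick] - nl;
      double sr = leaf_sum[pick] - sl;

      t.feature[node] = sp.feature;
      t.threshold[node] = sp.threshold;
      t.left[node] = lid;
      t.right[node] = rid;
      for (int c = 0; c < 2; ++c) {
        t.feature.push_back(-1);
        t.threshold.push_back(0.0);
        t.left.push_back(-1);
        t.right.push_back(-1);
      }
      t.value.push_back(sl / nl);
      t.value.push_back(sr / nr);
      importance[sp.feature] += sp.gain;
      ++splits_done;

      // replace the split leaf by its two children
      leaf_id[pick] = lid; leaf_n[pick] = nl; leaf_sum[pick] = sl;
      leaf_split[pick] = best_split(X, r, node_of, lid, nl, sl, order, leaf_min);
      leaf_id.push_back(rid); leaf_n.push_back(nr); leaf_sum.push_back(sr);
      leaf_split.push_back(best_split(X, r, node_of, rid, nr, sr, order, leaf_min));
    }

    // residual update with shrinkage; leaves carry the row's node value
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      r[i] -= rho * t.value[node_of[i]];
      sse += r[i] * r[i];
    }
    train_mse[m] = sse / n;

    trees[m] = List::create(
      _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
      _["value"] = NumericVector(t.value.begin(), t.value.end()));
  }

  return List::create(_["f0"] = f0, _["rho"] = rho, _["trees"] = trees,
                      _["importance_raw"] = importance,
                      _["train_mse"] = train_mse);
}

// [[Rcpp::export]]
NumericVector lsboost_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  double f0 = as<double>(model["f0"]);
  double rho = as<double>(model["rho"]);
  List trees = model["trees"];
  NumericVector out(n, f0);
  for (int m = 0; m < trees.size(); ++m) {
    List t = trees[m];
    IntegerVector feature = t["feature"], left = t["left"], right = t["right"];
    NumericVector threshold = t["threshold"], value = t["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      out[i] += rho * value[node];
    }
  }
  return out;
}
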