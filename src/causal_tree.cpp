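#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Honest causal tree: split structure is learned on one subsample half
// (structure), leaf treatment effects are estimated on a disjoint half
// (estimation).  The split criterion is the treatment-effect heterogeneity
// statistic  nL*nR/(nL+nR)^2 * (tauL - tauR)^2  evaluated on the structure
// half, with a minimum number of treated and control samples per child.

namespace {

struct Node {
  int feature;      // 1-based; -1 for leaf
  double threshold;
  int left, right;  // 1-based node ids; 0 for leaf
  double tau;       // estimation-half effect (leaves only)
  int valid;        // 1 if estimation-half arm counts meet the minimum
  int n_str, n_est1, n_est0;
};

struct Obs { double v; double y; int t; };

// draw k of n indices without replacement using R's RNG (deterministic
// under set.seed)
std::vector<int> sample_without_replacement(int n, int k) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> out(k);
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  return out;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const NumericVector& Y,
              const IntegerVector& T, int mtry, int min_leaf_t,
              int min_leaf_c, int max_depth)
    : X_(X), Y_(Y), T_(T), mtry_(mtry), min_t_(min_leaf_t),
      min_c_(min_leaf_c), max_depth_(max_depth) {}

  int build(std::vector<int>& idx, int depth) {
    int best_feature = -1;
    double best_thr = 0.0, best_gain = 0.0;
    if ((max_depth_ <= 0 || depth < max_depth_) &&
        (int)idx.size() >= 2 * (min_t_ + min_c_)) {
      find_best_split(idx, best_feature, best_thr, best_gain);
    }
    int id = (int)nodes_.size();
    nodes_.push_back(Node{-1, 0.0, 0, 0, NA_REAL, 0, (int)idx.size(), 0, 0});
    if (best_feature >= 0 && best_gain > 0.0) {
      std::vector<int> lidx, ridx;
      for (int i : idx) {
        if (X_(i, best_feature) <= best_thr) lidx.push_back(i);
        else ridx.push_back(i);
      }
      nodes_[id].feature = best_feature + 1;
      nodes_[id].threshold = best_thr;
      int l = build(lidx, depth + 1);
      int r = build(ridx, depth + 1);
      nodes_[id].left = l + 1;
      nodes_[id].right = r + 1;
    }
    return id;
  }

  std::vector<Node> nodes_;

private:
  void find_best_split(const std::vector<int>& idx, int& best_feature,
                       double& best_thr, double& best_gain) {
    int n = (int)idx.size();
    int p = X_.ncol();
    int m = std::min(mtry_, p);
    std::vector<int> feats = sample_without_replacement(p, m);
    std::vector<Obs> obs(n);
    for (int f : feats) {
      for (int i = 0; i < n; ++i)
        obs[i] = Obs{X_(idx[i], f), Y_[idx[i]], T_[idx[i]]};
      std::sort(obs.begin(), obs.end(),
                [](const Obs& a, const Obs& b) { return a.v < b.v; });
      double tot_y1 = 0, tot_y0 = 0;
      int tot_n1 = 0, tot_n0 = 0;
      for (int i = 0; i < n; ++i) {
        if (obs[i].t) { tot_y1 += obs[i].y; ++tot_n1; }
        else          { tot_y0 += obs[i].y; ++tot_n0; }
      }
      double cy1 = 0, cy0 = 0;
      int cn1 = 0, cn0 = 0;
      for (int i = 0; i < n - 1; ++i) {
        if (obs[i].t) { cy1 += obs[i].y; ++cn1; }
        else          { cy0 += obs[i].y; ++cn0; }
        if (obs[i].v >= obs[i + 1].v) continue;  // not a boundary
        int rn1 = tot_n1 - cn1, rn0 = tot_n0 - cn0;
        if (cn1 < min_t_ || cn0 < min_c_ || rn1 < min_t_ || rn0 < min_c_)
          continue;
        double tauL = cy1 / cn1 - cy0 / cn0;
        double tauR = (tot_y1 - cy1) / rn1 - (tot_y0 - cy0) / rn0;
        double nL = cn1 + cn0, nR = rn1 + rn0;
        double gain = nL * nR / ((double)n * n) * (tauL - tauR) * (tauL - tauR);
        if (gain > best_gain) {
          best_gain = gain;
          best_feature = f;
          best_thr = 0.5 * (obs[i].v + obs[i + 1].v);
        }
      }
    }
  }

  const NumericMatrix& X_;
  const NumericVector& Y_;
  const IntegerVector& T_;
  int mtry_, min_t_, min_c_, max_depth_;
};

int descend(const std::vector<Node>& nodes, const NumericMatrix& X, int row) {
  int id = 0;
  while (nodes[id].feature > 0) {
    int f = nodes[id].feature - 1;
    id = (X(row, f) <= nodes[id].threshold ? nodes[id].left : nodes[id].right) - 1;
  }
  return id;
}

int descend_mat(const NumericMatrix& nodes, const NumericMatrix& X, int row) {
  int id = 0;
  while (nodes(id, 0) > 0) {
    int f = (int)nodes(id, 0) - 1;
    id = (int)(X(row, f) <= nodes(id, 1) ? nodes(id, 2) : nodes(id, 3)) - 1;
  }
  return id;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_grow_tree(NumericMatrix X, NumericVector Y, IntegerVector T,
                            IntegerVector str_idx, IntegerVector est_idx,
                            int mtry, int min_leaf_t, int min_leaf_c,
                            int max_depth) {
  RNGScope scope;
  TreeBuilder tb(X, Y, T, mtry, min_leaf_t, min_leaf_c, max_depth);
  std::vector<int> idx(str_idx.size());
  for (int i = 0; i < str_idx.size(); ++i) idx[i] = str_idx[i] - 1;
  tb.build(idx, 0);
  std::vector<Node>& nodes = tb.nodes_;

  // route the estimation half and compute honest leaf effects
  int nn = (int)nodes.size();
  std::vector<double> sy1(nn, 0.0), sy0(nn, 0.0);
  std::vector<int> n1(nn, 0), n0(nn, 0);
  for (int k = 0; k < est_idx.size(); ++k) {
    int i = est_idx[k] - 1;
    int leaf = descend(nodes, X, i);
    if (T[i]) { sy1[leaf] += Y[i]; ++n1[leaf]; }
    else      { sy0[leaf] += Y[i]; ++n0[leaf]; }
  }
  for (int id = 0; id < nn; ++id) {
    if (nodes[id].feature > 0) continue;
    nodes[id].n_est1 = n1[id];
    nodes[id].n_est0 = n0[id];
    if (n1[id] >= min_leaf_t && n0[id] >= min_leaf_c) {
      nodes[id].tau = sy1[id] / n1[id] - sy0[id] / n0[id];
      nodes[id].valid = 1;
    }
  }

  NumericMatrix out(nn, 9);
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "tau", "valid", "n_str",
                                          "n_est1", "n_est0");
  for (int id = 0; id < nn; ++id) {
    out(id, 0) = nodes[id].feature;
    out(id, 1) = nodes[id].threshold;
    out(id, 2) = nodes[id].left;
    out(id, 3) = nodes[id].right;
    out(id, 4) = nodes[id].tau;
    out(id, 5) = nodes[id].valid;
    out(id, 6) = nodes[id].n_str;
    out(id, 7) = nodes[id].n_est1;
    out(id, 8) = nodes[id].n_est0;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_predict_forest(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector tau(n);
  IntegerVector nvalid(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    int m = 0;
    for (int t = 0; t < ntree; ++t) {
      NumericMatrix nodes = trees[t];
      int leaf = descend_mat(nodes, X, i);
      if (nodes(leaf, 5) > 0.5) { s += nodes(leaf, 4); ++m; }
    }
    tau[i] = m > 0 ? s / m : NA_REAL;
    nvalid[i] = m;
  }
  return List::create(_["tau"] = tau, _["nvalid"] = nvalid);
}
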