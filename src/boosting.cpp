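// Gradient-boosted regression trees with a normal accelerated-failure-time
// (AFT) loss for right-censored survival data, plus the supporting primitives
// the ml_os/explain modules need: terminal-leaf assignment, leaf co-occurrence
// similarity, and exact path-dependent TreeSHAP attributions.
//
// Trees are exact-greedy with second-order (Newton) leaf values, L2 penalty
// `lambda`, and native missing-value handling: each split learns a default
// direction by trying missing rows on either side. No row/column subsampling,
// so training is deterministic given the data.
//
// A tree is serialized as a NumericMatrix with one row per node and columns
//   0 feature (-1 for leaf), 1 threshold, 2 default_left, 3 left, 4 right,
//   5 value (leaf weight, already learning-rate scaled), 6 cover (sum of
//   training hessians reaching the node; used by TreeSHAP).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

const int COL_FEAT = 0, COL_THR = 1, COL_DEF = 2, COL_L = 3, COL_R = 4,
          COL_VAL = 5, COL_COV = 6;

struct NodeRec {
  int feature = -1;
  double threshold = 0.0;
  int default_left = 1;
  int left = -1, right = -1;
  double value = 0.0, cover = 0.0;
};

struct SplitInfo {
  double gain = 0.0;
  int feature = -1;
  double threshold = 0.0;
  bool default_left = true;
  bool valid = false;
};

double leaf_weight(double G, double H, double lambda) {
  return -G / (H + lambda);
}

double score(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

// AFT normal loss gradients wrt the location margin f (predicting log time).
// event == 1: -log phi((y - f)/sigma); event == 0: -log Phi((f - y)/sigma).
void aft_grad_hess(const std::vector<double>& y, const IntegerVector& event,
                   const std::vector<double>& f, double sigma,
                   std::vector<double>& g, std::vector<double>& h) {
  const double s2 = sigma * sigma;
  for (size_t i = 0; i < y.size(); ++i) {
    if (event[i] == 1) {
      double z = (y[i] - f[i]) / sigma;
      g[i] = -z / sigma;
      h[i] = 1.0 / s2;
    } else {
      double u = (f[i] - y[i]) / sigma;
      // hazard-like ratio phi(u)/Phi(u), computed on log scale for stability
      double lr = R::dnorm(u, 0.0, 1.0, 1) - R::pnorm(u, 0.0, 1.0, 1, 1);
      double r = std::exp(lr);
      g[i] = -r / sigma;
      double hh = (r * r + u * r) / s2;
      h[i] = std::max(hh, 1e-6);
    }
  }
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, double lambda, double min_child_weight,
              int max_depth, double eta)
      : X_(X), lambda_(lambda), mcw_(min_child_weight),
        max_depth_(max_depth), eta_(eta), n_(X.nrow()), p_(X.ncol()) {
    // pre-sort non-missing row indices per feature once per forest
    order_.resize(p_);
    for (int j = 0; j < p_; ++j) {
      std::vector<int> idx;
      idx.reserve(n_);
      for (int i = 0; i < n_; ++i)
        if (!NumericMatrix::is_na(X_(i, j))) idx.push_back(i);
      std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
        return X_(a, j) < X_(b, j);
      });
      order_[j] = std::move(idx);
    }
  }

  NumericMatrix build(const std::vector<double>& g,
                      const std::vector<double>& h) {
    nodes_.clear();
    in_node_.assign(n_, 0);
    std::vector<int> rows(n_);
    for (int i = 0; i < n_; ++i) rows[i] = i;
    grow(rows, 0, g, h);
    NumericMatrix out(nodes_.size(), 7);
    for (size_t k = 0; k < nodes_.size(); ++k) {
      out(k, COL_FEAT) = nodes_[k].feature;
      out(k, COL_THR) = nodes_[k].threshold;
      out(k, COL_DEF) = nodes_[k].default_left;
      out(k, COL_L) = nodes_[k].left;
      out(k, COL_R) = nodes_[k].right;
      out(k, COL_VAL) = nodes_[k].value;
      out(k, COL_COV) = nodes_[k].cover;
    }
    return out;
  }

private:
  int grow(const std::vector<int>& rows, int depth,
           const std::vector<double>& g, const std::vector<double>& h) {
    double G = 0.0, H = 0.0;
    for (int i : rows) { G += g[i]; H += h[i]; }
    int id = (int)nodes_.size();
    nodes_.push_back(NodeRec());
    nodes_[id].cover = H;
    nodes_[id].value = eta_ * leaf_weight(G, H, lambda_);
    if (depth >= max_depth_ || (int)rows.size() < 2) return id;

    SplitInfo best = find_split(rows, G, H, g, h);
    if (!best.valid) return id;

    std::vector<int> lrows, rrows;
    lrows.reserve(rows.size());
    rrows.reserve(rows.size());
    for (int i : rows) {
      double v = X_(i, best.feature);
      bool left;
      if (NumericMatrix::is_na(v)) left = best.default_left;
      else left = v < best.threshold;
      (left ? lrows : rrows).push_back(i);
    }
    if (lrows.empty() || rrows.empty()) return id;  // degenerate, keep leaf

    nodes_[id].feature = best.feature;
    nodes_[id].threshold = best.threshold;
    nodes_[id].default_left = best.default_left ? 1 : 0;
    int l = grow(lrows, depth + 1, g, h);
    int r = grow(rrows, depth + 1, g, h);
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }

  SplitInfo find_split(const std::vector<int>& rows, double G, double H,
                       const std::vector<double>& g,
                       const std::vector<double>& h) {
    SplitInfo best;
    for (int i : rows) in_node_[i] = 1;
    double parent = score(G, H, lambda_);
    for (int j = 0; j < p_; ++j) {
      // gradient/hessian mass of rows missing feature j in this node
      double Gm = 0.0, Hm = 0.0, Gnm = 0.0, Hnm = 0.0;
      int n_nm = 0;
      for (int i : rows) {
        if (NumericMatrix::is_na(X_(i, j))) { Gm += g[i]; Hm += h[i]; }
        else { Gnm += g[i]; Hnm += h[i]; ++n_nm; }
      }
      if (n_nm < 2) continue;
      double GL = 0.0, HL = 0.0;
      double prev = NA_REAL;
      bool have_prev = false;
      for (int i : order_[j]) {
        if (!in_node_[i]) continue;
        double v = X_(i, j);
        if (have_prev && v > prev) {
          double thr = 0.5 * (prev + v);
          // missing rows on the right
          double gain_r = score(GL, HL, lambda_) +
                          score(Gnm - GL + Gm, Hnm - HL + Hm, lambda_) -
                          parent;
          if (HL >= mcw_ && (Hnm - HL + Hm) >= mcw_ && gain_r > best.gain + 1e-12) {
            best = {gain_r, j, thr, false, true};
          }
          // missing rows on the left
          double gain_l = score(GL + Gm, HL + Hm, lambda_) +
                          score(Gnm - GL, Hnm - HL, lambda_) - parent;
          if ((HL + Hm) >= mcw_ && (Hnm - HL) >= mcw_ && gain_l > best.gain + 1e-12) {
            best = {gain_l, j, thr, true, true};
          }
        }
        GL += g[i];
        HL += h[i];
        prev = v;
        have_prev = true;
      }
    }
    for (int i : rows) in_node_[i] = 0;
    return best;
  }

  const NumericMatrix& X_;
  double lambda_, mcw_;
  int max_depth_;
  double eta_;
  int n_, p_;
  std::vector<std::vector<int>> order_;
  std::vector<NodeRec> nodes_;
  std::vector<char> in_node_;
};

int traverse(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while ((int)tree(node, COL_FEAT) >= 0) {
    int j = (int)tree(node, COL_FEAT);
    double v = X(row, j);
    bool left;
    if (NumericMatrix::is_na(v)) left = tree(node, COL_DEF) > 0.5;
    else left = v < tree(node, COL_THR);
    node = (int)(left ? tree(node, COL_L) : tree(node, COL_R));
  }
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".aft_boost_fit")]]
List aft_boost_fit(NumericMatrix X, NumericVector time, IntegerVector event,
                   int nrounds, double eta, int max_depth, double lambda,
                   double min_child_weight, double sigma, double base_score) {
  const int n = X.nrow();
  std::vector<double> y(n), f(n, base_score), g(n), h(n);
  for (int i = 0; i < n; ++i) y[i] = std::log(time[i]);
  TreeBuilder builder(X, lambda, min_child_weight, max_depth, eta);
  List trees(nrounds);
  for (int m = 0; m < nrounds; ++m) {
    aft_grad_hess(y, event, f, sigma, g, h);
    NumericMatrix tree = builder.build(g, h);
    for (int i = 0; i < n; ++i) f[i] += tree(traverse(tree, X, i), COL_VAL);
    trees[m] = tree;
  }
  return List::create(_["trees"] = trees, _["base_score"] = base_score,
                      _["sigma"] = sigma);
}

// [[Rcpp::export(name = ".boost_predict")]]
NumericVector boost_predict(List trees, double base_score, NumericMatrix X) {
  const int n = X.nrow(), M = trees.size();
  NumericVector out(n, base_score);
  for (int m = 0; m < M; ++m) {
    NumericMatrix tree = trees[m];
    for (int i = 0; i < n; ++i) out[i] += tree(traverse(tree, X, i), COL_VAL);
  }
  return out;
}

// [[Rcpp::export(name = ".boost_leaf")]]
IntegerMatrix boost_leaf(List trees, NumericMatrix X) {
  const int n = X.nrow(), M = trees.size();
  IntegerMatrix out(n, M);
  for (int m = 0; m < M; ++m) {
    NumericMatrix tree = trees[m];
    for (int i = 0; i < n; ++i) out(i, m) = traverse(tree, X, i);
  }
  return out;
}

// Fraction of trees in which a query row and a training row land in the same
// terminal leaf; rows of the result index queries, columns index training rows.
// [[Rcpp::export(name = ".leaf_similarity")]]
NumericMatrix leaf_similarity(IntegerMatrix leaf_train, IntegerMatrix leaf_query) {
  const int nt = leaf_train.nrow(), nq = leaf_query.nrow(),
            M = leaf_train.ncol();
  NumericMatrix out(nq, nt);
  for (int q = 0; q < nq; ++q) {
    for (int t = 0; t < nt; ++t) {
      int same = 0;
      for (int m = 0; m < M; ++m)
        if (leaf_query(q, m) == leaf_train(t, m)) ++same;
      out(q, t) = (double)same / M;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Path-dependent TreeSHAP (exact Shapley values for tree ensembles under the
// cover-weighted conditional expectation), following the recursive
// extend/unwind formulation of the TreeExplainer algorithm.

namespace {

struct PathElem {
  int feature;
  double zero_fraction, one_fraction, pweight;
};

void path_extend(std::vector<PathElem>& path, int unique_depth,
                 double zero_fraction, double one_fraction, int feature) {
  path[unique_depth] = {feature, zero_fraction, one_fraction,
                        unique_depth == 0 ? 1.0 : 0.0};
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight +=
        one_fraction * path[i].pweight * (i + 1) / (double)(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i) /
                      (double)(unique_depth + 1);
  }
}

void path_unwind(std::vector<PathElem>& path, int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      double tmp = path[i].pweight;
      path[i].pweight =
          next_one_portion * (unique_depth + 1) / ((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                                   (unique_depth - i) / (double)(unique_depth + 1);
    } else {
      path[i].pweight = path[i].pweight * (unique_depth + 1) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature = path[i + 1].feature;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const std::vector<PathElem>& path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      double tmp =
          next_one_portion * (unique_depth + 1) / ((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
                                               (unique_depth - i) /
                                               (double)(unique_depth + 1);
    } else {
      total += path[i].pweight /
               (zero_fraction * (unique_depth - i) / (double)(unique_depth + 1));
    }
  }
  return total;
}

void shap_recurse(const NumericMatrix& tree, const NumericMatrix& X, int row,
                  double* phi, int node, std::vector<PathElem> path,
                  int unique_depth, double parent_zero_fraction,
                  double parent_one_fraction, int parent_feature) {
  path_extend(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature);
  int feat = (int)tree(node, COL_FEAT);
  if (feat < 0) {
    double val = tree(node, COL_VAL);
    for (int i = 1; i <= unique_depth; ++i) {
      double w = unwound_path_sum(path, unique_depth, i);
      phi[path[i].feature] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * val;
    }
    return;
  }
  int left = (int)tree(node, COL_L), right = (int)tree(node, COL_R);
  double v = X(row, feat);
  bool go_left;
  if (NumericMatrix::is_na(v)) go_left = tree(node, COL_DEF) > 0.5;
  else go_left = v < tree(node, COL_THR);
  int hot = go_left ? left : right;
  int cold = go_left ? right : left;
  double cover = tree(node, COL_COV);
  double hot_frac = tree(hot, COL_COV) / cover;
  double cold_frac = tree(cold, COL_COV) / cover;

  double incoming_zero = 1.0, incoming_one = 1.0;
  int path_index = 0;
  while (path_index <= unique_depth && path[path_index].feature != feat)
    ++path_index;
  if (path_index != unique_depth + 1) {
    incoming_zero = path[path_index].zero_fraction;
    incoming_one = path[path_index].one_fraction;
    path_unwind(path, unique_depth, path_index);
    --unique_depth;
  }
  shap_recurse(tree, X, row, phi, hot, path, unique_depth + 1,
               incoming_zero * hot_frac, incoming_one, feat);
  shap_recurse(tree, X, row, phi, cold, path, unique_depth + 1,
               incoming_zero * cold_frac, 0.0, feat);
}

double tree_expected_value(const NumericMatrix& tree, int node) {
  if ((int)tree(node, COL_FEAT) < 0) return tree(node, COL_VAL);
  int l = (int)tree(node, COL_L), r = (int)tree(node, COL_R);
  double cl = tree(l, COL_COV), cr = tree(r, COL_COV);
  return (cl * tree_expected_value(tree, l) + cr * tree_expected_value(tree, r)) /
         (cl + cr);
}

}  // namespace

// Returns an n x (p + 1) matrix: per-feature attributions plus, in the last
// column, the ensemble expected value (base_score + cover-weighted leaf means).
// [[Rcpp::export(name = ".tree_shap")]]
NumericMatrix tree_shap(List trees, double base_score, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), M = trees.size();
  NumericMatrix out(n, p + 1);
  double base = base_score;
  for (int m = 0; m < M; ++m) {
    NumericMatrix tree = trees[m];
    base += tree_expected_value(tree, 0);
  }
  int max_nodes = 0;
  for (int m = 0; m < M; ++m) {
    NumericMatrix tree = trees[m];
    max_nodes = std::max(max_nodes, (int)tree.nrow());
  }
  for (int i = 0; i < n; ++i) {
    std::vector<double> phi(p, 0.0);
    for (int m = 0; m < M; ++m) {
      NumericMatrix tree = trees[m];
      std::vector<PathElem> path(max_nodes + 2);
      shap_recurse(tree, X, i, phi.data(), 0, path, 0, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) out(i, j) = phi[j];
    out(i, p) = base;
  }
  return out;
}
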