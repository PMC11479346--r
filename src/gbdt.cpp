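// Histogram-based gradient-boosted decision trees for binary classification
// (logistic loss), grown leaf-wise with L1/L2 leaf regularisation, column
// subsampling per tree, row bagging every k rounds, and a minimum leaf size —
// i.e. the seven tunables lambda_l1, lambda_l2, num_leaves, feature_fraction,
// bagging_fraction, bagging_freq, min_child_samples.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feat;      // -1 for a leaf
  double thr;    // go left iff x[feat] <= thr
  int left, right;
  double val;    // leaf value (already shrunk)
};

struct LeafCand {
  int node_id;
  std::vector<int> idx;
  double G, H;
  bool has_split;
  double gain, thr;
  int feat, bin;
};

inline double thr_l1(double g, double l1) {
  if (g > l1) return g - l1;
  if (g < -l1) return g + l1;
  return 0.0;
}

inline double leaf_obj(double G, double H, double l1, double l2) {
  double t = thr_l1(G, l1);
  return t * t / (H + l2);
}

inline double leaf_value(double G, double H, double l1, double l2) {
  return -thr_l1(G, l1) / (H + l2);
}

// Bin index: smallest i with x <= edges[i]; edges.size() if none (or NaN).
inline int bin_of(double x, const std::vector<double> &edges) {
  if (ISNAN(x)) return (int)edges.size();
  return (int)(std::lower_bound(edges.begin(), edges.end(), x) - edges.begin());
}

double auc_score(const std::vector<double> &score, const NumericVector &y) {
  int n = score.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return score[a] < score[b]; });
  double n1 = 0, n0 = 0, rank_sum = 0;
  int i = 0;
  double rank_pos = 0;
  while (i < n) {
    int j = i;
    while (j < n && score[ord[j]] == score[ord[i]]) ++j;
    double avg_rank = 0.5 * ((i + 1) + j);  // 1-based average rank of the tie block
    for (int k = i; k < j; ++k)
      if (y[ord[k]] > 0.5) rank_pos += avg_rank;
    i = j;
  }
  for (int k = 0; k < n; ++k) (y[k] > 0.5 ? n1 : n0) += 1.0;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  rank_sum = rank_pos;
  return (rank_sum - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

void find_best_split(LeafCand &leaf, const std::vector<std::vector<int>> &bins,
                     const std::vector<std::vector<double>> &edges,
                     const std::vector<int> &feats,
                     const std::vector<double> &grad,
                     const std::vector<double> &hess,
                     double l1, double l2, int min_child) {
  leaf.has_split = false;
  leaf.gain = 0.0;
  int n_leaf = leaf.idx.size();
  if (n_leaf < 2 * min_child) return;
  double parent = leaf_obj(leaf.G, leaf.H, l1, l2);
  for (int f : feats) {
    int nb = (int)edges[f].size() + 1;
    if (nb < 2) continue;
    std::vector<double> Gb(nb, 0.0), Hb(nb, 0.0);
    std::vector<int> Cb(nb, 0);
    const std::vector<int> &bf = bins[f];
    for (int id : leaf.idx) {
      int b = bf[id];
      Gb[b] += grad[id];
      Hb[b] += hess[id];
      Cb[b] += 1;
    }
    double GL = 0, HL = 0;
    int CL = 0;
    for (int b = 0; b < nb - 1; ++b) {
      GL += Gb[b]; HL += Hb[b]; CL += Cb[b];
      if (CL < min_child) continue;
      if (n_leaf - CL < min_child) break;
      double gain = 0.5 * (leaf_obj(GL, HL, l1, l2) +
                           leaf_obj(leaf.G - GL, leaf.H - HL, l1, l2) - parent);
      if (gain > leaf.gain + 1e-12) {
        leaf.gain = gain;
        leaf.feat = f;
        leaf.bin = b;
        leaf.thr = edges[f][b];
        leaf.has_split = true;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".gbdt_train")]]
List gbdt_train(NumericMatrix X, NumericVector y, NumericVector w, List params,
                NumericMatrix Xv, NumericVector yv) {
  const int n = X.nrow(), p = X.ncol();
  const int num_leaves = as<int>(params["num_leaves"]);
  const double lr = as<double>(params["learning_rate"]);
  const double l1 = as<double>(params["lambda_l1"]);
  const double l2 = as<double>(params["lambda_l2"]);
  const double ff = as<double>(params["feature_fraction"]);
  const double bf = as<double>(params["bagging_fraction"]);
  const int bfreq = as<int>(params["bagging_freq"]);
  const int min_child = as<int>(params["min_child_samples"]);
  const int max_bin = as<int>(params["max_bin"]);
  const int n_rounds = as<int>(params["n_rounds"]);
  const int esr = as<int>(params["early_stopping_rounds"]);
  const double es_min_delta = params.containsElementNamed("es_min_delta")
    ? as<double>(params["es_min_delta"]) : 0.0;
  const unsigned int seed = (unsigned int)as<double>(params["seed"]);
  const int nv = Xv.nrow();

  std::mt19937 rng(seed);

  // ---- pre-binning (quantile edges, deduplicated) ----
  std::vector<std::vector<double>> edges(p);
  std::vector<std::vector<int>> bins(p, std::vector<int>(n));
  {
    std::vector<double> col;
    for (int f = 0; f < p; ++f) {
      col.clear();
      for (int i = 0; i < n; ++i)
        if (!ISNAN(X(i, f))) col.push_back(X(i, f));
      std::sort(col.begin(), col.end());
      std::vector<double> uq(col);
      uq.erase(std::unique(uq.begin(), uq.end()), uq.end());
      std::vector<double> ed;
      if ((int)uq.size() <= max_bin) {
        for (size_t k = 0; k + 1 < uq.size(); ++k)
          ed.push_back(0.5 * (uq[k] + uq[k + 1]));
      } else {
        int m = col.size();
        for (int k = 1; k < max_bin; ++k) {
          double v = col[(size_t)((double)k * m / max_bin)];
          if (ed.empty() || v > ed.back()) ed.push_back(v);
        }
      }
      edges[f] = ed;
      for (int i = 0; i < n; ++i) bins[f][i] = bin_of(X(i, f), ed);
    }
  }

  // ---- base score ----
  double sw = 0, swy = 0;
  for (int i = 0; i < n; ++i) { sw += w[i]; swy += w[i] * y[i]; }
  double pbar = std::min(1.0 - 1e-12, std::max(1e-12, swy / sw));
  double f0 = std::log(pbar / (1.0 - pbar));

  std::vector<double> fhat(n, f0), fv(nv, f0);
  std::vector<double> grad(n), hess(n);
  NumericVector importance(p);
  std::vector<std::vector<Node>> trees;
  std::vector<double> valid_hist;

  std::vector<int> all_rows(n), bag_rows;
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  std::vector<int> feat_pool(p);
  for (int f = 0; f < p; ++f) feat_pool[f] = f;
  int n_feat_use = std::max(1, (int)std::ceil(ff * p));
  int n_bag = std::max(2, (int)std::floor(bf * n));
  bool do_bag = (bfreq > 0 && bf < 1.0);

  double best_score = -1.0;
  int best_iter = 0, since_best = 0;

  for (int round = 0; round < n_rounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-fhat[i]));
      grad[i] = w[i] * (pi - y[i]);
      hess[i] = std::max(1e-12, w[i] * pi * (1.0 - pi));
    }
    if (do_bag && (round % bfreq == 0)) {
      std::shuffle(all_rows.begin(), all_rows.end(), rng);
      bag_rows.assign(all_rows.begin(), all_rows.begin() + n_bag);
    }
    const std::vector<int> &rows = (do_bag ? bag_rows : all_rows);

    std::vector<int> feats(feat_pool);
    if (n_feat_use < p) {
      std::shuffle(feats.begin(), feats.end(), rng);
      feats.resize(n_feat_use);
      std::sort(feats.begin(), feats.end());
    }

    std::vector<Node> nodes;
    nodes.push_back({-1, 0.0, -1, -1, 0.0});
    std::vector<LeafCand> leaves;
    {
      LeafCand root;
      root.node_id = 0;
      root.idx = rows;
      root.G = root.H = 0;
      for (int id : rows) { root.G += grad[id]; root.H += hess[id]; }
      find_best_split(root, bins, edges, feats, grad, hess, l1, l2, min_child);
      leaves.push_back(std::move(root));
    }
    int n_leaves_now = 1;
    while (n_leaves_now < num_leaves) {
      int best = -1;
      double bg = 0.0;
      for (size_t k = 0; k < leaves.size(); ++k)
        if (leaves[k].has_split && leaves[k].gain > bg) {
          bg = leaves[k].gain;
          best = (int)k;
        }
      if (best < 0) break;
      LeafCand parent = std::move(leaves[best]);
      leaves.erase(leaves.begin() + best);
      importance[parent.feat] += parent.gain;

      LeafCand lc, rc;
      lc.node_id = (int)nodes.size();
      rc.node_id = (int)nodes.size() + 1;
      nodes.push_back({-1, 0.0, -1, -1, 0.0});
      nodes.push_back({-1, 0.0, -1, -1, 0.0});
      nodes[parent.node_id].feat = parent.feat;
      nodes[parent.node_id].thr = parent.thr;
      nodes[parent.node_id].left = lc.node_id;
      nodes[parent.node_id].right = rc.node_id;

      const std::vector<int> &bfv = bins[parent.feat];
      lc.G = lc.H = rc.G = rc.H = 0;
      for (int id : parent.idx) {
        if (bfv[id] <= parent.bin) {
          lc.idx.push_back(id); lc.G += grad[id]; lc.H += hess[id];
        } else {
          rc.idx.push_back(id); rc.G += grad[id]; rc.H += hess[id];
        }
      }
      find_best_split(lc, bins, edges, feats, grad, hess, l1, l2, min_child);
      find_best_split(rc, bins, edges, feats, grad, hess, l1, l2, min_child);
      leaves.push_back(std::move(lc));
      leaves.push_back(std::move(rc));
      ++n_leaves_now;
    }
    for (const LeafCand &lf : leaves)
      nodes[lf.node_id].val = lr * leaf_value(lf.G, lf.H, l1, l2);

    // update scores on train and valid
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while (nodes[cur].feat >= 0) {
        double v = X(i, nodes[cur].feat);
        cur = (!ISNAN(v) && v <= nodes[cur].thr) ? nodes[cur].left : nodes[cur].right;
      }
      fhat[i] += nodes[cur].val;
    }
    for (int i = 0; i < nv; ++i) {
      int cur = 0;
      while (nodes[cur].feat >= 0) {
        double v = Xv(i, nodes[cur].feat);
        cur = (!ISNAN(v) && v <= nodes[cur].thr) ? nodes[cur].left : nodes[cur].right;
      }
      fv[i] += nodes[cur].val;
    }
    trees.push_back(std::move(nodes));

    if (nv > 0) {
      double sc = auc_score(fv, yv);
      valid_hist.push_back(sc);
      if (ISNAN(sc)) sc = 0.5;
      if (sc > best_score + es_min_delta) {
        best_score = sc;
        best_iter = round + 1;
        since_best = 0;
      } else if (esr > 0 && ++since_best >= esr) {
        break;
      }
    } else {
      best_iter = round + 1;
    }
  }
  if (nv == 0) best_iter = (int)trees.size();
  if (best_iter == 0) best_iter = (int)trees.size();

  // serialise trees kept up to best_iter
  List tree_list(best_iter);
  for (int t = 0; t < best_iter; ++t) {
    const std::vector<Node> &nd = trees[t];
    int m = nd.size();
    IntegerVector feat(m), left(m), right(m);
    NumericVector thr(m), val(m);
    for (int i = 0; i < m; ++i) {
      feat[i] = nd[i].feat; left[i] = nd[i].left; right[i] = nd[i].right;
      thr[i] = nd[i].thr; val[i] = nd[i].val;
    }
    tree_list[t] = List::create(_["feat"] = feat, _["thr"] = thr,
                                _["left"] = left, _["right"] = right,
                                _["val"] = val);
  }
  return List::create(_["trees"] = tree_list, _["base_score"] = f0,
                      _["best_iter"] = best_iter,
                      _["best_valid_auc"] = (nv > 0 ? best_score : NA_REAL),
                      _["valid_history"] = valid_hist,
                      _["importance_gain"] = importance,
                      _["n_features"] = p);
}

// [[Rcpp::export(name = ".gbdt_predict_raw")]]
NumericVector gbdt_predict_raw(List model, NumericMatrix X) {
  List trees = model["trees"];
  double f0 = as<double>(model["base_score"]);
  int n = X.nrow();
  NumericVector out(n, f0);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], val = tr["val"];
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while (feat[cur] >= 0) {
        double v = X(i, feat[cur]);
        cur = (!ISNAN(v) && v <= thr[cur]) ? left[cur] : right[cur];
      }
      out[i] += val[cur];
    }
  }
  return out;
}
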