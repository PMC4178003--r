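// Out-of-bag permutation importance (mean decrease in accuracy) computed by
// traversing randomForest trees directly. For every tree: take its
// out-of-bag rows, record the accuracy on untouched data, then, for each
// feature, permute that feature's values within the OOB rows (Fisher-Yates
// driven by R's RNG, so set.seed() governs determinism) and record the drop
// in accuracy. The MDA of a feature is the per-tree drop averaged over trees
// with a non-empty OOB set. Features never used by any split are untouched
// by the permutation and therefore score exactly zero.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Predict one row with one getTree() matrix; `perm_feat` (0-based, or -1)
// marks the feature whose value comes from `perm_val` instead of X.
static int tree_predict(const arma::mat& tr, const arma::rowvec& xrow,
                        int perm_feat, double perm_val) {
  int node = 0;
  while (tr(node, 4) != -1.0) {  // status -1 marks a terminal node
    int v = (int)tr(node, 2) - 1;
    double x = (v == perm_feat) ? perm_val : xrow[v];
    node = (x <= tr(node, 3)) ? (int)tr(node, 0) - 1 : (int)tr(node, 1) - 1;
  }
  return (int)tr(node, 5);  // class index (1-based)
}

// [[Rcpp::export]]
List mda_oob_cpp(List trees, const arma::mat& X, const IntegerVector& y,
                 const IntegerMatrix& inbag) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int ntree = trees.size();
  arma::vec mda_sum(p, arma::fill::zeros);
  arma::ivec mda_cnt(p, arma::fill::zeros);
  arma::vec base_acc(ntree, arma::fill::value(NA_REAL));
  // OOB vote matrix for ensemble OOB predictions
  arma::imat votes(n, 2, arma::fill::zeros);
  int skipped = 0;
  RNGScope scope;  // permutations use R's RNG
  for (int t = 0; t < ntree; ++t) {
    arma::mat tr = as<arma::mat>(trees[t]);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob.push_back(i);
    const int m = (int)oob.size();
    if (m == 0) { ++skipped; continue; }
    std::vector<int> pred(m);
    int correct = 0;
    for (int k = 0; k < m; ++k) {
      pred[k] = tree_predict(tr, X.row(oob[k]), -1, 0.0);
      votes(oob[k], pred[k] - 1) += 1;
      if (pred[k] == y[oob[k]]) ++correct;
    }
    double acc0 = (double)correct / m;
    base_acc[t] = acc0;
    for (int j = 0; j < p; ++j) {
      // permute feature j's OOB values (Fisher-Yates via R RNG)
      std::vector<double> vals(m);
      for (int k = 0; k < m; ++k) vals[k] = X(oob[k], j);
      for (int k = m - 1; k > 0; --k) {
        int r = (int)(unif_rand() * (k + 1));
        if (r > k) r = k;
        std::swap(vals[k], vals[r]);
      }
      int corr_p = 0;
      for (int k = 0; k < m; ++k) {
        int pr = tree_predict(tr, X.row(oob[k]), j, vals[k]);
        if (pr == y[oob[k]]) ++corr_p;
      }
      mda_sum[j] += acc0 - (double)corr_p / m;
      mda_cnt[j] += 1;
    }
  }
  NumericVector mda(p);
  for (int j = 0; j < p; ++j) {
    mda[j] = mda_cnt[j] > 0 ? mda_sum[j] / mda_cnt[j] : NA_REAL;
  }
  // majority-vote OOB prediction per row (0 = no vote)
  IntegerVector oob_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int tot = votes(i, 0) + votes(i, 1);
    if (tot > 0) oob_pred[i] = votes(i, 1) > votes(i, 0) ? 2 : 1;
  }
  return List::create(_["mda"] = mda,
                      _["base_accuracy"] = NumericVector(base_acc.begin(), base_acc.end()),
                      _["oob_pred"] = oob_pred,
                      _["skipped_trees"] = skipped);
}
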