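// Exhaustive best-subset search for the multiple correlation with a
// one-dimensional outcome. Works off the feature covariance matrix C and the
// feature-outcome covariance vector s: for a subset S,
//   R^2(S) = s_S' C_SS^{-1} s_S / var(y),
// with a pseudo-inverse fallback for rank-deficient subsets (the supremum
// correlation over the column space). Subsets are enumerated in
// lexicographic order and ties keep the first (lexicographically smallest)
// maximizer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double subset_rsq(const arma::mat& C, const arma::vec& s, double vy,
                         const arma::uvec& idx, double pinv_tol_factor) {
  arma::mat Css = C.submat(idx, idx);
  arma::vec ss = s.elem(idx);
  arma::vec sol;
  bool ok = arma::solve(sol, Css, ss, arma::solve_opts::no_approx);
  if (!ok) {
    // rank-deficient subset: pseudo-inverse with relative tolerance
    arma::mat P = arma::pinv(Css, pinv_tol_factor * arma::norm(Css, 2));
    sol = P * ss;
  }
  double r2 = arma::dot(ss, sol) / vy;
  if (r2 < 0.0) r2 = 0.0;
  if (r2 > 1.0) r2 = 1.0;
  return r2;
}

// [[Rcpp::export]]
List best_subset_cpp(const arma::mat& C, const arma::vec& s, double vy,
                     int k, double pinv_tol = 1e-10) {
  const int p = C.n_rows;
  if (k < 1 || k > p) stop("subset size k out of range");
  std::vector<unsigned int> comb(k);
  for (int i = 0; i < k; ++i) comb[i] = i;
  arma::uvec idx(k);
  double best = -1.0;
  std::vector<unsigned int> best_comb(k);
  while (true) {
    for (int i = 0; i < k; ++i) idx[i] = comb[i];
    double r2 = subset_rsq(C, s, vy, idx, pinv_tol);
    if (r2 > best) {  // strict: lexicographically first maximizer wins ties
      best = r2;
      best_comb = comb;
    }
    // next lexicographic combination
    int i = k - 1;
    while (i >= 0 && comb[i] == (unsigned int)(p - k + i)) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
  }
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = best_comb[i] + 1;  // 1-based
  return List::create(_["subset"] = out, _["rsq"] = best);
}

// [[Rcpp::export]]
double subset_rsq_cpp(const arma::mat& C, const arma::vec& s, double vy,
                      const arma::uvec& idx0, double pinv_tol = 1e-10) {
  return subset_rsq(C, s, vy, idx0, pinv_tol);
}
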