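// Dense tableau simplex for the 1-norm soft-margin SVM linear program
//
//   min  1'u + 1'v + sum_i c_i xi_i
//   s.t. y_i ((u - v).x_i + b1 - b2) + xi_i >= 1,   u, v, b1, b2, xi >= 0
//
// in the standard split w = u - v, b = b1 - b2. The slack variables xi give
// an immediate basic feasible point (xi = 1), so no phase-1 is needed, and
// the objective is bounded below by zero, so the LP is never unbounded.
// Dantzig pricing with a switch to Bland's rule guards against cycling.
// The tableau is stored transposed (one column per constraint row) so that
// pivot updates are contiguous column operations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Generic solver for: min c'z  s.t.  A z >= b (b > 0), z >= 0, where the
// last m columns of A are an identity (the slack block).
// [[Rcpp::export]]
List svm_lp_solve(const arma::mat& A, const arma::vec& b, const arma::vec& c,
                  int max_iter = 50000, double tol = 1e-9) {
  const int m = A.n_rows;
  const int N = A.n_cols;
  const int ncol = N + m;      // structural + surplus variables
  // TT(j, i) = coefficient of variable j in constraint row i (i < m);
  // TT(ncol, i) = rhs of row i; column m holds the reduced-cost row with
  // TT(ncol, m) = -objective.
  arma::mat TT(ncol + 1, m + 1, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < N; ++j) TT(j, i) = A(i, j);
    TT(N + i, i) = -1.0;       // surplus
    TT(ncol, i) = b[i];
  }
  arma::ivec basis(m);
  for (int i = 0; i < m; ++i) basis[i] = N - m + i;  // xi_i basic in row i
  arma::vec cfull(ncol, arma::fill::zeros);
  cfull.head(N) = c;
  TT.col(m).head(ncol) = cfull;
  TT(ncol, m) = 0.0;
  for (int i = 0; i < m; ++i) {
    double cb = cfull[basis[i]];
    if (cb != 0.0) TT.col(m) -= cb * TT.col(i);
  }
  int iter = 0;
  const int bland_after = 8000;
  for (; iter < max_iter; ++iter) {
    const double* cost = TT.colptr(m);
    int enter = -1;
    if (iter < bland_after) {
      double most = -tol;
      for (int j = 0; j < ncol; ++j) {
        if (cost[j] < most) { most = cost[j]; enter = j; }
      }
    } else {  // Bland
      for (int j = 0; j < ncol; ++j) {
        if (cost[j] < -tol) { enter = j; break; }
      }
    }
    if (enter < 0) break;  // optimal
    // ratio test (ties -> smallest basis index, anti-cycling)
    int leave = -1;
    double best_ratio = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = TT(enter, i);
      if (a > tol) {
        double ratio = TT(ncol, i) / a;
        if (leave < 0 || ratio < best_ratio - tol ||
            (ratio < best_ratio + tol && basis[i] < basis[leave])) {
          leave = i; best_ratio = ratio;
        }
      }
    }
    if (leave < 0) {
      return List::create(_["status"] = "unbounded", _["iterations"] = iter);
    }
    double piv = TT(enter, leave);
    TT.col(leave) /= piv;
    const double* lv = TT.colptr(leave);
    for (int i = 0; i <= m; ++i) {
      if (i == leave) continue;
      double f = TT(enter, i);
      if (f != 0.0) {
        double* ci = TT.colptr(i);
        for (int j = 0; j <= ncol; ++j) ci[j] -= f * lv[j];
      }
    }
    basis[leave] = enter;
  }
  std::string status = (iter >= max_iter) ? "iteration-limit" : "optimal";
  arma::vec z(ncol, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    double val = TT(ncol, i);
    z[basis[i]] = (val > 0.0) ? val : 0.0;
  }
  double obj = arma::dot(cfull, z);
  return List::create(_["status"] = status,
                      _["z"] = NumericVector(z.begin(), z.begin() + N),
                      _["objective"] = obj,
                      _["iterations"] = iter);
}
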