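// Sparse multinomial logistic regression fitted by cyclic coordinate-wise
// bound optimization. The multinomial log-likelihood Hessian is majorized by
// B = (1/2)(1 - 1/K) * diag(X'X), giving soft-threshold updates for the
// L1-penalized weights (intercepts unpenalized, reference class pinned at 0).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static void softmax_row(NumericMatrix& S, NumericMatrix& P, int i) {
  int K = S.ncol();
  double m = S(i, 0);
  for (int k = 1; k < K; ++k) if (S(i, k) > m) m = S(i, k);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { P(i, k) = std::exp(S(i, k) - m); tot += P(i, k); }
  for (int k = 0; k < K; ++k) P(i, k) /= tot;
}

// [[Rcpp::export]]
List smlr_fit_cpp(NumericMatrix X, IntegerMatrix Y, double lambda,
                  double tol, int max_sweeps) {
  int n = X.nrow(), p = X.ncol(), K = Y.ncol();
  NumericMatrix W(p + 1, K);   // row 0 = intercept; column K-1 stays 0
  NumericMatrix S(n, K), P(n, K);
  for (int i = 0; i < n; ++i) softmax_row(S, P, i);

  std::vector<double> sumsq(p + 1);
  sumsq[0] = (double)n;
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    sumsq[j + 1] = s;
  }
  double curv = 0.5 * (1.0 - 1.0 / K);
  int sweep = 0;
  bool converged = false;

  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int k = 0; k < K - 1; ++k) {
      for (int j = 0; j <= p; ++j) {
        double B = curv * sumsq[j];
        if (B <= 1e-12) continue;
        double g = 0.0;
        if (j == 0) {
          for (int i = 0; i < n; ++i) g += (double)Y(i, k) - P(i, k);
        } else {
          for (int i = 0; i < n; ++i) g += X(i, j - 1) * ((double)Y(i, k) - P(i, k));
        }
        double z = W(j, k) + g / B;
        double w_new;
        if (j == 0) {
          w_new = z;
        } else {
          double thr = lambda / B;
          w_new = (z > thr) ? z - thr : ((z < -thr) ? z + thr : 0.0);
        }
        double d = w_new - W(j, k);
        if (d != 0.0) {
          W(j, k) = w_new;
          if (j == 0) {
            for (int i = 0; i < n; ++i) { S(i, k) += d; softmax_row(S, P, i); }
          } else {
            for (int i = 0; i < n; ++i) { S(i, k) += X(i, j - 1) * d; softmax_row(S, P, i); }
          }
          double ad = std::fabs(d);
          if (ad > max_delta) max_delta = ad;
        }
      }
    }
    if (max_delta < tol) { converged = true; break; }
  }
  return List::create(_["weights"] = W, _["converged"] = converged,
                      _["sweeps"] = std::min(sweep, max_sweeps));
}
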