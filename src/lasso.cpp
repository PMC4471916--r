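#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the L1-penalised least-squares path with
// warm starts along a decreasing lambda grid. Covariance (Gram) updates:
// the partial-residual inner product for coordinate j is
//   z_j = x_j'y/n - sum_k G_jk b_k + d_j b_j,  G = X'X/n, d_j = G_jj,
// followed by soft-thresholding. Convergence: largest coefficient change
// in a full sweep < tol. Returns p x nlambda coefficient matrix; throws on
// non-convergence.
// [[Rcpp::export]]
NumericMatrix cpp_lasso_path(NumericMatrix X, NumericVector yc,
                             NumericVector lambda, double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  std::vector<double> G(p * p), xty(p), d(p), b(p, 0.0);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * yc[i];
    xty[j] = s / n;
    for (int k = j; k < p; ++k) {
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += X(i, j) * X(i, k);
      g /= n;
      G[j * p + k] = g;
      G[k * p + j] = g;
    }
    d[j] = G[j * p + j];
  }
  NumericMatrix beta(p, nl);
  for (int l = 0; l < nl; ++l) {
    double lam = lambda[l];
    int it = 0;
    double delta;
    do {
      delta = 0.0;
      for (int j = 0; j < p; ++j) {
        double bj = b[j];
        double z = xty[j] + d[j] * bj;
        const double* Gj = &G[j * p];
        for (int k = 0; k < p; ++k) z -= Gj[k] * b[k];
        // relative fuzz keeps the all-zero solution exact at lambda_max
        // despite summation-order rounding differences
        double th = lam * (1.0 + 1e-12);
        double bn = 0.0;
        if (z > th) bn = (z - lam) / d[j];
        else if (z < -th) bn = (z + lam) / d[j];
        if (bn != bj) {
          b[j] = bn;
          double ch = std::abs(bn - bj);
          if (ch > delta) delta = ch;
        }
      }
      if (++it > max_iter) {
        stop("coordinate descent failed to converge at lambda = %f", lam);
      }
    } while (delta >= tol);
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return beta;
}
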