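#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the weighted elastic net on centered data,
// using covariance updates. Solves, for each lambda in decreasing order with
// warm starts,
//   min_b (1/2n)||y - X b||^2
//         + lambda * sum_j w_j ( alpha |b_j| + (1 - alpha)/2 b_j^2 )
// given XtX = X'X / n, Xty = X'y / n. Columns with zero variance are held at
// zero. Unpenalized columns (w_j = 0) are updated without shrinkage.
// Convergence: max absolute coefficient change within a sweep < tol.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export]]
List enet_cd_path(const NumericMatrix& XtX, const NumericVector& Xty,
                  const NumericVector& penalty, double alpha,
                  const NumericVector& lambda, double tol, int maxit) {
  const int p = Xty.size();
  const int nlam = lambda.size();
  NumericMatrix beta(p, nlam);
  IntegerVector iters(nlam);
  LogicalVector converged(nlam);

  std::vector<double> b(p, 0.0), q(p, 0.0); // q = XtX %*% b
  std::vector<double> diag(p);
  for (int j = 0; j < p; ++j) diag[j] = XtX(j, j);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    int it = 0;
    double maxdiff = R_PosInf;
    while (it < maxit && maxdiff >= tol) {
      maxdiff = 0.0;
      for (int j = 0; j < p; ++j) {
        if (diag[j] <= 0.0) continue;
        const double w = penalty[j];
        const double z = Xty[j] - q[j] + diag[j] * b[j];
        double bj;
        if (w == 0.0) {
          bj = z / diag[j];
        } else {
          bj = soft(z, lam * alpha * w) / (diag[j] + lam * (1.0 - alpha) * w);
        }
        const double d = bj - b[j];
        if (d != 0.0) {
          b[j] = bj;
          const double* col = &XtX(0, j);
          for (int k = 0; k < p; ++k) q[k] += d * col[k];
          const double ad = std::fabs(d);
          if (ad > maxdiff) maxdiff = ad;
        }
      }
      ++it;
    }
    iters[l] = it;
    converged[l] = (maxdiff < tol);
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["converged"] = converged);
}
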