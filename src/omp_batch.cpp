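// Batched orthogonal matching pursuit over many pixel curves sharing one
// dictionary. Residual correlations are updated through the Gram matrix:
// D'r = D'x - G[, S] c, so after the initial D'X (one BLAS gemm) each
// pixel's pursuit costs only O(K k) per step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat omp_batch_cpp(const arma::mat& D, const arma::mat& G,
                        const arma::mat& X, int k_max, double tol_rel) {
  const arma::uword m = D.n_rows, K = D.n_cols, P = X.n_cols;
  if (X.n_rows != m) Rcpp::stop("signal length must equal dictionary rows");
  if (k_max < 1 || (arma::uword)k_max > K) Rcpp::stop("k_max out of range");
  arma::mat C0 = D.t() * X;                  // K x P initial correlations
  arma::mat fitted(m, P, arma::fill::zeros);
  arma::vec corr(K), b(k_max), c;
  arma::mat Gs(k_max, k_max);
  arma::uvec sup(k_max);
  for (arma::uword p = 0; p < P; ++p) {
    const double xnorm2 = arma::dot(X.col(p), X.col(p));
    if (xnorm2 <= 0) continue;
    const double tol2 = tol_rel * tol_rel * xnorm2;
    corr = C0.col(p);
    int k = 0;
    while (k < k_max) {
      arma::uword j = arma::index_max(arma::abs(corr));
      if (std::abs(corr[j]) <= 1e-14 * std::sqrt(xnorm2)) break;
      bool dup = false;
      for (int i = 0; i < k; ++i) if (sup[i] == j) { dup = true; break; }
      if (dup) break;
      sup[k] = j;
      ++k;
      for (int i = 0; i < k; ++i) {
        b[i] = C0(sup[i], p);
        for (int l = 0; l < k; ++l) Gs(i, l) = G(sup[i], sup[l]);
      }
      if (!arma::solve(c, Gs.submat(0, 0, k - 1, k - 1), b.head(k),
                       arma::solve_opts::likely_sympd)) { --k; break; }
      // residual correlations and residual norm^2 via the Gram identity
      corr = C0.col(p);
      for (int i = 0; i < k; ++i) corr -= c[i] * G.col(sup[i]);
      double fit2 = arma::dot(b.head(k), c);
      if (xnorm2 - fit2 <= tol2) break;
    }
    if (k > 0) {
      arma::vec f(m, arma::fill::zeros);
      for (int i = 0; i < k; ++i) f += c[i] * D.col(sup[i]);
      fitted.col(p) = f;
    }
  }
  return fitted;
}
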