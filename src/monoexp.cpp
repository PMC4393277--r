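// Batched three-parameter mono-exponential fit by variable projection.
// Model: x(t) = a + b exp(-t / T1s) with a = M0*, b = -(M0 + M0*). For a
// fixed T1s the linear pair (a, b) has a closed form, so the nonlinear fit
// reduces to a 1-D search over T1s: a shared coarse log-spaced grid
// (correlations batched over pixels via one gemm) followed by per-pixel
// golden-section refinement between the bracketing grid points.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {
struct LinFit { double sse, a, b; };

LinFit lin_fit(const arma::vec& t, const arma::vec& x, double Sx, double Sxx,
               double T1s) {
  const arma::uword m = t.n_elem;
  double S1 = 0, S2 = 0, Sxe = 0;
  for (arma::uword i = 0; i < m; ++i) {
    double e = std::exp(-t[i] / T1s);
    S1 += e; S2 += e * e; Sxe += x[i] * e;
  }
  double det = m * S2 - S1 * S1;
  LinFit f;
  if (det <= 0) { f.sse = arma::datum::inf; f.a = f.b = arma::datum::nan; return f; }
  f.a = (S2 * Sx - S1 * Sxe) / det;
  f.b = (m * Sxe - S1 * Sx) / det;
  f.sse = Sxx - f.a * Sx - f.b * Sxe;
  return f;
}
}

// [[Rcpp::export]]
Rcpp::List monoexp_varpro_cpp(const arma::mat& X, const arma::vec& t,
                              const arma::vec& t1_grid, double lo, double hi,
                              int refine_iters) {
  const arma::uword m = X.n_rows, P = X.n_cols, ng = t1_grid.n_elem;
  if (t.n_elem != m) Rcpp::stop("time/frame mismatch");
  arma::mat E(m, ng);
  for (arma::uword g = 0; g < ng; ++g)
    for (arma::uword i = 0; i < m; ++i)
      E(i, g) = std::exp(-t[i] / t1_grid[g]);
  arma::vec S1 = arma::sum(E, 0).t();
  arma::vec S2 = arma::sum(E % E, 0).t();
  arma::mat Sxe = E.t() * X;                 // ng x P
  arma::vec T1s(P), M0s(P), M0(P), resid(P);
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  for (arma::uword p = 0; p < P; ++p) {
    arma::vec x = X.col(p);
    double Sx = arma::accu(x), Sxx = arma::dot(x, x);
    if (!x.is_finite() || Sxx == 0) {
      T1s[p] = M0s[p] = M0[p] = resid[p] = arma::datum::nan;
      continue;
    }
    // coarse stage: closed-form SSE at every grid T1s
    double best = arma::datum::inf;
    arma::uword jb = 0;
    for (arma::uword g = 0; g < ng; ++g) {
      double det = m * S2[g] - S1[g] * S1[g];
      if (det <= 0) continue;
      double a = (S2[g] * Sx - S1[g] * Sxe(g, p)) / det;
      double b = (m * Sxe(g, p) - S1[g] * Sx) / det;
      double sse = Sxx - a * Sx - b * Sxe(g, p);
      if (sse < best) { best = sse; jb = g; }
    }
    // golden-section refinement in log(T1s) between the bracket neighbors
    double la = std::log(jb > 0 ? t1_grid[jb - 1] : lo);
    double lb = std::log(jb + 1 < ng ? t1_grid[jb + 1] : hi);
    double c1 = lb - gr * (lb - la), c2 = la + gr * (lb - la);
    double f1 = lin_fit(t, x, Sx, Sxx, std::exp(c1)).sse;
    double f2 = lin_fit(t, x, Sx, Sxx, std::exp(c2)).sse;
    for (int it = 0; it < refine_iters && (lb - la) > 1e-7; ++it) {
      if (f1 < f2) {
        lb = c2; c2 = c1; f2 = f1;
        c1 = lb - gr * (lb - la);
        f1 = lin_fit(t, x, Sx, Sxx, std::exp(c1)).sse;
      } else {
        la = c1; c1 = c2; f1 = f2;
        c2 = la + gr * (lb - la);
        f2 = lin_fit(t, x, Sx, Sxx, std::exp(c2)).sse;
      }
    }
    double T1 = std::exp((la + lb) / 2);
    LinFit f = lin_fit(t, x, Sx, Sxx, T1);
    T1s[p] = T1;
    M0s[p] = f.a;
    M0[p] = -f.b - f.a;
    resid[p] = std::sqrt(std::max(f.sse, 0.0) / m);
  }
  return Rcpp::List::create(Rcpp::Named("T1_star") = T1s,
                            Rcpp::Named("M0_star") = M0s,
                            Rcpp::Named("M0") = M0,
                            Rcpp::Named("residual") = resid);
}
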