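// Exact k-space values of per-frame model images along their own spokes:
// out[m, i] = (1/side) * sum_j img(j, i) * exp(-i r_m u_j(theta_i)),
// with u_j = 2 pi (x_j cos th + y_j sin th) / side. The images are given on
// an arbitrary pixel subset (the object support), which keeps the per-
// iteration cost of the model-shift consistency low.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List nudft_model_spokes_cpp(const Rcpp::List& images,
                                  const arma::vec& x, const arma::vec& y,
                                  int side, const arma::vec& angles_rad,
                                  const arma::vec& offsets) {
  const int n_coils = images.size();
  if (n_coils < 1) Rcpp::stop("at least one coil image matrix required");
  std::vector<arma::cx_mat> imgs(n_coils);
  for (int g = 0; g < n_coils; ++g)
    imgs[g] = Rcpp::as<arma::cx_mat>(images[g]);
  const arma::uword n_sub = imgs[0].n_rows, n_fr = imgs[0].n_cols;
  const arma::uword m = offsets.n_elem;
  if (x.n_elem != n_sub || y.n_elem != n_sub) Rcpp::stop("coordinate mismatch");
  if (angles_rad.n_elem != n_fr) Rcpp::stop("one spoke angle per frame required");
  for (arma::uword i = 1; i < m; ++i)
    if (std::abs(offsets[i] - offsets[i - 1] - 1.0) > 1e-9)
      Rcpp::stop("readout offsets must be consecutive integers");
  std::vector<arma::cx_mat> out(n_coils, arma::cx_mat(m, n_fr));
  const double two_pi = 2.0 * arma::datum::pi;
  arma::cx_vec w(n_sub), row(n_sub);
  for (arma::uword i = 0; i < n_fr; ++i) {
    const double ct = std::cos(angles_rad[i]), st = std::sin(angles_rad[i]);
    for (arma::uword j = 0; j < n_sub; ++j) {
      double u = two_pi * (x[j] * ct + y[j] * st) / side;
      w[j] = arma::cx_double(std::cos(u), -std::sin(u));
    }
    long r0 = (long)std::llround(offsets[0]);
    row.ones();
    {
      unsigned long e = (unsigned long)std::labs(r0);
      arma::cx_vec base = (r0 < 0) ? arma::cx_vec(arma::conj(w)) : w;
      while (e) {
        if (e & 1UL) row %= base;
        base %= base;
        e >>= 1UL;
      }
    }
    // the phase rows are coil-independent; dot each against every coil
    for (arma::uword r = 0; r < m; ++r) {
      if (r > 0) row %= w;
      const arma::cx_double* rp = row.memptr();
      for (int g = 0; g < n_coils; ++g) {
        const arma::cx_double* ip = imgs[g].colptr(i);
        arma::cx_double acc(0.0, 0.0);
        for (arma::uword j = 0; j < n_sub; ++j) acc += rp[j] * ip[j];
        out[g](r, i) = acc / (double)side;
      }
    }
  }
  Rcpp::List res(n_coils);
  for (int g = 0; g < n_coils; ++g) res[g] = out[g];
  return res;
}
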