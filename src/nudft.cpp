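// Exact nonuniform DFT of a stack of static images along radial spokes.
// Convention (unitary, centered): s[r, spoke, l] =
//   (1/side) * sum_j img_l(j) * exp(-i * r * (x_j cos th + y_j sin th) * 2 pi / side)
// with centered pixel coordinates x, y in {-side/2, ..., side/2 - 1} and
// readout offsets r required to be consecutive integers, which allows the
// per-spoke phase rows to be built by recursive multiplication (error
// O(machine eps * n_readout)) instead of n_readout * n_pixels exp calls.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::cx_cube nudft_spokes_cpp(const arma::cx_mat& images, int side,
                               const arma::vec& angles_rad,
                               const arma::vec& offsets) {
  const arma::uword n_pix = images.n_rows, L = images.n_cols;
  const arma::uword n_sp = angles_rad.n_elem, m = offsets.n_elem;
  if ((int)n_pix != side * side) Rcpp::stop("images rows must be side^2");
  for (arma::uword i = 1; i < m; ++i)
    if (std::abs(offsets[i] - offsets[i - 1] - 1.0) > 1e-9)
      Rcpp::stop("readout offsets must be consecutive integers");
  arma::cx_cube out(m, n_sp, L);
  arma::vec x(n_pix), y(n_pix);
  for (arma::uword j = 0; j < n_pix; ++j) {
    x[j] = (double)((int)(j / side) - side / 2);
    y[j] = (double)((int)(j % side) - side / 2);
  }
  const double two_pi = 2.0 * arma::datum::pi;
  arma::cx_vec w(n_pix), row(n_pix);
  arma::cx_mat vals(1, L);
  for (arma::uword s = 0; s < n_sp; ++s) {
    const double ct = std::cos(angles_rad[s]), st = std::sin(angles_rad[s]);
    for (arma::uword j = 0; j < n_pix; ++j) {
      double u = two_pi * (x[j] * ct + y[j] * st) / side;
      w[j] = arma::cx_double(std::cos(u), -std::sin(u));  // exp(-i u)
    }
    // row = w^{r0} by binary exponentiation (elementwise)
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
    for (arma::uword r = 0; r < m; ++r) {
      if (r > 0) row %= w;
      vals = row.st() * images;              // 1 x L (BLAS)
      for (arma::uword l = 0; l < L; ++l) out(r, s, l) = vals(0, l) / (double)side;
    }
  }
  return out;
}
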