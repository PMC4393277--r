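// Batched centered unitary 2D DFT. Each column of `stack` is one
// side x side frame (column-major, DC at 0-based index side/2). The
// centering shifts are folded into the load/store passes. Power-of-two
// sides use an iterative radix-2 kernel: the y-direction transforms run
// per contiguous column; the x-direction runs as a vector radix whose
// butterflies operate on whole contiguous columns, so there are no
// transposes and no strided scalar accesses. Other even sides fall back to
// Armadillo's FFT.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

typedef std::complex<double> cxd;

struct Radix2Plan {
  int n;
  std::vector<int> rev;
  std::vector<cxd> tw;   // forward twiddles, per stage concatenated
  explicit Radix2Plan(int n_) : n(n_), rev(n_) {
    int lg = 0; while ((1 << lg) < n) ++lg;
    for (int i = 0; i < n; ++i) {
      int r = 0;
      for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1 << (lg - 1 - b);
      rev[i] = r;
    }
    for (int len = 2; len <= n; len <<= 1)
      for (int j = 0; j < len / 2; ++j) {
        double ang = -2.0 * M_PI * j / len;
        tw.push_back(cxd(std::cos(ang), std::sin(ang)));
      }
  }
  // unscaled in-place FFT of a contiguous length-n vector
  void run(cxd* a, bool inverse) const {
    for (int i = 0; i < n; ++i)
      if (i < rev[i]) std::swap(a[i], a[rev[i]]);
    size_t toff = 0;
    for (int len = 2; len <= n; len <<= 1) {
      const int half = len / 2;
      for (int i = 0; i < n; i += len)
        for (int j = 0; j < half; ++j) {
          cxd w = tw[toff + j];
          if (inverse) w = std::conj(w);
          cxd u = a[i + j], v = a[i + j + half] * w;
          a[i + j] = u + v;
          a[i + j + half] = u - v;
        }
      toff += half;
    }
  }
  // unscaled FFT across the column index of a side x side frame: each
  // "scalar" of the radix-2 scheme is one contiguous column of `n` values
  void run_columns(cxd* a, bool inverse, cxd* scratch) const {
    for (int i = 0; i < n; ++i)
      if (i < rev[i]) {
        std::memcpy(scratch, a + (size_t)i * n, n * sizeof(cxd));
        std::memcpy(a + (size_t)i * n, a + (size_t)rev[i] * n, n * sizeof(cxd));
        std::memcpy(a + (size_t)rev[i] * n, scratch, n * sizeof(cxd));
      }
    size_t toff = 0;
    for (int len = 2; len <= n; len <<= 1) {
      const int half = len / 2;
      for (int i = 0; i < n; i += len)
        for (int j = 0; j < half; ++j) {
          cxd w = tw[toff + j];
          if (inverse) w = std::conj(w);
          cxd* c1 = a + (size_t)(i + j) * n;
          cxd* c2 = a + (size_t)(i + j + half) * n;
          for (int k = 0; k < n; ++k) {
            cxd v = c2[k] * w;
            c2[k] = c1[k] - v;
            c1[k] += v;
          }
        }
      toff += half;
    }
  }
};

bool is_pow2(int n) { return n > 0 && (n & (n - 1)) == 0; }

}  // namespace

// [[Rcpp::export]]
arma::cx_mat centered_dft2_stack(const arma::cx_mat& stack, int side, bool inverse) {
  if (side % 2 != 0) Rcpp::stop("side must be even");
  if ((int)stack.n_rows != side * side) Rcpp::stop("stack rows must be side^2");
  const arma::uword n_frames = stack.n_cols;
  const int h = side / 2;
  arma::cx_mat out(stack.n_rows, n_frames);
  std::vector<int> sh(side);                // fftshift == ifftshift (even)
  for (int i = 0; i < side; ++i) sh[i] = (i + h) % side;
  const double scale = 1.0 / side;          // unitary both directions
  if (is_pow2(side)) {
    Radix2Plan plan(side);
    std::vector<cxd> A((size_t)side * side), scratch(side);
    for (arma::uword f = 0; f < n_frames; ++f) {
      const arma::cx_double* src = stack.colptr(f);
      for (int c = 0; c < side; ++c) {
        cxd* dst = &A[(size_t)c * side];
        const arma::cx_double* s0 = src + (size_t)sh[c] * side;
        for (int r = 0; r < side; ++r) dst[r] = s0[sh[r]];
      }
      for (int c = 0; c < side; ++c) plan.run(&A[(size_t)c * side], inverse);
      plan.run_columns(A.data(), inverse, scratch.data());
      arma::cx_double* dst = out.colptr(f);
      for (int c = 0; c < side; ++c) {
        arma::cx_double* d0 = dst + (size_t)sh[c] * side;
        const cxd* s0 = &A[(size_t)c * side];
        for (int r = 0; r < side; ++r) d0[sh[r]] = s0[r] * scale;
      }
    }
  } else {
    arma::cx_mat A(side, side), B(side, side);
    for (arma::uword f = 0; f < n_frames; ++f) {
      const arma::cx_double* src = stack.colptr(f);
      for (int c = 0; c < side; ++c)
        for (int r = 0; r < side; ++r)
          A(r, c) = src[(size_t)sh[c] * side + sh[r]];
      B = inverse ? arma::cx_mat(arma::ifft2(A) * (double)(side * side))
                  : arma::cx_mat(arma::fft2(A));
      arma::cx_double* dst = out.colptr(f);
      for (int c = 0; c < side; ++c)
        for (int r = 0; r < side; ++r)
          dst[(size_t)c * side + r] = B(sh[r], sh[c]) * scale;
    }
  }
  return out;
}
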