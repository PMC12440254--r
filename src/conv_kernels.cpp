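// im2col / col2im for 1-D "same" convolutions, and a fused column-wise
// affine transform. Time-major flat layout: row n + t*N of an (N*L x C)
// matrix is sample n at time step t (matching R's (N, L, C) arrays).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Builds the patch matrix (N*L x k*C + 1); the trailing ones column
// carries the bias through the subsequent GEMM. Out-of-range taps are
// zero (symmetric "same" padding).
// [[Rcpp::export(name = ".cpp_im2col")]]
arma::mat cpp_im2col(const arma::mat& xflat, int N, int L, int k) {
  const int C = xflat.n_cols;
  const int pl = (k - 1) / 2;
  mat out((uword)N * L, (uword)k * C + 1, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = xflat.colptr(c);
    for (int j = 0; j < k; ++j) {
      double* dst = out.colptr((uword)j * C + c);
      for (int l = 0; l < L; ++l) {
        const int ls = l + j - pl;
        if (ls >= 0 && ls < L)
          std::memcpy(dst + (size_t)l * N, src + (size_t)ls * N,
                      sizeof(double) * N);
      }
    }
  }
  out.col((uword)k * C).ones();
  return out;
}

// Adjoint of im2col (without the ones column): scatter-adds patch
// gradients back onto the (N*L x C) input gradient.
// [[Rcpp::export(name = ".cpp_col2im")]]
arma::mat cpp_col2im(const arma::mat& dXcol, int N, int L, int k, int C) {
  const int pl = (k - 1) / 2;
  mat dx((uword)N * L, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dx.colptr(c);
    for (int j = 0; j < k; ++j) {
      const double* src = dXcol.colptr((uword)j * C + c);
      for (int l = 0; l < L; ++l) {
        const int ls = l + j - pl;
        if (ls >= 0 && ls < L) {
          const double* s = src + (size_t)l * N;
          double* d = dst + (size_t)ls * N;
          for (int n = 0; n < N; ++n) d[n] += s[n];
        }
      }
    }
  }
  return dx;
}

// out[i, c] = x[i, c] * a[c] + b[c], one pass over the matrix
// [[Rcpp::export(name = ".cpp_affine_cols")]]
arma::mat cpp_affine_cols(const arma::mat& x, const arma::vec& a,
                          const arma::vec& b) {
  mat out(x.n_rows, x.n_cols);
  for (uword c = 0; c < x.n_cols; ++c) {
    const double ac = a(c), bc = b(c);
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    for (uword i = 0; i < x.n_rows; ++i) dst[i] = src[i] * ac + bc;
  }
  return out;
}
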