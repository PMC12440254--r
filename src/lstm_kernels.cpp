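// LSTM cell recurrences (forward + BPTT backward).
//
// The input projection X * Wx + b is computed on the R side as one large
// BLAS product; these kernels run only the sequential recurrent part.
// Time-major flat layout throughout: row n + (t-1)*N of an (N*L x k)
// matrix holds sample n at time step t, matching R's array((N, L, k))
// flattening.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const arma::mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export(name = ".cpp_lstm_forward")]]
Rcpp::List cpp_lstm_forward(const arma::mat& Xproj, const arma::mat& Wh,
                            int N, int L, int H, bool want_cache) {
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  mat Hseq(N * L, H), Gi, Gf, Gg, Go, Tc, Cs;
  if (want_cache) {
    Gi.set_size(N * L, H); Gf.set_size(N * L, H); Gg.set_size(N * L, H);
    Go.set_size(N * L, H); Tc.set_size(N * L, H); Cs.set_size(N * L, H);
  }
  for (int t = 0; t < L; ++t) {
    const uword r0 = (uword)t * N, r1 = r0 + N - 1;
    mat z = Xproj.rows(r0, r1) + h * Wh;
    mat i = sigm(z.cols(0, H - 1));
    mat f = sigm(z.cols(H, 2 * H - 1));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = sigm(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    Hseq.rows(r0, r1) = h;
    if (want_cache) {
      Gi.rows(r0, r1) = i; Gf.rows(r0, r1) = f; Gg.rows(r0, r1) = g;
      Go.rows(r0, r1) = o; Tc.rows(r0, r1) = tc; Cs.rows(r0, r1) = c;
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("Hseq") = Hseq, Rcpp::Named("last_h") = h);
  if (want_cache) {
    out["Gi"] = Gi; out["Gf"] = Gf; out["Gg"] = Gg;
    out["Go"] = Go; out["Tc"] = Tc; out["Cs"] = Cs;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_lstm_backward")]]
Rcpp::List cpp_lstm_backward(const arma::mat& dout, const arma::mat& Hseq,
                             const arma::mat& Gi, const arma::mat& Gf, const arma::mat& Gg,
                             const arma::mat& Go, const arma::mat& Tc, const arma::mat& Cs,
                             const arma::mat& Wh, int N, int L, int H,
                             bool seq_grad) {
  mat dZ(N * L, 4 * H);
  mat dWh(H, 4 * H, fill::zeros);
  mat dh_next(N, H, fill::zeros), dc_next(N, H, fill::zeros);
  const mat WhT = Wh.t();
  for (int t = L - 1; t >= 0; --t) {
    const uword r0 = (uword)t * N, r1 = r0 + N - 1;
    mat dh = dh_next;
    if (seq_grad) dh += dout.rows(r0, r1);
    else if (t == L - 1) dh += dout;
    const mat i = Gi.rows(r0, r1), f = Gf.rows(r0, r1);
    const mat g = Gg.rows(r0, r1), o = Go.rows(r0, r1);
    const mat tc = Tc.rows(r0, r1);
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat c_prev(N, H, fill::zeros), h_prev(N, H, fill::zeros);
    if (t > 0) {
      c_prev = Cs.rows(r0 - N, r0 - 1);
      h_prev = Hseq.rows(r0 - N, r0 - 1);
    }
    mat dz(N, 4 * H);
    dz.cols(0, H - 1) = dc % g % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = dc % c_prev % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = dc % i % (1.0 - g % g);
    dz.cols(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
    dZ.rows(r0, r1) = dz;
    dWh += h_prev.t() * dz;
    dh_next = dz * WhT;
    dc_next = dc % f;
  }
  return Rcpp::List::create(Rcpp::Named("dZ") = dZ,
                            Rcpp::Named("dWh") = dWh);
}
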