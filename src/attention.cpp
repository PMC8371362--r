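// Channel-attention mixing: per-slice small GEMMs (one M x M weight matrix
// per segment-sample slice). Softmax and score computation stay in R where
// they are single large matrix operations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;

// A: (d_a, M, S), W: (M, M, S) -> Ahat[, , s] = A[, , s] * W[, , s]
// [[Rcpp::export(name = ".att_mix_fwd_cpp")]]
arma::cube att_mix_fwd_cpp(const arma::cube& A, const arma::cube& W) {
  const int S = A.n_slices;
  cube Ahat(A.n_rows, A.n_cols, S);
  for (int s = 0; s < S; ++s) Ahat.slice(s) = A.slice(s) * W.slice(s);
  return Ahat;
}

// Gradients of the per-slice mix: dA = dAhat * W^T, dW = A^T * dAhat.
// [[Rcpp::export(name = ".att_mix_bwd_cpp")]]
List att_mix_bwd_cpp(const arma::cube& A, const arma::cube& W,
                     const arma::cube& dAhat) {
  const int S = A.n_slices;
  cube dA(A.n_rows, A.n_cols, S);
  cube dW(W.n_rows, W.n_cols, S);
  for (int s = 0; s < S; ++s) {
    dA.slice(s) = dAhat.slice(s) * W.slice(s).t();
    dW.slice(s) = A.slice(s).t() * dAhat.slice(s);
  }
  return List::create(_["dA"] = dA, _["dW"] = dW);
}
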