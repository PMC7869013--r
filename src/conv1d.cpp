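// 1D convolution kernels for the branch networks.
// Layout: X is (in_ch x L), W is (out_ch x in_ch*K) with the K taps of one
// input channel contiguous (column block k*in_ch + c), Y is (out_ch x L).
// 'same' alignment: output column j sees input columns j - pad .. j - pad + K - 1
// with pad = (K - 1) / 2 (integer division), zeros outside.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::mat& X, const arma::mat& W,
                     const arma::vec& b, const int K) {
  const int in_ch = X.n_rows, L = X.n_cols, out_ch = W.n_rows;
  const int pad = (K - 1) / 2;
  mat Y(out_ch, L);
  Y.each_col() = b;
  for (int k = 0; k < K; ++k) {
    // input column index for output j is j + k - pad
    int j0 = std::max(0, pad - k);            // first output col with valid input
    int j1 = std::min(L - 1, L - 1 + pad - k);// last
    if (j0 > j1) continue;
    const mat Wk = W.cols(k * in_ch, (k + 1) * in_ch - 1);
    Y.cols(j0, j1) += Wk * X.cols(j0 + k - pad, j1 + k - pad);
  }
  return Y;
}

// gradient w.r.t. input: full correlation with flipped kernel
// [[Rcpp::export]]
arma::mat conv1d_bwd_x(const arma::mat& dY, const arma::mat& W,
                       const int in_ch, const int K) {
  const int L = dY.n_cols;
  const int pad = (K - 1) / 2;
  mat dX(in_ch, L, fill::zeros);
  for (int k = 0; k < K; ++k) {
    int j0 = std::max(0, pad - k);
    int j1 = std::min(L - 1, L - 1 + pad - k);
    if (j0 > j1) continue;
    const mat Wk = W.cols(k * in_ch, (k + 1) * in_ch - 1);
    dX.cols(j0 + k - pad, j1 + k - pad) += Wk.t() * dY.cols(j0, j1);
  }
  return dX;
}

// gradients w.r.t. weights and bias
// [[Rcpp::export]]
Rcpp::List conv1d_bwd_w(const arma::mat& dY, const arma::mat& X, const int K) {
  const int in_ch = X.n_rows, L = X.n_cols, out_ch = dY.n_rows;
  const int pad = (K - 1) / 2;
  mat dW(out_ch, in_ch * K, fill::zeros);
  for (int k = 0; k < K; ++k) {
    int j0 = std::max(0, pad - k);
    int j1 = std::min(L - 1, L - 1 + pad - k);
    if (j0 > j1) continue;
    dW.cols(k * in_ch, (k + 1) * in_ch - 1) =
      dY.cols(j0, j1) * X.cols(j0 + k - pad, j1 + k - pad).t();
  }
  vec db = sum(dY, 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}
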