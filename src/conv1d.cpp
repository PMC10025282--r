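// Batched 1D convolution kernels for the network layers. Batches travel as
// channel x (batch * length) concatenations; each kernel offset contributes
// one GEMM, computed in place to avoid the allocation churn of the
// equivalent R indexing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: C x (B*Tin); W: O x C x K (flattened O x (C*K) column-major by k);
// returns O x (B*Tout), Tout = Tin - K + 1.
// [[Rcpp::export(name = ".conv1dForward")]]
arma::mat conv1dForward(const arma::mat& X, const arma::cube& W,
                        const arma::vec& b, int B, int Tin) {
  const int K = W.n_slices, O = W.n_rows;
  const int Tout = Tin - K + 1;
  mat Y(O, (std::size_t)B * Tout);
  Y.each_col() = b;
  for (int s = 0; s < B; ++s) {
    const std::size_t xo = (std::size_t)s * Tin;
    const std::size_t yo = (std::size_t)s * Tout;
    for (int k = 0; k < K; ++k) {
      Y.cols(yo, yo + Tout - 1) +=
        W.slice(k) * X.cols(xo + k, xo + k + Tout - 1);
    }
  }
  return Y;
}

// Gradients of the batched convolution: dY is O x (B*Tout).
// [[Rcpp::export(name = ".conv1dBackward")]]
Rcpp::List conv1dBackward(const arma::mat& dY, const arma::mat& X,
                          const arma::cube& W, int B, int Tin) {
  const int K = W.n_slices, O = W.n_rows, C = W.n_cols;
  const int Tout = Tin - K + 1;
  cube dW(O, C, K, fill::zeros);
  mat dX(C, X.n_cols, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const std::size_t xo = (std::size_t)s * Tin;
    const std::size_t yo = (std::size_t)s * Tout;
    const mat dYs = dY.cols(yo, yo + Tout - 1);
    for (int k = 0; k < K; ++k) {
      dW.slice(k) += dYs * X.cols(xo + k, xo + k + Tout - 1).t();
      dX.cols(xo + k, xo + k + Tout - 1) += W.slice(k).t() * dYs;
    }
  }
  vec db = sum(dY, 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
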