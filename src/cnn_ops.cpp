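// Hot loops of the dilated convolutional network: per-tap gathered
// matrix products over channel x pixel activation matrices. Index
// vectors (0-based) are precomputed in R; each tap m maps input pixels
// idx_in[m] onto output pixels idx_out[m].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cnn_tap_conv(const arma::mat& X, const arma::cube& W,
                       const List& idx_out, const List& idx_in,
                       const IntegerVector& tap_m,
                       const arma::vec& b, int P_out) {
  const int C_out = W.n_rows;
  arma::mat Y(C_out, P_out);
  Y.each_col() = b;
  for (int t = 0; t < idx_out.size(); ++t) {
    arma::uvec o = as<arma::uvec>(idx_out[t]);
    arma::uvec i = as<arma::uvec>(idx_in[t]);
    Y.cols(o) += W.slice(tap_m[t]) * X.cols(i);
  }
  return Y;
}

// [[Rcpp::export]]
List cnn_tap_backward(const arma::mat& dY, const arma::mat& X,
                      const arma::cube& W, const List& idx_out,
                      const List& idx_in, const IntegerVector& tap_m,
                      int P_in, bool need_dx) {
  arma::cube dW(W.n_rows, W.n_cols, W.n_slices, arma::fill::zeros);
  arma::mat dX;
  if (need_dx) dX.zeros(W.n_cols, P_in);
  for (int t = 0; t < idx_out.size(); ++t) {
    arma::uvec o = as<arma::uvec>(idx_out[t]);
    arma::uvec i = as<arma::uvec>(idx_in[t]);
    arma::mat dYo = dY.cols(o);
    dW.slice(tap_m[t]) += dYo * X.cols(i).t();
    if (need_dx) dX.cols(i) += W.slice(tap_m[t]).t() * dYo;
  }
  arma::vec db = arma::sum(dY, 1);
  if (need_dx)
    return List::create(Named("dW") = dW, Named("db") = db,
                        Named("dX") = dX);
  return List::create(Named("dW") = dW, Named("db") = db);
}
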