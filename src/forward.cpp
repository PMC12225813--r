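// Hot path of the Mushroom-Body forward pass: sparse vPN->KC input
// summation and APL top-k novelty readout, batched over facing directions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// KC input matrix: W (n_kc x n_vpn, sparse) times V (n_vpn x m, dense).
// [[Rcpp::export(name = ".kc_input_cpp")]]
arma::mat kc_input_cpp(const arma::sp_mat& W, const arma::mat& V) {
  return arma::mat(W * V);
}

// Per-column APL readout. For each column of IN: the k cells with the
// largest input fire; ties at the threshold are broken by ascending index;
// cells with zero input never fire. Returns the sum of w over firing cells
// per column (the MBON output).
// [[Rcpp::export(name = ".apl_novelty_cols_cpp")]]
arma::rowvec apl_novelty_cols_cpp(const arma::mat& IN, const arma::vec& w,
                                  const int k) {
  const arma::uword n = IN.n_rows, m = IN.n_cols;
  arma::rowvec out(m, arma::fill::zeros);
  if (k <= 0) return out;
  std::vector<double> buf(n);
  for (arma::uword j = 0; j < m; ++j) {
    const double* x = IN.colptr(j);
    double nov = 0.0;
    if ((arma::uword)k >= n) {
      for (arma::uword i = 0; i < n; ++i)
        if (x[i] > 0) nov += w(i);
    } else {
      std::copy(x, x + n, buf.begin());
      std::nth_element(buf.begin(), buf.begin() + (n - k), buf.end());
      const double thr = buf[n - k];
      int n_above = 0;
      for (arma::uword i = 0; i < n; ++i)
        if (x[i] > thr) { if (x[i] > 0) nov += w(i); ++n_above; }
      int m_tie = k - n_above;
      for (arma::uword i = 0; i < n && m_tie > 0; ++i)
        if (x[i] == thr) { if (x[i] > 0) nov += w(i); --m_tie; }
    }
    out(j) = nov;
  }
  return out;
}
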