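#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// b, a must be same length with a(0) == 1; zi has length(b) - 1.
// [[Rcpp::export]]
arma::vec df2t_filter(const arma::vec& b, const arma::vec& a,
                      const arma::vec& x, const arma::vec& zi) {
  const int n = x.n_elem;
  const int m = b.n_elem;
  arma::vec z = zi;
  arma::vec y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x(i);
    const double yi = b(0) * xi + (m > 1 ? z(0) : 0.0);
    for (int j = 0; j < m - 2; ++j)
      z(j) = b(j + 1) * xi + z(j + 1) - a(j + 1) * yi;
    if (m > 1)
      z(m - 2) = b(m - 1) * xi - a(m - 1) * yi;
    y(i) = yi;
  }
  return y;
}
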