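// Amplitude-envelope-correlation kernel.
//
// Leakage correction is pairwise time-domain orthogonalization of the
// band-limited signals; because the Hilbert transform is linear, the
// analytic signal of (y - b x) is A_y - b A_x, so one analytic matrix per
// epoch serves all pairs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// A: n_roi x T complex analytic band-limited signals (rows = ROIs).
// Returns D (n x n) with D(i,j) = Pearson corr over the interior samples of
// env(x_i) and env(x_j orthogonalized to x_i); diagonal and degenerate pairs
// (residual numerically proportional to zero) are NaN.
// [[Rcpp::export]]
arma::mat aec_directional_cpp(const arma::cx_mat& A, double guard_frac) {
  const arma::uword n = A.n_rows, T = A.n_cols;
  const arma::uword g = static_cast<arma::uword>(std::floor(guard_frac * T));
  const arma::uword lo = g, hi = T - g - 1;  // inclusive interior span
  const arma::uword Ti = hi - lo + 1;

  arma::mat X = arma::real(A);              // band-limited real signals
  arma::mat G = X * X.t();                  // gram matrix for regressions

  // interior real/imag parts, transposed so time is the fast index
  arma::mat Ar = X.cols(lo, hi).t();        // Ti x n
  arma::mat Aim = arma::imag(A.cols(lo, hi)).t();

  // envelopes of the raw signals, centered, with norms
  arma::mat E(Ti, n);
  for (arma::uword j = 0; j < n; ++j) {
    const double* pr = Ar.colptr(j);
    const double* pi = Aim.colptr(j);
    double* pe = E.colptr(j);
    for (arma::uword t = 0; t < Ti; ++t)
      pe[t] = std::sqrt(pr[t] * pr[t] + pi[t] * pi[t]);
  }
  arma::rowvec emean = arma::mean(E, 0);
  arma::rowvec escale(n);
  for (arma::uword j = 0; j < n; ++j)
    escale(j) = std::sqrt(arma::mean(arma::square(E.col(j))));
  arma::mat Ec = E.each_row() - emean;
  arma::rowvec enorm(n);
  for (arma::uword j = 0; j < n; ++j)
    enorm(j) = std::sqrt(arma::dot(Ec.col(j), Ec.col(j)));

  arma::mat D(n, n);
  D.fill(arma::datum::nan);

  for (arma::uword i = 0; i < n; ++i) {
    if (G(i, i) <= 0 || enorm(i) <= 0) continue;
    const double* xr = Ar.colptr(i);
    const double* xi = Aim.colptr(i);
    const double* ei = Ec.colptr(i);
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      const double b = G(j, i) / G(i, i);
      const double* yr = Ar.colptr(j);
      const double* yi = Aim.colptr(j);
      // single pass: residual envelope e_t, accumulate moments and the
      // cross-product with the centered envelope of i
      double s1 = 0.0, s2 = 0.0, sx = 0.0;
      for (arma::uword t = 0; t < Ti; ++t) {
        const double rr = yr[t] - b * xr[t];
        const double ri = yi[t] - b * xi[t];
        const double e = std::sqrt(rr * rr + ri * ri);
        s1 += e;
        s2 += e * e;
        sx += e * ei[t];
      }
      const double varn = s2 - s1 * s1 / double(Ti);
      // degenerate: x_j proportional to x_i, residual envelope ~ constant 0
      if (varn <= 1e-20 * double(Ti) * escale(j) * escale(j)) continue;
      D(i, j) = sx / (std::sqrt(varn) * enorm(i));
    }
  }
  return D;
}
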