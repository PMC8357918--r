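// Allocation-light kernels for the source simulator and sensor projection.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// declared in rng.cpp
NumericVector gaussian_stream_cpp(double n, double seed);

// out = bg + amp_a * ca .* ea + amp_b * cb .* eb, all time-major (n x roi)
// [[Rcpp::export]]
NumericMatrix combine_bands_cpp(const NumericMatrix& bg,
                                const NumericMatrix& ca,
                                const NumericMatrix& ea,
                                const NumericMatrix& cb,
                                const NumericMatrix& eb,
                                double amp_a, double amp_b) {
  const R_xlen_t N = bg.size();
  NumericMatrix out(bg.nrow(), bg.ncol());
  const double *pbg = bg.begin(), *pca = ca.begin(), *pea = ea.begin(),
               *pcb = cb.begin(), *peb = eb.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < N; ++i)
    po[i] = pbg[i] + amp_a * pca[i] * pea[i] + amp_b * pcb[i] * peb[i];
  return out;
}

// transpose time-major (n x roi) to roi x n, removing the per-column mean
// and scaling each ROI by its dipole amplitude
// [[Rcpp::export]]
NumericMatrix finalize_source_cpp(const NumericMatrix& x,
                                  const NumericVector& roi_amp) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(m, n);
  for (int j = 0; j < m; ++j) {
    const double* pc = &x(0, j);
    double mu = 0.0;
    for (int t = 0; t < n; ++t) mu += pc[t];
    mu /= n;
    const double a = roi_amp[j];
    for (int t = 0; t < n; ++t) out(j, t) = (pc[t] - mu) * a;
  }
  return out;
}

// linear interpolation of envelope rows onto the carrier grid with unit-RMS
// column normalization; E is K x roi, idx/frac have length n (idx 1-based)
// [[Rcpp::export]]
NumericMatrix env_interp_cpp(const NumericMatrix& E,
                             const IntegerVector& idx,
                             const NumericVector& frac) {
  const int n = idx.size(), m = E.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double* pe = &E(0, j);
    double* po = &out(0, j);
    double ss = 0.0;
    for (int t = 0; t < n; ++t) {
      const int k = idx[t] - 1;
      const double v = pe[k] * (1.0 - frac[t]) + pe[k + 1] * frac[t];
      po[t] = v;
      ss += v * v;
    }
    const double s = std::sqrt(ss / n);
    if (s > 0) for (int t = 0; t < n; ++t) po[t] /= s;
  }
  return out;
}

// add white Gaussian noise (per-row standard deviation) in place
// [[Rcpp::export]]
void add_noise_cpp(NumericMatrix data, const NumericVector& sd_row,
                   double seed) {
  const int m = data.nrow();
  const R_xlen_t N = data.size();
  NumericVector z = gaussian_stream_cpp(double(N), seed);
  double* pd = data.begin();
  const double* pz = z.begin();
  for (R_xlen_t i = 0; i < N; ++i) pd[i] += pz[i] * sd_row[i % m];
}

// Assemble the packed random spectrum for one or two band-limited real
// carriers (real part = profile A, imaginary part = profile B), drawing
// from R's RNG. prof vectors cover bins 0..n-1; only bins 1..half are used.
// [[Rcpp::export]]
ComplexMatrix spectrum_noise_cpp(int n, int n_roi,
                                 const NumericVector& prof_a,
                                 Nullable<NumericVector> prof_b) {
  const int half = (n - 1) / 2;
  ComplexMatrix X(n, n_roi);
  const bool two = prof_b.isNotNull();
  NumericVector pb;
  if (two) pb = prof_b.get();
  for (int j = 0; j < n_roi; ++j) {
    Rcomplex* col = &X(0, j);
    for (int k = 1; k <= half; ++k) {
      double ar = 0.0, ai = 0.0, br = 0.0, bi = 0.0;
      const double wa = prof_a[k];
      if (wa > 0) { ar = norm_rand() * wa; ai = norm_rand() * wa; }
      if (two) {
        const double wb = pb[k];
        if (wb > 0) { br = norm_rand() * wb; bi = norm_rand() * wb; }
      }
      if (wa > 0 || (two && pb[k] > 0)) {
        // upper half: A + iB ; lower half: conj(A) + i conj(B)
        col[k].r = ar - bi;      col[k].i = ai + br;
        col[n - k].r = ar + bi;  col[n - k].i = -ai + br;
      }
    }
  }
  return X;
}
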