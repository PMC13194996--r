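// Fast IIR filtering for long multichannel recordings: direct form II
// transposed single-pass filtering and zero-phase forward-backward
// filtering with odd-extension edge padding.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Direct form II transposed: y[n] = b0*x[n] + z0;  z_i = b_{i+1}*x[n] +
// z_{i+1} - a_{i+1}*y[n]. Coefficients must be normalized (a[0] == 1).
static vec df2t(const vec& b, const vec& a, const vec& x) {
  const uword nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  const uword nz = std::max(nb, na) - 1;
  vec bz(nz + 1, fill::zeros), az(nz + 1, fill::zeros);
  bz.head(nb) = b;
  az.head(na) = a;
  vec z(nz, fill::zeros), y(n);
  for (uword i = 0; i < n; ++i) {
    const double xi = x(i);
    const double yi = bz(0) * xi + (nz ? z(0) : 0.0);
    for (uword j = 0; j + 1 < nz; ++j)
      z(j) = bz(j + 1) * xi + z(j + 1) - az(j + 1) * yi;
    if (nz) z(nz - 1) = bz(nz) * xi - az(nz) * yi;
    y(i) = yi;
  }
  return y;
}

// [[Rcpp::export]]
arma::vec iir_filter_cpp(arma::vec b, arma::vec a, arma::vec x) {
  if (a.n_elem == 0 || a(0) == 0) Rcpp::stop("a[0] must be non-zero");
  if (a(0) != 1.0) { b /= a(0); a /= a(0); }
  return df2t(b, a, x);
}

// Zero-phase filtering: odd extension of ~3 filter lengths at both edges,
// forward pass, time reversal, forward pass, reversal, trim.
// [[Rcpp::export]]
arma::vec filtfilt_cpp(arma::vec b, arma::vec a, arma::vec x) {
  if (a.n_elem == 0 || a(0) == 0) Rcpp::stop("a[0] must be non-zero");
  if (a(0) != 1.0) { b /= a(0); a /= a(0); }
  const uword n = x.n_elem;
  const uword pad = 3 * (std::max(a.n_elem, b.n_elem) - 1);
  if (n <= pad + 1) Rcpp::stop("signal too short for zero-phase filtering");
  vec ext(n + 2 * pad);
  for (uword i = 0; i < pad; ++i)
    ext(i) = 2 * x(0) - x(pad - i);
  ext.subvec(pad, pad + n - 1) = x;
  for (uword i = 0; i < pad; ++i)
    ext(pad + n + i) = 2 * x(n - 1) - x(n - 2 - i);
  vec y = df2t(b, a, ext);
  y = reverse(y);
  y = df2t(b, a, y);
  y = reverse(y);
  return y.subvec(pad, pad + n - 1);
}
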