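#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// direct form II transposed, zero initial state; a[0] must be 1
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 const double* x, double* y, int n, int nz) {
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (nz > 0) z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
}

// Single-pass IIR filtering, zero initial conditions.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  const int n = x.size();
  const int nz = std::max(a.size(), b.size()) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  NumericVector y(n);
  df2t(bb, aa, REAL(x), REAL(y), n, nz);
  return y;
}

// Zero-phase forward-backward filtering with odd (point-reflected)
// end extension of pad_len samples; returns a vector of length(x).
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a,
                           NumericVector x, int pad_len) {
  const int n = x.size();
  if (pad_len > n - 1) pad_len = n - 1;
  if (pad_len < 0) pad_len = 0;
  const int m = n + 2 * pad_len;
  const int nz = std::max(a.size(), b.size()) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];

  std::vector<double> xe(m), tmp(m);
  const double* px = REAL(x);
  for (int i = 0; i < pad_len; ++i)
    xe[i] = 2.0 * px[0] - px[pad_len - i];
  std::copy(px, px + n, xe.begin() + pad_len);
  for (int i = 0; i < pad_len; ++i)
    xe[pad_len + n + i] = 2.0 * px[n - 1] - px[n - 2 - i];

  df2t(bb, aa, xe.data(), tmp.data(), m, nz);
  std::reverse(tmp.begin(), tmp.end());
  df2t(bb, aa, tmp.data(), xe.data(), m, nz);
  std::reverse(xe.begin(), xe.end());

  NumericVector y(n);
  std::copy(xe.begin() + pad_len, xe.begin() + pad_len + n, REAL(y));
  return y;
}
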