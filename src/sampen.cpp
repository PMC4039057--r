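#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy (Chebyshev distance, self-matches
// excluded). Both template lengths range over the first N - m starting
// points so every length-m template has a defined m+1 extension.
// Returns c(B, A): matches at length m and at length m + 1.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int n = N - m;
  double B = 0.0, A = 0.0;
  if (n < 2) return NumericVector::create(0.0, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Per-(channel, epoch) maximum absolute amplitude of a C x E x T cube.
// [[Rcpp::export]]
NumericMatrix cell_absmax(NumericVector data, int C, int E, int T) {
  NumericMatrix out(C, E);
  const double *p = data.begin();
  for (int t = 0; t < T; ++t) {
    const double *slab = p + (R_xlen_t)t * C * E;
    double *o = out.begin();
    for (R_xlen_t i = 0; i < (R_xlen_t)C * E; ++i) {
      double a = std::fabs(slab[i]);
      if (a > o[i]) o[i] = a;
    }
  }
  return out;
}

// Column-wise medians (average-of-middle-two convention for even counts).
// [[Rcpp::export]]
NumericVector col_medians(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(p);
  std::vector<double> buf(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    const int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = (med + lo) / 2.0;
    }
    out[j] = med;
  }
  return out;
}
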