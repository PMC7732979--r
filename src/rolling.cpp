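#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Centered rolling quantile with edge truncation. Quantile uses linear
// interpolation between order statistics (stats::quantile type 7) so the
// result is bit-identical to the brute-force R computation.
// [[Rcpp::export]]
NumericVector roll_quantile_cpp(NumericVector x, int half, double p) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * half + 1);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    std::sort(buf.begin(), buf.end());
    // replicate stats::quantile type 7 arithmetic exactly
    double index = 1.0 + (m - 1) * p;
    int k = (int)std::floor(index);
    double qs = buf[k - 1];
    if (index > k && k < m && buf[k] != qs) {
      double h = index - k;
      qs = (1.0 - h) * qs + h * buf[k];
    }
    out[i] = qs;
  }
  return out;
}

// Companion rolling standard deviation (n-1 denominator), same windows.
// [[Rcpp::export]]
NumericVector roll_sd_cpp(NumericVector x, int half) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    int m = hi - lo + 1;
    if (m < 2) { out[i] = NA_REAL; continue; }
    double mean = 0.0;
    for (int j = lo; j <= hi; ++j) mean += x[j];
    mean /= m;
    double ss = 0.0;
    for (int j = lo; j <= hi; ++j) ss += (x[j] - mean) * (x[j] - mean);
    out[i] = std::sqrt(ss / (m - 1));
  }
  return out;
}
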