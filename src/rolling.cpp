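#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centered rolling window bounds: for window width n_win the window at i
// spans [i - left, i + right] with left = floor((n_win - 1) / 2) and
// right = n_win - 1 - left (for even widths the window extends one sample
// further forward). Edges truncate to the available samples.
static inline void window_bounds(int i, int n, int left, int right,
                                 int &lo, int &hi) {
  lo = i - left;  if (lo < 0) lo = 0;
  hi = i + right; if (hi > n - 1) hi = n - 1;
}

// [[Rcpp::export]]
NumericVector roll_median_c(NumericVector x, int n_win) {
  const int n = x.size();
  const int left = (n_win - 1) / 2;
  const int right = n_win - 1 - left;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(n_win);
  for (int i = 0; i < n; ++i) {
    int lo, hi;
    window_bounds(i, n, left, right, lo, hi);
    const int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const int mid = m / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (m % 2 == 0) {
      double lower = *std::max_element(buf.begin(), buf.begin() + mid);
      med = 0.5 * (med + lower);
    }
    out[i] = med;
  }
  return out;
}

// Mean Amplitude Deviation per centered window: mean(|x - mean(window)|).
// [[Rcpp::export]]
NumericVector roll_mad_c(NumericVector x, int n_win) {
  const int n = x.size();
  const int left = (n_win - 1) / 2;
  const int right = n_win - 1 - left;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo, hi;
    window_bounds(i, n, left, right, lo, hi);
    const int m = hi - lo + 1;
    double mean = 0.0;
    for (int j = lo; j <= hi; ++j) mean += x[j];
    mean /= m;
    double acc = 0.0;
    for (int j = lo; j <= hi; ++j) acc += std::fabs(x[j] - mean);
    out[i] = acc / m;
  }
  return out;
}
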