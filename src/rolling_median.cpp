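#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Rolling median with an even window of length `width` covering samples
// [i - width/2, i + width/2 - 1] around each index i, with reflection
// padding at the edges. An even window has no unique centre; this left-heavy
// convention keeps the filter phase-free to within half a sample.
// [[Rcpp::export(name = ".rolling_median_even")]]
NumericVector rolling_median_even(NumericVector x, int width) {
  int n = x.size();
  if (width < 2 || width % 2 != 0) stop("width must be an even integer >= 2");
  if (n < 1) return NumericVector(0);
  int half = width / 2; // window offsets: -half .. half-1
  // reflect: index -1 -> 0, -2 -> 1, ...; n -> n-1, n+1 -> n-2, ...
  std::vector<double> pad(n + width);
  for (int i = -half; i < n + half; ++i) {
    int j = i;
    if (j < 0) j = -j - 1;
    if (j >= n) j = 2 * n - j - 1;
    if (j < 0) j = 0; // very short inputs: clamp after double reflection
    if (j >= n) j = n - 1;
    pad[i + half] = x[j];
  }
  NumericVector out(n);
  std::vector<double> win(width);
  for (int i = 0; i < n; ++i) {
    std::copy(pad.begin() + i, pad.begin() + i + width, win.begin());
    std::nth_element(win.begin(), win.begin() + half - 1, win.end());
    double lo = win[half - 1];
    double hi = *std::min_element(win.begin() + half, win.end());
    out[i] = (lo + hi) / 2.0; // even window: mean of the two middle values
  }
  return out;
}
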