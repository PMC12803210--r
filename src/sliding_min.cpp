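#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window minimum with edge truncation (monotonic deque, O(n)).
// For frame t (0-based) the window is [max(0, t - left), min(n - 1, t + right)];
// centered windows split width-1 as left = (width-1)/2, right = rest, so the
// window always contains t. Both endpoints are nondecreasing in t, which is
// what the deque requires.
// [[Rcpp::export]]
NumericVector sliding_min_cpp(NumericVector x, int width, bool centered) {
  int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  if (width < 1) stop("window width must be >= 1");
  int left, right;
  if (centered) {
    left = (width - 1) / 2;
    right = width - 1 - left;
  } else {
    left = width - 1;
    right = 0;
  }
  std::deque<int> dq;
  int j = -1;
  for (int t = 0; t < n; ++t) {
    int r = t + right;
    if (r > n - 1) r = n - 1;
    while (j < r) {
      ++j;
      while (!dq.empty() && x[dq.back()] >= x[j]) dq.pop_back();
      dq.push_back(j);
    }
    int l = t - left;
    if (l < 0) l = 0;
    while (dq.front() < l) dq.pop_front();
    out[t] = x[dq.front()];
  }
  return out;
}
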