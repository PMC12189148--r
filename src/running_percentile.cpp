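#include <Rcpp.h>
#include <set>

using namespace Rcpp;

// Causal sliding-window order statistic, columnwise.
//
// For frame t (0-based) the window holds the last min(t + 1, window) values
// of the column; the returned value is the k-th smallest with
// k = ceil(p * n), n the current occupancy. During warm-up (t + 1 < window)
// the window is simply the available history.
//
// Two-multiset scheme: `low` holds the k smallest window members, `high`
// the rest, so each frame costs O(log window) regardless of window length.
// Output is required to be bit-identical to the naive sort-based
// percentile, which both sides guarantee by selecting an actual window
// member (no interpolation) with k computed as ceil(p * n) in double
// precision.

// [[Rcpp::export]]
NumericMatrix running_percentile_cpp(NumericMatrix x, int window, double p) {
  const int n_frames = x.nrow();
  const int n_chan = x.ncol();
  if (window < 1) stop("window must be at least 1 frame");
  if (p <= 0.0 || p > 0.5) stop("percentile must lie in (0, 0.5]");

  NumericMatrix out(n_frames, n_chan);

  for (int c = 0; c < n_chan; ++c) {
    std::multiset<double> low, high;  // low holds the k smallest
    for (int t = 0; t < n_frames; ++t) {
      const double xin = x(t, c);
      if (low.empty() || xin <= *low.rbegin()) low.insert(xin);
      else high.insert(xin);

      if (t >= window) {
        const double xout = x(t - window, c);
        std::multiset<double>::iterator it = low.find(xout);
        if (it != low.end()) low.erase(it);
        else high.erase(high.find(xout));
      }

      const int n = (int)(low.size() + high.size());
      const int k = (int)std::ceil(p * (double)n);
      while ((int)low.size() < k) {
        std::multiset<double>::iterator it = high.begin();
        low.insert(*it);
        high.erase(it);
      }
      while ((int)low.size() > k) {
        std::multiset<double>::iterator it = low.end();
        --it;
        high.insert(*it);
        low.erase(it);
      }
      out(t, c) = *low.rbegin();
    }
  }
  return out;
}
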