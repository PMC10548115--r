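#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Causal sliding median along the time axis (columns) for every depth row
// independently. Position t uses the most recent `window` samples
// x(r, t-window+1 .. t); start-up positions with fewer than `window` past
// samples use all available ones. Even-sized populations take the mean of
// the two middle order statistics.
// [[Rcpp::export]]
NumericMatrix causal_median_mat(const NumericMatrix& x, const int window) {
  if (window < 1) stop("window must be >= 1");
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(window);
  for (int r = 0; r < nr; ++r) {
    buf.clear();
    for (int t = 0; t < nc; ++t) {
      const double v = x(r, t);
      buf.insert(std::lower_bound(buf.begin(), buf.end(), v), v);
      if (t >= window) {
        const double old = x(r, t - window);
        buf.erase(std::lower_bound(buf.begin(), buf.end(), old));
      }
      const int m = (int)buf.size();
      out(r, t) = (m % 2 == 1) ? buf[m / 2]
                               : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
    }
  }
  return out;
}
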