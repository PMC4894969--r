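#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Running 2-D median filter with a rectangular window and replicate padding.
// For an even window of width w the window spans floor((w-1)/2) pixels before
// and w-1-floor((w-1)/2) after the centre pixel (e.g. w=10: 4 before, 5
// after), so even windows carry a half-pixel shift toward larger indices.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int wr, int wc) {
  const int nr = x.nrow(), nc = x.ncol();
  if (wr < 1 || wc < 1) stop("window dimensions must be >= 1");
  NumericMatrix out(nr, nc);
  const int br = (wr - 1) / 2, bc = (wc - 1) / 2; // pixels before the centre
  const int ar = wr - 1 - br, ac = wc - 1 - bc;   // pixels after
  std::vector<double> buf;
  buf.reserve((size_t)wr * wc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -bc; dj <= ac; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        for (int di = -br; di <= ar; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          buf.push_back(x(ii, jj));
        }
      }
      const size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double hi = buf[n / 2];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        out(i, j) = (lo + hi) / 2.0;
      } else {
        out(i, j) = hi;
      }
    }
  }
  return out;
}
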