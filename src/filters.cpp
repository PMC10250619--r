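#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// reflect index into [0, n): (c b a | a b c), matching scipy's "reflect" mode
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int m) {
  if (m < 1 || m % 2 == 0) stop("median filter size must be odd and >= 1");
  int nr = img.nrow(), nc = img.ncol(), h = m / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> win(m * m);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -h; di <= h; ++di) {
          int ii = reflect_idx(i + di, nr);
          win[k++] = img(ii, jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + k / 2, win.begin() + k);
      out(i, j) = win[k / 2];
    }
  }
  return out;
}

// Maximum over the strict L1 ball {p : |p - center|_1 < d}, clipped to bounds.
// [[Rcpp::export(name = ".l1_max_filter_cpp")]]
NumericMatrix l1_max_filter_cpp(NumericMatrix img, int d) {
  if (d < 1) stop("radius must be >= 1");
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double mx = img(i, j);
      for (int di = -(d - 1); di <= d - 1; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        int rem = d - 1 - std::abs(di);
        int j0 = std::max(0, j - rem), j1 = std::min(nc - 1, j + rem);
        for (int jj = j0; jj <= j1; ++jj) {
          double v = img(ii, jj);
          if (v > mx) mx = v;
        }
      }
      out(i, j) = mx;
    }
  }
  return out;
}
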