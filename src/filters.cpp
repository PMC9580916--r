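#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-column median of a numeric matrix. Used by the temporal median
// background filter, where each column is one pixel's trace inside a window.
// [[Rcpp::export]]
NumericVector cpp_col_medians(NumericMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = m(i, j);
    int h = nr / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    if (nr % 2 == 1) {
      out[j] = buf[h];
    } else {
      double hi = buf[h];
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      out[j] = 0.5 * (lo + hi);
    }
  }
  return out;
}

static inline int reflect_index(int i, int n) {
  // symmetric boundary: (... c b a | a b c ...)
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable Gaussian blur with symmetric (reflective) boundary handling.
// Kernel truncated at 4 sigma and renormalised.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur_reflect(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * img(reflect_index(i + d, nr), j);
      tmp(i, j) = acc;
    }
  // along columns (horizontal pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * tmp(i, reflect_index(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}
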