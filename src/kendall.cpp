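#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Kendall's tau-b in O(n log n) (Knight 1966): sort by (x, y), count
// inversions in y by merge sort, correct the denominator for ties.

namespace {

double tie_count(std::vector<double>& v) {
  std::sort(v.begin(), v.end());
  double t = 0.0;
  std::size_t i = 0;
  while (i < v.size()) {
    std::size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    double m = static_cast<double>(j - i);
    t += m * (m - 1.0) / 2.0;
    i = j;
  }
  return t;
}

double merge_count(std::vector<double>& y, std::vector<double>& buf,
                   std::size_t lo, std::size_t hi) {
  if (hi - lo < 2) return 0.0;
  std::size_t mid = lo + (hi - lo) / 2;
  double sw = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  std::size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {
      sw += static_cast<double>(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return sw;
}

}  // namespace

// [[Rcpp::export]]
double ktau_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  std::size_t n = x.size();
  if (n != static_cast<std::size_t>(y.size()))
    Rcpp::stop("x and y must have equal length");
  if (n < 2) return NA_REAL;

  std::vector<std::size_t> idx(n);
  for (std::size_t i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](std::size_t a, std::size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> ys(n);
  for (std::size_t i = 0; i < n; ++i) ys[i] = y[idx[i]];

  double n0 = static_cast<double>(n) * (n - 1.0) / 2.0;

  // joint ties and ties in x (pairs tied in x are not inversions because
  // they are pre-sorted by y within each x group)
  double n1 = 0.0, n3 = 0.0;
  {
    std::size_t i = 0;
    while (i < n) {
      std::size_t j = i;
      while (j < n && x[idx[j]] == x[idx[i]]) ++j;
      double m = static_cast<double>(j - i);
      n1 += m * (m - 1.0) / 2.0;
      std::size_t a = i;
      while (a < j) {
        std::size_t b = a;
        while (b < j && y[idx[b]] == y[idx[a]]) ++b;
        double mm = static_cast<double>(b - a);
        n3 += mm * (mm - 1.0) / 2.0;
        a = b;
      }
      i = j;
    }
  }
  std::vector<double> yt(ys);
  double n2 = tie_count(yt);

  std::vector<double> buf(n);
  double swaps = merge_count(ys, buf, 0, n);

  double num = n0 - n1 - n2 + n3 - 2.0 * swaps;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den <= 0.0) return NA_REAL;
  return num / den;
}
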