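#include <Rcpp.h>
using namespace Rcpp;

// Flat grayscale erosion (running minimum) with an odd window of `width`
// channels. Edges use the shrunken window (min over the in-range part), the
// usual convention for spectra so that edge channels are not padded with -Inf.
static void erode_into(const double* x, double* out, int n, int width) {
  int h = width / 2;
  for (int i = 0; i < n; ++i) {
    int lo = i - h; if (lo < 0) lo = 0;
    int hi = i + h; if (hi > n - 1) hi = n - 1;
    double m = x[lo];
    for (int j = lo + 1; j <= hi; ++j) if (x[j] < m) m = x[j];
    out[i] = m;
  }
}

static void dilate_into(const double* x, double* out, int n, int width) {
  int h = width / 2;
  for (int i = 0; i < n; ++i) {
    int lo = i - h; if (lo < 0) lo = 0;
    int hi = i + h; if (hi > n - 1) hi = n - 1;
    double m = x[lo];
    for (int j = lo + 1; j <= hi; ++j) if (x[j] > m) m = x[j];
    out[i] = m;
  }
}

// [[Rcpp::export(name = ".erode1d")]]
NumericVector erode1d(NumericVector x, int width) {
  int n = x.size();
  NumericVector out(n);
  erode_into(x.begin(), out.begin(), n, width);
  return out;
}

// [[Rcpp::export(name = ".dilate1d")]]
NumericVector dilate1d(NumericVector x, int width) {
  int n = x.size();
  NumericVector out(n);
  dilate_into(x.begin(), out.begin(), n, width);
  return out;
}

// Tophat baseline removal applied to every row of a spots x channels matrix:
// row - opening(row), where opening = dilate(erode(row)).
// [[Rcpp::export(name = ".tophat_rows")]]
NumericMatrix tophat_rows(NumericMatrix x, int width) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> row(nc), ero(nc), open_(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = x(i, j);
    erode_into(row.data(), ero.data(), nc, width);
    dilate_into(ero.data(), open_.data(), nc, width);
    for (int j = 0; j < nc; ++j) {
      double v = row[j] - open_[j];
      out(i, j) = v > 0 ? v : 0;
    }
  }
  return out;
}
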