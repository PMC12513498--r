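#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared-distance transform along a sampled line with physical spacing w
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas, O(n)).
// f holds squared distances; output d is min_j f[j] + w^2 (i-j)^2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  const int n = (int)f.size();
  const double w2 = w * w;
  int k = -1; // envelope holds finite parabolas only
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k; // k stays >= 0 because z[0] = -INF < s
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite source on this line
    d.assign(n, INF);
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int j = v[k];
    d[q] = f[j] + w2 * (double)(q - j) * (double)(q - j);
  }
}

//' Exact anisotropic 2-D squared Euclidean distance transform
//'
//' For every pixel of a logical matrix, the squared Euclidean distance (in
//' physical units) from its center to the nearest \code{TRUE} pixel center,
//' with independent row and column spacing. Pixels inside the foreground get
//' distance 0; if the matrix has no \code{TRUE} pixel every distance is
//' \code{Inf}.
//'
//' @param mask logical matrix (foreground = \code{TRUE}).
//' @param spacing_row physical distance between adjacent rows (mm).
//' @param spacing_col physical distance between adjacent columns (mm).
//' @return numeric matrix of squared distances in mm^2.
//' @keywords internal
// [[Rcpp::export(rng = false)]]
NumericMatrix edt2_sq(LogicalMatrix mask, double spacing_row, double spacing_col) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  std::vector<int> v(std::max(nr, nc));
  std::vector<double> z(std::max(nr, nc) + 1);

  // pass 1: along rows (within each column), spacing_row
  for (int j = 0; j < nc; ++j) {
    f.assign(nr, INF);
    bool any = false;
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) { f[i] = 0.0; any = true; }
    if (!any) {
      for (int i = 0; i < nr; ++i) out(i, j) = INF;
      continue;
    }
    d.assign(nr, INF);
    dt1d(f, d, spacing_row, v, z);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }

  // pass 2: along columns (within each row), spacing_col
  for (int i = 0; i < nr; ++i) {
    f.assign(nc, INF);
    bool any = false;
    for (int j = 0; j < nc; ++j) {
      f[j] = out(i, j);
      if (f[j] < INF) any = true;
    }
    if (!any) continue;
    d.assign(nc, INF);
    dt1d(f, d, spacing_col, v, z);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}
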