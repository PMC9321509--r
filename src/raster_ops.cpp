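#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Connected-component labelling of a logical mask, 4- or 8-connectivity.
// Labels are dense 1..P, assigned in row-major scan order (deterministic).

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;

  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || mask(r, c) == NA_LOGICAL || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push({r, c});
      while (!q.empty()) {
        auto [cr, cc] = q.front();
        q.pop();
        for (int m = 0; m < nn; ++m) {
          const int r2 = cr + dr[m], c2 = cc + dc[m];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) == NA_LOGICAL || !mask(r2, c2)) continue;
          if (lab(r2, c2) == 0) { lab(r2, c2) = next; q.push({r2, c2}); }
        }
      }
    }
  return lab;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance in metres from each cell centre to the nearest true cell.

// "infinite" parabola height: large but finite so intersection abscissae
// stay well-defined in columns that contain no feature cells
static const double DT_BIG = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask, double cellsize) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::vector<double>> g(nr, std::vector<double>(nc));
  // column pass
  std::vector<double> f(nr), d(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r)
      f[r] = (mask(r, c) != NA_LOGICAL && mask(r, c)) ? 0.0 : DT_BIG;
    dt1d(f, d);
    for (int r = 0; r < nr; ++r) g[r][c] = d[r];
  }
  // row pass
  NumericMatrix out(nr, nc);
  std::vector<double> f2(nc), d2(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f2[c] = g[r][c];
    dt1d(f2, d2);
    for (int c = 0; c < nc; ++c)
      out(r, c) = (d2[c] < DT_BIG) ? std::sqrt(d2[c]) * cellsize : NA_REAL;
  }
  return out;
}

// Focal range: max - min over a w x w window centred on each cell
// (w odd; edge windows truncated; NA cells excluded; all-NA window -> NA).

// [[Rcpp::export]]
NumericMatrix cpp_focal_range(NumericMatrix x, int w) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = w / 2;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double lo = R_PosInf, hi = R_NegInf;
      bool any = false;
      const int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
      const int c0 = std::max(0, c - h), c1 = std::min(nc - 1, c + h);
      for (int rr = r0; rr <= r1; ++rr)
        for (int cc = c0; cc <= c1; ++cc) {
          const double v = x(rr, cc);
          if (NumericMatrix::is_na(v)) continue;
          any = true;
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
      out(r, c) = any ? hi - lo : NA_REAL;
    }
  return out;
}
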