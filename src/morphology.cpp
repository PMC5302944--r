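// Low-level image primitives used by the FNTD read-out and nucleus/focus
// segmentation stages. Images are R numeric matrices (column-major); all
// neighbourhood operations replicate-pad at the border.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Grayscale erosion (minimum) or dilation (maximum) over an arbitrary
// structuring element given as integer offsets (dr, dc).
// [[Rcpp::export]]
NumericMatrix cpp_morph(const NumericMatrix& img, const IntegerVector& dr,
                        const IntegerVector& dc, bool dilate) {
  const int nr = img.nrow(), nc = img.ncol(), k = dr.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = dilate ? -std::numeric_limits<double>::infinity()
                           : std::numeric_limits<double>::infinity();
      for (int t = 0; t < k; ++t) {
        const int ii = clampi(i + dr[t], 0, nr - 1);
        const int jj = clampi(j + dc[t], 0, nc - 1);
        const double v = img(ii, jj);
        if (dilate ? (v > best) : (v < best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Separable 1D erosion/dilation along rows or columns with window
// half-width r (used to build large square openings cheaply).
// [[Rcpp::export]]
NumericMatrix cpp_morph_line(const NumericMatrix& img, int r, bool dilate,
                             bool along_rows) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = dilate ? -std::numeric_limits<double>::infinity()
                           : std::numeric_limits<double>::infinity();
      for (int t = -r; t <= r; ++t) {
        const int ii = along_rows ? i : clampi(i + t, 0, nr - 1);
        const int jj = along_rows ? clampi(j + t, 0, nc - 1) : j;
        const double v = img(ii, jj);
        if (dilate ? (v > best) : (v < best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Median filter over a square window of half-width r.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int r) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((2 * r + 1) * (2 * r + 1));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -r; dj <= r; ++dj)
        for (int di = -r; di <= r; ++di)
          buf.push_back(img(clampi(i + di, 0, nr - 1), clampi(j + dj, 0, nc - 1)));
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      double med = buf[buf.size() / 2];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + buf.size() / 2 - 1, buf.end());
        med = 0.5 * (med + buf[buf.size() / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Separable convolution with a 1D kernel applied along rows then columns
// (replicate padding). Used for Gaussian smoothing.
// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(const NumericMatrix& img, const NumericVector& kernel) {
  const int nr = img.nrow(), nc = img.ncol(), k = kernel.size();
  const int h = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int t = 0; t < k; ++t)
        acc += kernel[t] * img(i, clampi(j + t - h, 0, nc - 1));
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int t = 0; t < k; ++t)
        acc += kernel[t] * tmp(clampi(i + t - h, 0, nr - 1), j);
      out(i, j) = acc;
    }
  return out;
}

// Connected-component labelling of a logical mask (8-connectivity),
// breadth-first; labels are 1..n in scan order of first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance in pixels from every TRUE pixel to the nearest FALSE pixel.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix sq(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      sq(i, j) = mask(i, j) ? INF : 0.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = sq(i, j);
    edt_1d(std::vector<double>(f.begin(), f.begin() + nr), d);
    for (int i = 0; i < nr; ++i) sq(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = sq(i, j);
    edt_1d(std::vector<double>(f.begin(), f.begin() + nc), d);
    for (int j = 0; j < nc; ++j) sq(i, j) = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      sq(i, j) = std::sqrt(sq(i, j));
  return sq;
}

// Marker-based watershed by priority flooding: grow marker labels over the
// foreground mask in order of increasing elevation (pass -distance to grow
// ridge-first). FIFO order breaks elevation ties, keeping fronts balanced.
struct WsNode {
  double elev;
  long long order;
  int i, j, lab;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elev, const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      lab(i, j) = markers(i, j);
      if (markers(i, j) > 0) {
        WsNode n = {elev(i, j), order++, i, j, markers(i, j)};
        pq.push(n);
      }
    }
  while (!pq.empty()) {
    const WsNode n = pq.top();
    pq.pop();
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int ii = n.i + di, jj = n.j + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
        lab(ii, jj) = n.lab;
        WsNode m = {elev(ii, jj), order++, ii, jj, n.lab};
        pq.push(m);
      }
    }
  }
  return lab;
}
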