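#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// reflected index (mirror without repeating the edge pixel; falls back to
// clamping for pathologically small images)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Separable convolution: `kcol` runs along rows (vertical), `krow` along
// columns (horizontal). Both kernels must have odd length.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& m, const NumericVector& kcol,
                           const NumericVector& krow) {
  const int nr = m.nrow(), nc = m.ncol();
  const int hc = (kcol.size() - 1) / 2, hr = (krow.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = -hc; k <= hc; ++k)
        s += kcol[k + hc] * m(reflect(i + k, nr), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = -hr; k <= hr; ++k)
        s += krow[k + hr] * tmp(i, reflect(j + k, nc));
      out(i, j) = s;
    }
  return out;
}

// Median over a disc neighbourhood (dx^2 + dy^2 <= r^2), reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_median_disc(const NumericMatrix& m, const double radius) {
  const int nr = m.nrow(), nc = m.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> di, dj;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)(a * a + b * b) <= radius * radius + 1e-9) {
        di.push_back(a);
        dj.push_back(b);
      }
  const int k = (int)di.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      for (int q = 0; q < k; ++q)
        buf[q] = m(reflect(i + di[q], nr), reflect(j + dj[q], nc));
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + k / 2 - 1, buf.end());
        med = 0.5 * (med + buf[k / 2 - 1]);
      }
      out(i, j) = med;
    }
  return out;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
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
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
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

// Background estimate by grayscale opening with a paraboloid structuring
// element z(d) = d^2 / (2 * radius) (the "sliding paraboloid" model). The
// quadratic SE is additively separable, and each 1-D erosion
// min_d v[i+d] + a d^2 = a * DT(v / a) is a lower-envelope (weighted
// distance) transform, so the whole opening runs in O(n) per pixel line.
static void quad_erode_line(std::vector<double>& f, std::vector<double>& d,
                            double a) {
  for (size_t i = 0; i < f.size(); ++i) f[i] /= a;
  dt1d(f, d);
  for (size_t i = 0; i < d.size(); ++i) d[i] *= a;
}

// [[Rcpp::export]]
NumericMatrix cpp_paraboloid_background(const NumericMatrix& m,
                                        const double radius) {
  const int nr = m.nrow(), nc = m.ncol();
  const double a = 1.0 / (2.0 * radius);
  NumericMatrix work(nr, nc);
  std::vector<double> f, d;
  // erosion then dilation (dilation = -erosion of the negated image),
  // each separable into column and row passes
  for (int sign = 0; sign < 2; ++sign) {
    const NumericMatrix& src = (sign == 0) ? m : work;
    double s = (sign == 0) ? 1.0 : -1.0;
    NumericMatrix tmp(nr, nc);
    f.resize(nr); d.resize(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = s * src(i, j);
      quad_erode_line(f, d, a);
      for (int i = 0; i < nr; ++i) tmp(i, j) = d[i];
    }
    f.resize(nc); d.resize(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = tmp(i, j);
      quad_erode_line(f, d, a);
      for (int j = 0; j < nc; ++j) work(i, j) = s * d[j];
    }
  }
  return work;
}

// Iterated box blur (3 passes per axis) approximating a Gaussian of the
// given sigma; O(n) per pixel regardless of sigma. Borders use
// antisymmetric (linear-extrapolating) reflection, v(-i) = 2 v(0) - v(i),
// so linear intensity trends — the vignetting fields this blur estimates —
// pass through unchanged at the edges.
static inline double val_odd(const std::vector<double>& v, int i) {
  const int n = (int)v.size();
  if (i >= 0 && i < n) return v[i];
  if (i < 0) return 2.0 * v[0] - v[reflect(i, n)];
  return 2.0 * v[n - 1] - v[reflect(i, n)];
}

static void box_blur_line(const std::vector<double>& v, std::vector<double>& o,
                          int r) {
  const int n = (int)v.size();
  double w = 2.0 * r + 1.0;
  double s = 0.0;
  for (int k = -r; k <= r; ++k) s += val_odd(v, k);
  for (int i = 0; i < n; ++i) {
    o[i] = s / w;
    s += val_odd(v, i + r + 1) - val_odd(v, i - r);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_box_gauss(const NumericMatrix& m, const double sigma) {
  // box width for 3 iterations: var(box of radius r) = r(r+1)/3 per pass
  int r = (int)std::round(std::sqrt(sigma * sigma / 3.0 * 3.0 + 0.25) - 0.5);
  if (r < 1) r = 1;
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out = clone(m);
  std::vector<double> f, d;
  for (int pass = 0; pass < 3; ++pass) {
    f.resize(nr); d.resize(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = out(i, j);
      box_blur_line(f, d, r);
      for (int i = 0; i < nr; ++i) out(i, j) = d[i];
    }
    f.resize(nc); d.resize(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = out(i, j);
      box_blur_line(f, d, r);
      for (int j = 0; j < nc; ++j) out(i, j) = d[j];
    }
  }
  return out;
}

// Exact squared Euclidean distance from each foreground pixel to the nearest
// background pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  std::vector<double> f, d;
  f.resize(nr); d.resize(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  f.resize(nc); d.resize(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, d);
    for (int j = 0; j < nc; ++j) g(i, j) = std::min(d[j], INF);
  }
  return g;
}

// Connected-component labelling (conn = 4 or 8), BFS, labels 1..k.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, const int conn) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int di4[4] = {-1, 0, 0, 1};
  const int dj4[4] = {0, -1, 1, 0};
  const int* di = (conn == 8) ? di8 : di4;
  const int* dj = (conn == 8) ? dj8 : dj4;
  const int nn = (conn == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int t = 0; t < nn; ++t) {
          int ii = p.first + di[t], jj = p.second + dj[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}

struct WsNode {
  double elev;
  long order;
  int i, j;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;
  }
};

// Marker-controlled watershed by priority flooding of `elev` (ascending)
// restricted to `mask`. Pixels where distinct basins meet become 0
// (watershed lines); all other masked pixels inherit a marker label.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elev,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        WsNode nd = {elev(i, j), order++, i, j};
        pq.push(nd);
      }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    const int lp = lab(nd.i, nd.j);
    if (lp <= 0) continue;
    for (int t = 0; t < 8; ++t) {
      int ii = nd.i + di[t], jj = nd.j + dj[t];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
      // does this pixel touch a competing basin?
      bool boundary = false;
      for (int s = 0; s < 8 && !boundary; ++s) {
        int ai = ii + di[s], aj = jj + dj[s];
        if (ai < 0 || ai >= nr || aj < 0 || aj >= nc) continue;
        if (lab(ai, aj) > 0 && lab(ai, aj) != lp) boundary = true;
      }
      if (boundary) {
        lab(ii, jj) = -1;
      } else {
        lab(ii, jj) = lp;
        WsNode nx = {elev(ii, jj), order++, ii, jj};
        pq.push(nx);
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) < 0) lab(i, j) = 0;
  return lab;
}

// Zhang-Suen topology-preserving thinning to a 1-px-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) img[i + j * nr] = mask(i, j) ? 1 : 0;
  std::vector<unsigned char> mark(nr * nc, 0);
  bool changed = true;
  // neighbours P2..P9 clockwise starting north
  const int di[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::fill(mark.begin(), mark.end(), 0);
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!img[i + j * nr]) continue;
          int p[8];
          for (int t = 0; t < 8; ++t) {
            int ii = i + di[t], jj = j + dj[t];
            p[t] = (ii >= 0 && ii < nr && jj >= 0 && jj < nc)
                       ? img[ii + jj * nr]
                       : 0;
          }
          int B = 0;
          for (int t = 0; t < 8; ++t) B += p[t];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int t = 0; t < 8; ++t)
            if (p[t] == 0 && p[(t + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          mark[i + j * nr] = 1;
        }
      for (int q = 0; q < nr * nc; ++q)
        if (mark[q]) {
          img[q] = 0;
          changed = true;
        }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = img[i + j * nr] != 0;
  return out;
}
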