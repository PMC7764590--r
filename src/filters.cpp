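// Low-level raster primitives: separable Gaussian smoothing (reflect
// boundary, kernel truncated at 4 sigma), Sobel gradient magnitude,
// median over a disk neighbourhood, bilinear/nearest resampling and
// scanline polygon rasterization.  All matrices are R (row, col) layout.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// mirror index into [0, n): reflection without edge duplication beyond
// one sample, i.e. (d c b a | a b c d | d c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export(name = ".cpp_gauss_blur")]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& x, double sigma) {
  const int h = x.nrow(), w = x.ncol();
  std::vector<double> k = gauss_kernel(sigma);
  const int r = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // along rows (vertical)
  for (int c = 0; c < w; ++c)
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += k[d + r] * x(reflect_idx(i + d, h), c);
      tmp(i, c) = s;
    }
  // along cols (horizontal)
  for (int c = 0; c < w; ++c)
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += k[d + r] * tmp(i, reflect_idx(c + d, w));
      out(i, c) = s;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_sobel_mag")]]
NumericMatrix cpp_sobel_mag(const NumericMatrix& x) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix out(h, w);
  // correlation kernels; gx detects horizontal change (along columns)
  static const int kx[3][3] = {{-1, 0, 1}, {-2, 0, 2}, {-1, 0, 1}};
  static const int ky[3][3] = {{-1, -2, -1}, {0, 0, 0}, {1, 2, 1}};
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double gx = 0.0, gy = 0.0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          double v = x(reflect_idx(i + di, h), reflect_idx(j + dj, w));
          gx += kx[di + 1][dj + 1] * v;
          gy += ky[di + 1][dj + 1] * v;
        }
      out(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_median_disk")]]
NumericMatrix cpp_median_disk(const NumericMatrix& x, int radius) {
  const int h = x.nrow(), w = x.ncol();
  std::vector<std::pair<int, int> > off;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= radius * radius) off.push_back(std::make_pair(di, dj));
  NumericMatrix out(h, w);
  std::vector<double> buf(off.size());
  const size_t n = off.size();
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      for (size_t t = 0; t < n; ++t)
        buf[t] = x(reflect_idx(i + off[t].first, h), reflect_idx(j + off[t].second, w));
      size_t mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        m = 0.5 * (m + lo);
      }
      out(i, j) = m;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& x, int oh, int ow) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix out(oh, ow);
  const double sr = (double)h / oh, sc = (double)w / ow;
  for (int i = 0; i < oh; ++i) {
    double fi = (i + 0.5) * sr - 0.5;
    int i0 = (int)std::floor(fi);
    double wi = fi - i0;
    int i0c = std::min(std::max(i0, 0), h - 1);
    int i1c = std::min(std::max(i0 + 1, 0), h - 1);
    for (int j = 0; j < ow; ++j) {
      double fj = (j + 0.5) * sc - 0.5;
      int j0 = (int)std::floor(fj);
      double wj = fj - j0;
      int j0c = std::min(std::max(j0, 0), w - 1);
      int j1c = std::min(std::max(j0 + 1, 0), w - 1);
      out(i, j) = (1 - wi) * ((1 - wj) * x(i0c, j0c) + wj * x(i0c, j1c)) +
                  wi * ((1 - wj) * x(i1c, j0c) + wj * x(i1c, j1c));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_resize_nearest")]]
NumericMatrix cpp_resize_nearest(const NumericMatrix& x, int oh, int ow) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix out(oh, ow);
  const double sr = (double)h / oh, sc = (double)w / ow;
  for (int i = 0; i < oh; ++i) {
    int si = std::min((int)std::floor((i + 0.5) * sr), h - 1);
    for (int j = 0; j < ow; ++j) {
      int sj = std::min((int)std::floor((j + 0.5) * sc), w - 1);
      out(i, j) = x(si, sj);
    }
  }
  return out;
}

// Even-odd point-in-polygon fill.  Polygons are n x 2 (x, y) matrices in
// 0-based pixel coordinates; pixel (row i, col j) is tested at its centre
// (x = j + 0.5, y = i + 0.5).  Later polygons overwrite earlier ones.
// [[Rcpp::export(name = ".cpp_fill_polygons")]]
IntegerMatrix cpp_fill_polygons(int h, int w, const List& polys,
                                const IntegerVector& codes) {
  IntegerMatrix out(h, w);
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix v = polys[p];
    const int n = v.nrow();
    const int code = codes[p];
    double ymin = R_PosInf, ymax = R_NegInf, xmin = R_PosInf, xmax = R_NegInf;
    for (int t = 0; t < n; ++t) {
      ymin = std::min(ymin, v(t, 1)); ymax = std::max(ymax, v(t, 1));
      xmin = std::min(xmin, v(t, 0)); xmax = std::max(xmax, v(t, 0));
    }
    int i0 = std::max(0, (int)std::floor(ymin - 0.5));
    int i1 = std::min(h - 1, (int)std::ceil(ymax));
    int j0 = std::max(0, (int)std::floor(xmin - 0.5));
    int j1 = std::min(w - 1, (int)std::ceil(xmax));
    std::vector<double> xs;
    for (int i = i0; i <= i1; ++i) {
      double py = i + 0.5;
      xs.clear();
      for (int t = 0; t < n; ++t) {
        double y1 = v(t, 1), y2 = v((t + 1) % n, 1);
        if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
          double x1 = v(t, 0), x2 = v((t + 1) % n, 0);
          xs.push_back(x1 + (py - y1) / (y2 - y1) * (x2 - x1));
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t t = 0; t + 1 < xs.size(); t += 2) {
        int ja = std::max(j0, (int)std::ceil(xs[t] - 0.5));
        int jb = std::min(j1, (int)std::floor(xs[t + 1] - 0.5 - 1e-12));
        for (int j = ja; j <= jb; ++j)
          if (j + 0.5 > xs[t] && j + 0.5 < xs[t + 1]) out(i, j) = code;
      }
    }
  }
  return out;
}
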