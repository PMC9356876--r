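#include <Rcpp.h>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Feature maps are R arrays dim c(H, W, C), column-major.
// im2col rows enumerate output pixels in (ho, wo) column-major order;
// columns enumerate (ki, kj, c) with ki fastest. The conv weight matrix in R
// must use the same (ki, kj, c) x out_channel layout.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = po + (size_t)(ki + k * kj + k * k * c) * Ho * Wo;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc + (size_t)H * wi;
          double* dst = col + (size_t)Ho * wo;
          int ho0 = 0, ho1 = Ho;                  // hi = ho*stride + ki - pad
          while (ho0 < Ho && ho0 * stride + ki - pad < 0) ++ho0;
          while (ho1 > ho0 && (ho1 - 1) * stride + ki - pad >= H) --ho1;
          if (stride == 1) {
            if (ho1 > ho0)
              std::memcpy(dst + ho0, src + ho0 + ki - pad,
                          (size_t)(ho1 - ho0) * sizeof(double));
          } else {
            for (int ho = ho0; ho < ho1; ++ho)
              dst[ho] = src[ho * stride + ki - pad];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx(H * W * C);
  const double* pc = cols.begin();
  double* pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = pdx + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = pc + (size_t)(ki + k * kj + k * k * c) * Ho * Wo;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = xc + (size_t)H * wi;
          const double* src = col + (size_t)Ho * wo;
          int ho0 = 0, ho1 = Ho;
          while (ho0 < Ho && ho0 * stride + ki - pad < 0) ++ho0;
          while (ho1 > ho0 && (ho1 - 1) * stride + ki - pad >= H) --ho1;
          for (int ho = ho0; ho < ho1; ++ho)
            dst[ho * stride + ki - pad] += src[ho];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

static inline double bilinear_at(const NumericMatrix& img, double x, double y) {
  // x = column, y = row, 1-based pixel centers
  int H = img.nrow(), W = img.ncol();
  double xf = x - 1.0, yf = y - 1.0; // 0-based
  if (xf < 0 || yf < 0 || xf > W - 1 || yf > H - 1) return NA_REAL;
  int x0 = (int)std::floor(xf), y0 = (int)std::floor(yf);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = xf - x0, fy = yf - y0;
  return img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy) +
         img(y1, x0) * (1 - fx) * fy + img(y1, x1) * fx * fy;
}

// Inverse-mapped resampling: out(r, c) = img at (x, y) = Hinv %*% (c, r, 1).
// Coordinates are 1-based pixel centers, x = column, y = row.
// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix img, NumericMatrix Hinv,
                       int outH, int outW, bool bilinear, double fill) {
  NumericMatrix out(outH, outW);
  int H = img.nrow(), W = img.ncol();
  for (int c = 0; c < outW; ++c) {
    for (int r = 0; r < outH; ++r) {
      double X = c + 1.0, Y = r + 1.0;
      double d = Hinv(2, 0) * X + Hinv(2, 1) * Y + Hinv(2, 2);
      if (std::fabs(d) < 1e-12) { out(r, c) = fill; continue; }
      double x = (Hinv(0, 0) * X + Hinv(0, 1) * Y + Hinv(0, 2)) / d;
      double y = (Hinv(1, 0) * X + Hinv(1, 1) * Y + Hinv(1, 2)) / d;
      if (bilinear) {
        double v = bilinear_at(img, x, y);
        out(r, c) = ISNAN(v) ? fill : v;
      } else {
        int ri = (int)std::lround(y) - 1, ci = (int)std::lround(x) - 1;
        out(r, c) = (ri >= 0 && ri < H && ci >= 0 && ci < W) ? img(ri, ci) : fill;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix img, NumericVector xs,
                                  NumericVector ys) {
  int n = xs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double v = bilinear_at(img, xs[i], ys[i]);
    out[i] = ISNAN(v) ? 0.0 : v;
  }
  return out;
}

// Zhang-Suen thinning of a binary mask (values 0/1).
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m = clone(mask);
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      del.clear();
      for (int c = 1; c < W - 1; ++c) {
        for (int r = 1; r < H - 1; ++r) {
          if (m(r, c) != 1) continue;
          int p2 = m(r - 1, c),     p3 = m(r - 1, c + 1), p4 = m(r, c + 1),
              p5 = m(r + 1, c + 1), p6 = m(r + 1, c),     p7 = m(r + 1, c - 1),
              p8 = m(r, c - 1),     p9 = m(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (phase == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i) m(del[i].first, del[i].second) = 0;
    }
  }
  return m;
}

// Rasterize thick line segments: pixel on iff distance to any segment
// (x0,y0)-(x1,y1) is <= its half-width. Coordinates 1-based, x = col, y = row.
// [[Rcpp::export]]
IntegerMatrix cpp_draw_segments(int H, int W, NumericVector x0, NumericVector y0,
                                NumericVector x1, NumericVector y1,
                                NumericVector halfw) {
  IntegerMatrix out(H, W);
  int n = x0.size();
  for (int i = 0; i < n; ++i) {
    double ax = x0[i], ay = y0[i], bx = x1[i], by = y1[i], hw = halfw[i];
    double dx = bx - ax, dy = by - ay;
    double len2 = dx * dx + dy * dy;
    int cmin = std::max(0, (int)std::floor(std::min(ax, bx) - hw) - 1);
    int cmax = std::min(W - 1, (int)std::ceil(std::max(ax, bx) + hw));
    int rmin = std::max(0, (int)std::floor(std::min(ay, by) - hw) - 1);
    int rmax = std::min(H - 1, (int)std::ceil(std::max(ay, by) + hw));
    for (int c = cmin; c <= cmax; ++c) {
      for (int r = rmin; r <= rmax; ++r) {
        double px = c + 1.0, py = r + 1.0;
        double t = len2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / len2 : 0.0;
        t = std::max(0.0, std::min(1.0, t));
        double qx = ax + t * dx, qy = ay + t * dy;
        double d2 = (px - qx) * (px - qx) + (py - qy) * (py - qy);
        if (d2 <= hw * hw) out(r, c) = 1;
      }
    }
  }
  return out;
}

// Separable Gaussian blur with reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + rad];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double v = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr;
        if (rr >= H) rr = 2 * H - 2 - rr;
        v += kern[i + rad] * img(rr, c);
      }
      tmp(r, c) = v;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double v = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc;
        if (cc >= W) cc = 2 * W - 2 - cc;
        v += kern[i + rad] * tmp(r, cc);
      }
      out(r, c) = v;
    }
  return out;
}

// Greedy non-maximum suppression; boxes given as centers + sizes.
// Returns 1-based indices of kept boxes, in descending score order.
// [[Rcpp::export]]
IntegerVector cpp_nms(NumericVector cx, NumericVector cy, NumericVector w,
                      NumericVector h, NumericVector score, double iou_thresh) {
  int n = cx.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return score[a] > score[b]; });
  std::vector<bool> removed(n, false);
  std::vector<int> keep;
  for (int ii = 0; ii < n; ++ii) {
    int i = idx[ii];
    if (removed[i]) continue;
    keep.push_back(i + 1);
    double ax0 = cx[i] - w[i] / 2, ax1 = cx[i] + w[i] / 2;
    double ay0 = cy[i] - h[i] / 2, ay1 = cy[i] + h[i] / 2;
    double areaA = w[i] * h[i];
    for (int jj = ii + 1; jj < n; ++jj) {
      int j = idx[jj];
      if (removed[j]) continue;
      double bx0 = cx[j] - w[j] / 2, bx1 = cx[j] + w[j] / 2;
      double by0 = cy[j] - h[j] / 2, by1 = cy[j] + h[j] / 2;
      double iw = std::min(ax1, bx1) - std::max(ax0, bx0);
      double ih = std::min(ay1, by1) - std::max(ay0, by0);
      if (iw <= 0 || ih <= 0) continue;
      double inter = iw * ih;
      double uni = areaA + w[j] * h[j] - inter;
      if (inter / uni > iou_thresh) removed[j] = true;
    }
  }
  return wrap(keep);
}

// y = x * a[col] + b[col], column-recycled (batch-norm scale/shift)
// [[Rcpp::export]]
NumericMatrix cpp_scale_shift(NumericMatrix x, NumericVector a,
                              NumericVector b) {
  int N = x.nrow(), C = x.ncol();
  NumericMatrix out(N, C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    double ac = a[c], bc = b[c];
    const double* s = px + (size_t)N * c;
    double* d = po + (size_t)N * c;
    for (int i = 0; i < N; ++i) d[i] = s[i] * ac + bc;
  }
  return out;
}
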