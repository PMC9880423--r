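// Low-level raster operations: fused affine warp with bicubic sampling,
// 8-connected component labelling, and 8-bit HSV / Lab colour conversions.
// Images are R arrays dim c(H, W) or c(H, W, C), values in [0, 1].

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Keys cubic convolution kernel, a = -0.75 (the OpenCV choice).
static inline double cubic_w(double x, double a = -0.75) {
  x = std::fabs(x);
  if (x < 1.0) return ((a + 2.0) * x - (a + 3.0)) * x * x + 1.0;
  if (x < 2.0) return a * (((x - 5.0) * x + 8.0) * x - 4.0);
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Affine warp with a fused crop: dst(yo, xo) samples the source at
// (cx0 + (xo - tx)/s, cy0 + (yo - ty)/s), where (cx0, cy0, cw, ch) is
// the crop rectangle in source coordinates.  Pixels mapping outside
// the crop are set to `fill`; bicubic taps are clamped to the crop.
// method: 0 = bicubic, 1 = nearest neighbour.
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector img, int out_h, int out_w,
                              double s, double tx, double ty,
                              double cx0, double cy0, double cw, double ch,
                              double fill, int method) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const int C = d.size() == 3 ? d[2] : 1;
  NumericVector out(static_cast<R_xlen_t>(out_h) * out_w * C);
  const double* src = img.begin();
  double* dst = out.begin();
  const size_t planeS = static_cast<size_t>(H) * W;
  const size_t planeD = static_cast<size_t>(out_h) * out_w;
  const int xlo = (int)cx0, ylo = (int)cy0;
  const int xhi = (int)(cx0 + cw) - 1, yhi = (int)(cy0 + ch) - 1;

  for (int xo = 0; xo < out_w; ++xo) {
    const double xs = cx0 + (xo - tx) / s;
    for (int yo = 0; yo < out_h; ++yo) {
      const double ys = cy0 + (yo - ty) / s;
      const size_t di = static_cast<size_t>(yo) + static_cast<size_t>(xo) * out_h;
      const bool inside = xs >= cx0 - 0.5 && xs < cx0 + cw - 0.5 &&
                          ys >= cy0 - 0.5 && ys < cy0 + ch - 0.5;
      if (!inside) {
        for (int c = 0; c < C; ++c) dst[di + c * planeD] = fill;
        continue;
      }
      if (method == 1) {
        const int xi = clampi((int)std::lround(xs), xlo, xhi);
        const int yi = clampi((int)std::lround(ys), ylo, yhi);
        const size_t si = static_cast<size_t>(yi) + static_cast<size_t>(xi) * H;
        for (int c = 0; c < C; ++c) dst[di + c * planeD] = src[si + c * planeS];
        continue;
      }
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double wx[4], wy[4];
      for (int k = 0; k < 4; ++k) {
        wx[k] = cubic_w(xs - (x0 - 1 + k));
        wy[k] = cubic_w(ys - (y0 - 1 + k));
      }
      for (int c = 0; c < C; ++c) {
        double acc = 0.0;
        for (int j = 0; j < 4; ++j) {
          const int xc = clampi(x0 - 1 + j, xlo, xhi);
          const double* col = src + c * planeS + static_cast<size_t>(xc) * H;
          double rowacc = 0.0;
          for (int i = 0; i < 4; ++i)
            rowacc += wy[i] * col[clampi(y0 - 1 + i, ylo, yhi)];
          acc += wx[j] * rowacc;
        }
        dst[di + c * planeD] = acc < 0.0 ? 0.0 : (acc > 1.0 ? 1.0 : acc);
      }
    }
  }
  if (C == 1)
    out.attr("dim") = IntegerVector::create(out_h, out_w);
  else
    out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  return out;
}

// Nearest-neighbour integer zoom by pixel replication.
// [[Rcpp::export]]
NumericVector cpp_zoom_nearest(NumericVector img, int k) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const int C = d.size() == 3 ? d[2] : 1;
  const int oh = H * k, ow = W * k;
  NumericVector out(static_cast<R_xlen_t>(oh) * ow * C);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* sp = src + static_cast<size_t>(c) * H * W;
    double* dp = dst + static_cast<size_t>(c) * oh * ow;
    for (int x = 0; x < ow; ++x) {
      const double* scol = sp + static_cast<size_t>(x / k) * H;
      double* dcol = dp + static_cast<size_t>(x) * oh;
      for (int y = 0; y < oh; ++y) dcol[y] = scol[y / k];
    }
  }
  if (C == 1)
    out.attr("dim") = IntegerVector::create(oh, ow);
  else
    out.attr("dim") = IntegerVector::create(oh, ow, C);
  return out;
}

// 8-connected component labelling of a binary matrix; background = 0,
// components numbered 1..n in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(y + x * H);
      lab(y, x) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int py = p % H, px = p / H;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy) {
            const int ny = py + dy, nx = px + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
              lab(ny, nx) = next;
              stack.push_back(ny + nx * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// 8-bit HSV channels (OpenCV convention: H in 0..180 = degrees/2,
// S and V in 0..255) from an RGB array in [0,1].
// [[Rcpp::export]]
List cpp_rgb2hsv8(NumericVector img) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const size_t n = static_cast<size_t>(H) * W;
  const double* r = img.begin();
  const double* g = r + n;
  const double* b = g + n;
  IntegerMatrix hm(H, W), sm(H, W), vm(H, W);
  for (size_t i = 0; i < n; ++i) {
    const double mx = std::max(r[i], std::max(g[i], b[i]));
    const double mn = std::min(r[i], std::min(g[i], b[i]));
    const double delta = mx - mn;
    double h = 0.0;
    if (delta > 0) {
      if (mx == r[i])      h = 60.0 * ((g[i] - b[i]) / delta);  // in (-60, 60)
      else if (mx == g[i]) h = 60.0 * ((b[i] - r[i]) / delta + 2.0);
      else                 h = 60.0 * ((r[i] - g[i]) / delta + 4.0);
      if (h < 0) h += 360.0;
    }
    const double s = mx > 0 ? delta / mx : 0.0;
    hm[i] = (int)std::lround(h / 2.0);
    sm[i] = (int)std::lround(255.0 * s);
    vm[i] = (int)std::lround(255.0 * mx);
  }
  return List::create(_["h"] = hm, _["s"] = sm, _["v"] = vm);
}

static inline double srgb_lin(double c) {
  return c <= 0.04045 ? c / 12.92 : std::pow((c + 0.055) / 1.055, 2.4);
}
static inline double lab_f(double t) {
  const double d = 6.0 / 29.0;
  return t > d * d * d ? std::cbrt(t) : t / (3.0 * d * d) + 4.0 / 29.0;
}

// 8-bit CIE Lab channels (OpenCV convention: L scaled to 0..255,
// a and b offset by 128) from an sRGB array in [0,1], D65 white.
// [[Rcpp::export]]
List cpp_rgb2lab8(NumericVector img) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const size_t n = static_cast<size_t>(H) * W;
  const double* r = img.begin();
  const double* g = r + n;
  const double* b = g + n;
  IntegerMatrix lm(H, W), am(H, W), bm(H, W);
  for (size_t i = 0; i < n; ++i) {
    const double rl = srgb_lin(r[i]), gl = srgb_lin(g[i]), bl = srgb_lin(b[i]);
    const double X = 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl;
    const double Y = 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl;
    const double Z = 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl;
    const double fx = lab_f(X / 0.95047), fy = lab_f(Y), fz = lab_f(Z / 1.08883);
    const double L = 116.0 * fy - 16.0;
    const double a = 500.0 * (fx - fy);
    const double bb = 200.0 * (fy - fz);
    lm[i] = clampi((int)std::lround(L * 255.0 / 100.0), 0, 255);
    am[i] = clampi((int)std::lround(a + 128.0), 0, 255);
    bm[i] = clampi((int)std::lround(bb + 128.0), 0, 255);
  }
  return List::create(_["l"] = lm, _["a"] = am, _["b"] = bm);
}

// Block-mean pooling by integer factor k (used to shrink the 224 px
// canvas to the tiny backbone's working resolution).
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector img, int k) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1];
  const int C = d.size() == 3 ? d[2] : 1;
  const int oh = H / k, ow = W / k;
  NumericVector out(static_cast<R_xlen_t>(oh) * ow * C);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* sp = src + static_cast<size_t>(c) * H * W;
    double* dp = dst + static_cast<size_t>(c) * oh * ow;
    for (int xo = 0; xo < ow; ++xo) {
      for (int yo = 0; yo < oh; ++yo) {
        double acc = 0.0;
        for (int dx2 = 0; dx2 < k; ++dx2)
          for (int dy2 = 0; dy2 < k; ++dy2)
            acc += sp[(yo * k + dy2) + static_cast<size_t>(xo * k + dx2) * H];
        dp[yo + static_cast<size_t>(xo) * oh] = acc / (k * k);
      }
    }
  }
  if (C == 1)
    out.attr("dim") = IntegerVector::create(oh, ow);
  else
    out.attr("dim") = IntegerVector::create(oh, ow, C);
  return out;
}
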