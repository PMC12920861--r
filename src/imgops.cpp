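// Image helpers shared by preprocessing, augmentation and rasterization.
// Coordinates are 0-based pixel centers, x rightward (columns), y downward
// (rows); R images are [H, W, C] arrays.
#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Bilinear resampling to th x tw using half-pixel-center mapping.
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericVector resize_bilinear(NumericVector img, int th, int tw) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  NumericVector out((size_t)th * tw * C);
  out.attr("dim") = IntegerVector::create(th, tw, C);
  double sy = (double)H / th, sx = (double)W / tw;
  for (int c = 0; c < C; c++) {
    const double* src = img.begin() + (size_t)H * W * c;
    double* dst = out.begin() + (size_t)th * tw * c;
    for (int x = 0; x < tw; x++) {
      double fx = (x + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double ax = fx - x0;
      int x0c = x0 < 0 ? 0 : (x0 >= W ? W - 1 : x0);
      int x1c = x0 + 1 < 0 ? 0 : (x0 + 1 >= W ? W - 1 : x0 + 1);
      for (int y = 0; y < th; y++) {
        double fy = (y + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(fy);
        double ay = fy - y0;
        int y0c = y0 < 0 ? 0 : (y0 >= H ? H - 1 : y0);
        int y1c = y0 + 1 < 0 ? 0 : (y0 + 1 >= H ? H - 1 : y0 + 1);
        double v = (1 - ay) * ((1 - ax) * src[y0c + (size_t)H * x0c] +
                               ax * src[y0c + (size_t)H * x1c]) +
                   ay * ((1 - ax) * src[y1c + (size_t)H * x0c] +
                         ax * src[y1c + (size_t)H * x1c]);
        dst[y + (size_t)th * x] = v;
      }
    }
  }
  return out;
}

// Inverse-map affine warp: output pixel (x,y) samples input at
// (a11*x + a12*y + a13, a21*x + a22*y + a23), bilinear, constant fill.
// [[Rcpp::export(name = ".affine_warp")]]
NumericVector affine_warp(NumericVector img, NumericVector m, double fill) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  double a11 = m[0], a12 = m[1], a13 = m[2], a21 = m[3], a22 = m[4], a23 = m[5];
  for (int c = 0; c < C; c++) {
    const double* src = img.begin() + (size_t)H * W * c;
    double* dst = out.begin() + (size_t)H * W * c;
    for (int x = 0; x < W; x++) {
      for (int y = 0; y < H; y++) {
        double fx = a11 * x + a12 * y + a13;
        double fy = a21 * x + a22 * y + a23;
        double v = fill;
        if (fx >= -1 && fx <= W && fy >= -1 && fy <= H) {
          int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
          double ax = fx - x0, ay = fy - y0;
          double v00 = fill, v01 = fill, v10 = fill, v11 = fill;
          if (x0 >= 0 && x0 < W) {
            if (y0 >= 0 && y0 < H) v00 = src[y0 + (size_t)H * x0];
            if (y0 + 1 >= 0 && y0 + 1 < H) v10 = src[y0 + 1 + (size_t)H * x0];
          }
          if (x0 + 1 >= 0 && x0 + 1 < W) {
            if (y0 >= 0 && y0 < H) v01 = src[y0 + (size_t)H * (x0 + 1)];
            if (y0 + 1 >= 0 && y0 + 1 < H) v11 = src[y0 + 1 + (size_t)H * (x0 + 1)];
          }
          v = (1 - ay) * ((1 - ax) * v00 + ax * v01) + ay * ((1 - ax) * v10 + ax * v11);
        }
        dst[y + (size_t)H * x] = v;
      }
    }
  }
  return out;
}

// Rasterize a filled triangle: pixel centers inside or on the boundary get 1.
// Vertices (xs, ys) in 0-based pixel-center coordinates.
// [[Rcpp::export(name = ".raster_triangle")]]
IntegerMatrix raster_triangle(NumericVector xs, NumericVector ys, int height,
                              int width) {
  IntegerMatrix out(height, width);
  double x1 = xs[0], y1 = ys[0], x2 = xs[1], y2 = ys[1], x3 = xs[2], y3 = ys[2];
  double area2 = (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1);
  if (area2 == 0) stop("degenerate (collinear) triangle cannot be rasterized");
  double tol = 1e-9 * (std::fabs(area2) + 1.0);
  int xmin = std::max(0, (int)std::floor(std::min({x1, x2, x3})));
  int xmax = std::min(width - 1, (int)std::ceil(std::max({x1, x2, x3})));
  int ymin = std::max(0, (int)std::floor(std::min({y1, y2, y3})));
  int ymax = std::min(height - 1, (int)std::ceil(std::max({y1, y2, y3})));
  double s = area2 > 0 ? 1.0 : -1.0;
  for (int x = xmin; x <= xmax; x++) {
    for (int y = ymin; y <= ymax; y++) {
      double e1 = s * ((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1));
      double e2 = s * ((x3 - x2) * (y - y2) - (y3 - y2) * (x - x2));
      double e3 = s * ((x1 - x3) * (y - y3) - (y1 - y3) * (x - x3));
      if (e1 >= -tol && e2 >= -tol && e3 >= -tol) out(y, x) = 1;
    }
  }
  return out;
}

// Euclidean distance from every pixel center to a segment; used by the
// synthetic renderer for fold-band drawing.
// [[Rcpp::export(name = ".dist_to_segment")]]
NumericMatrix dist_to_segment(int height, int width, double x1, double y1,
                              double x2, double y2) {
  NumericMatrix out(height, width);
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  for (int x = 0; x < width; x++) {
    for (int y = 0; y < height; y++) {
      double t = L2 > 0 ? ((x - x1) * dx + (y - y1) * dy) / L2 : 0.0;
      t = t < 0 ? 0 : (t > 1 ? 1 : t);
      double px = x1 + t * dx, py = y1 + t * dy;
      out(y, x) = std::sqrt((x - px) * (x - px) + (y - py) * (y - py));
    }
  }
  return out;
}
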