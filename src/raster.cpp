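// Deterministic scanline rasterizer for triangle-index / barycentric buffers.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// px: n x 2 projected pixel coordinates (0-based, origin at top-left pixel
//     center, x right / y down); z: per-vertex view depth (z_CCS for the
//     perspective path, z_VCS for the orthographic path); tri: m x 3 0-based
//     vertex indices; keep: per-triangle mask (front-facing, in front of the
//     camera). A pixel belongs to a triangle iff its center lies inside or on
//     the boundary of the projection; the nearer triangle wins, depth ties go
//     to the lower triangle id. Barycentric weights are perspective-correct
//     when `perspective`, affine otherwise.
// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix px, NumericVector z, IntegerMatrix tri,
                   LogicalVector keep, int W, int H, bool perspective) {
  int m = tri.nrow();
  IntegerMatrix index(H, W);
  NumericMatrix depth(H, W);
  NumericVector bary((R_xlen_t)H * W * 3, NA_REAL);
  std::fill(depth.begin(), depth.end(), R_PosInf);
  double* db = REAL(bary);
  R_xlen_t plane = (R_xlen_t)H * W;

  for (int t = 0; t < m; ++t) {
    if (!keep[t]) continue;
    int a = tri(t, 0), b = tri(t, 1), c = tri(t, 2);
    double x0 = px(a, 0), y0 = px(a, 1);
    double x1 = px(b, 0), y1 = px(b, 1);
    double x2 = px(c, 0), y2 = px(c, 1);
    if (!R_finite(x0) || !R_finite(y0) || !R_finite(x1) || !R_finite(y1) ||
        !R_finite(x2) || !R_finite(y2))
      continue;
    double area2 = (x1 - x0) * (y2 - y0) - (y1 - y0) * (x2 - x0);
    if (std::fabs(area2) < 1e-14) continue;
    double sgn = area2 > 0 ? 1.0 : -1.0;
    double inv = 1.0 / area2;
    int xs = std::max(0, (int)std::ceil(std::min({x0, x1, x2})));
    int xe = std::min(W - 1, (int)std::floor(std::max({x0, x1, x2})));
    int ys = std::max(0, (int)std::ceil(std::min({y0, y1, y2})));
    int ye = std::min(H - 1, (int)std::floor(std::max({y0, y1, y2})));
    if (xs > xe || ys > ye) continue;
    double za = z[a], zb = z[b], zc = z[c];
    for (int yi = ys; yi <= ye; ++yi) {
      double y = (double)yi;
      for (int xi = xs; xi <= xe; ++xi) {
        double x = (double)xi;
        double w0 = ((x1 - x) * (y2 - y) - (y1 - y) * (x2 - x)) * sgn;
        double w1 = ((x2 - x) * (y0 - y) - (y2 - y) * (x0 - x)) * sgn;
        double w2 = ((x0 - x) * (y1 - y) - (y0 - y) * (x1 - x)) * sgn;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double b0 = w0 * inv * sgn, b1 = w1 * inv * sgn, b2 = w2 * inv * sgn;
        double zp, g0, g1, g2;
        if (perspective) {
          double q0 = b0 / za, q1 = b1 / zb, q2 = b2 / zc;
          double s = q0 + q1 + q2;
          zp = 1.0 / s;
          g0 = q0 * zp; g1 = q1 * zp; g2 = q2 * zp;
        } else {
          zp = b0 * za + b1 * zb + b2 * zc;
          g0 = b0; g1 = b1; g2 = b2;
        }
        if (zp < depth(yi, xi)) {
          depth(yi, xi) = zp;
          index(yi, xi) = t + 1;
          R_xlen_t off = (R_xlen_t)yi + (R_xlen_t)H * xi;
          db[off] = g0;
          db[off + plane] = g1;
          db[off + 2 * plane] = g2;
        }
      }
    }
  }
  bary.attr("dim") = IntegerVector::create(H, W, 3);
  return List::create(_["index"] = index, _["bary"] = bary,
                      _["depth"] = depth);
}
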