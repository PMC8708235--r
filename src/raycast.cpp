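// Ray casting against a triangle mesh (used by the virtual depth scanners
// and as a geometric utility; the renderer itself is raster-based).
// Moller-Trumbore intersection with a uniform-grid DDA traversal so whole-
// body meshes can be scanned at depth-camera resolutions quickly.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {
struct TriPre {
  double v0[3], e1[3], e2[3];
};

inline bool intersect(const TriPre& T, const double* o, const double* d,
                      double& t, double& u, double& v) {
  double px = d[1] * T.e2[2] - d[2] * T.e2[1];
  double py = d[2] * T.e2[0] - d[0] * T.e2[2];
  double pz = d[0] * T.e2[1] - d[1] * T.e2[0];
  double det = T.e1[0] * px + T.e1[1] * py + T.e1[2] * pz;
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  double tx = o[0] - T.v0[0], ty = o[1] - T.v0[1], tz = o[2] - T.v0[2];
  u = (tx * px + ty * py + tz * pz) * inv;
  if (u < -1e-12 || u > 1 + 1e-12) return false;
  double qx = ty * T.e1[2] - tz * T.e1[1];
  double qy = tz * T.e1[0] - tx * T.e1[2];
  double qz = tx * T.e1[1] - ty * T.e1[0];
  v = (d[0] * qx + d[1] * qy + d[2] * qz) * inv;
  if (v < -1e-12 || u + v > 1 + 1e-12) return false;
  t = (T.e2[0] * qx + T.e2[1] * qy + T.e2[2] * qz) * inv;
  return true;
}
}  // namespace

// Returns, per ray, the nearest intersection t >= tmin along dir (Inf on
// miss), the 1-based triangle id (0 on miss) and the barycentric weights
// of the hit w.r.t. the triangle's (A,B,C).
// [[Rcpp::export]]
List cpp_raycast(NumericMatrix V, IntegerMatrix F, NumericMatrix orig,
                 NumericMatrix dir, double tmin = 1e-9) {
  int m = F.nrow(), nr = orig.nrow();
  std::vector<TriPre> tris(m);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int t = 0; t < m; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      tris[t].v0[d] = V(a, d);
      tris[t].e1[d] = V(b, d) - V(a, d);
      tris[t].e2[d] = V(c, d) - V(a, d);
      for (int vi : {a, b, c}) {
        lo[d] = std::min(lo[d], V(vi, d));
        hi[d] = std::max(hi[d], V(vi, d));
      }
    }
  }
  // uniform grid sized to ~2 triangles per occupied cell
  int ng = std::max(4, (int)std::cbrt((double)m / 2.0));
  ng = std::min(ng, 96);
  double cell[3], eps = 1e-9;
  for (int d = 0; d < 3; ++d) {
    lo[d] -= eps + 1e-6;
    hi[d] += eps + 1e-6;
    cell[d] = (hi[d] - lo[d]) / ng;
    if (cell[d] <= 0) cell[d] = 1e-6;
  }
  auto cidx = [&](int ix, int iy, int iz) {
    return (size_t)ix + (size_t)ng * (iy + (size_t)ng * iz);
  };
  std::vector<std::vector<int>> bins((size_t)ng * ng * ng);
  for (int t = 0; t < m; ++t) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int d = 0; d < 3; ++d) {
      double a = tris[t].v0[d];
      double b = a + tris[t].e1[d];
      double c = a + tris[t].e2[d];
      tlo[d] = std::min({a, b, c});
      thi[d] = std::max({a, b, c});
    }
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      i0[d] = std::max(0, (int)((tlo[d] - lo[d]) / cell[d]));
      i1[d] = std::min(ng - 1, (int)((thi[d] - lo[d]) / cell[d]));
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          bins[cidx(ix, iy, iz)].push_back(t);
  }

  NumericVector tout(nr, R_PosInf);
  IntegerVector hit(nr);
  NumericMatrix bw(nr, 3);
  for (int r = 0; r < nr; ++r) {
    double o[3] = {orig(r, 0), orig(r, 1), orig(r, 2)};
    double d[3] = {dir(r, 0), dir(r, 1), dir(r, 2)};
    // clip ray to grid box
    double t0 = tmin, t1 = R_PosInf;
    bool miss = false;
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(d[k]) < 1e-15) {
        if (o[k] < lo[k] || o[k] > hi[k]) { miss = true; break; }
      } else {
        double ta = (lo[k] - o[k]) / d[k];
        double tb = (hi[k] - o[k]) / d[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
        if (t0 > t1) { miss = true; break; }
      }
    }
    if (miss) continue;
    // DDA setup at entry point
    double px = o[0] + t0 * d[0], py = o[1] + t0 * d[1],
           pz = o[2] + t0 * d[2];
    int ix = std::min(ng - 1, std::max(0, (int)((px - lo[0]) / cell[0])));
    int iy = std::min(ng - 1, std::max(0, (int)((py - lo[1]) / cell[1])));
    int iz = std::min(ng - 1, std::max(0, (int)((pz - lo[2]) / cell[2])));
    int step[3], icur[3] = {ix, iy, iz};
    double tmax[3], tdelta[3];
    for (int k = 0; k < 3; ++k) {
      if (d[k] > 1e-15) {
        step[k] = 1;
        tmax[k] = ((lo[k] + (icur[k] + 1) * cell[k]) - o[k]) / d[k];
        tdelta[k] = cell[k] / d[k];
      } else if (d[k] < -1e-15) {
        step[k] = -1;
        tmax[k] = ((lo[k] + icur[k] * cell[k]) - o[k]) / d[k];
        tdelta[k] = -cell[k] / d[k];
      } else {
        step[k] = 0;
        tmax[k] = R_PosInf;
        tdelta[k] = R_PosInf;
      }
    }
    double best = R_PosInf, bu = 0, bv = 0;
    int bid = 0;
    while (true) {
      const std::vector<int>& bin = bins[cidx(icur[0], icur[1], icur[2])];
      for (int t : bin) {
        double tt, u, v;
        if (intersect(tris[t], o, d, tt, u, v) && tt >= tmin && tt < best) {
          best = tt; bid = t + 1; bu = u; bv = v;
        }
      }
      double texit = std::min({tmax[0], tmax[1], tmax[2]});
      if (bid > 0 && best <= texit + 1e-12) break;  // hit inside this cell
      int k = (tmax[0] <= tmax[1])
                  ? (tmax[0] <= tmax[2] ? 0 : 2)
                  : (tmax[1] <= tmax[2] ? 1 : 2);
      icur[k] += step[k];
      if (icur[k] < 0 || icur[k] >= ng || texit > t1) break;
      tmax[k] += tdelta[k];
    }
    tout[r] = best;
    hit[r] = bid;
    if (bid > 0) {
      bw(r, 0) = 1.0 - bu - bv;
      bw(r, 1) = bu;
      bw(r, 2) = bv;
    }
  }
  return List::create(_["t"] = tout, _["tri"] = hit, _["bary"] = bw);
}
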