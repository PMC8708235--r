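// Isosurface extraction by marching tetrahedra on a node lattice, with
// vertex welding on shared lattice edges so the output is watertight for a
// level set that closes inside the grid. The Kuhn 6-tetrahedra subdivision
// of each cube is face-consistent across neighboring cells.
#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

namespace {
struct V3 { double x, y, z; };

inline uint64_t edge_key(uint32_t a, uint32_t b) {
  if (a > b) std::swap(a, b);
  return ((uint64_t)a << 32) | b;
}
}  // namespace

// field: node lattice values, x fastest (dims = nodes per axis); iso: level.
// Triangles are wound so normals point toward field > iso (outside when the
// field is a signed distance with outward-oriented normals).
// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, double cell, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* f0 = REAL(field);
  // nudge exact-iso nodes to avoid degenerate (zero-area) output triangles
  std::vector<double> f(f0, f0 + (size_t)nx * ny * nz);
  double eps = 1e-12 * (cell > 0 ? cell : 1.0);
  for (auto& v : f)
    if (v == iso) v = iso + eps;

  auto nid = [&](int i, int j, int k) -> uint32_t {
    return (uint32_t)(i + nx * (j + (size_t)ny * k));
  };
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> verts;       // x,y,z triplets
  std::vector<int> tris;           // 1-based triples
  std::vector<V3> npos((size_t)0); // not materialized; compute on the fly

  auto node_pos = [&](uint32_t id, V3& p) {
    uint32_t i = id % nx, rem = id / nx;
    uint32_t j = rem % ny, k = rem / ny;
    p.x = origin[0] + cell * i;
    p.y = origin[1] + cell * j;
    p.z = origin[2] + cell * k;
  };
  auto edge_vertex = [&](uint32_t a, uint32_t b) -> int {
    uint64_t key = edge_key(a, b);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = f[a] - iso, fb = f[b] - iso;
    double t = fa / (fa - fb);
    V3 pa, pb;
    node_pos(a, pa);
    node_pos(b, pb);
    verts.push_back(pa.x + t * (pb.x - pa.x));
    verts.push_back(pa.y + t * (pb.y - pa.y));
    verts.push_back(pa.z + t * (pb.z - pa.z));
    int id = (int)(verts.size() / 3);  // 1-based
    vmap.emplace(key, id);
    return id;
  };
  auto vpos = [&](int id1, V3& p) {
    p.x = verts[3 * (id1 - 1)];
    p.y = verts[3 * (id1 - 1) + 1];
    p.z = verts[3 * (id1 - 1) + 2];
  };
  // emit triangle (p,q,r), flipping so the normal points from the negative
  // side (ref_in, inside) toward positive
  auto emit = [&](int p, int q, int r, const V3& ref_in) {
    V3 a, b, c;
    vpos(p, a); vpos(q, b); vpos(r, c);
    double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
    double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
    double nxn = uy * vz - uz * vy;
    double nyn = uz * vx - ux * vz;
    double nzn = ux * vy - uy * vx;
    double gx = (a.x + b.x + c.x) / 3.0 - ref_in.x;
    double gy = (a.y + b.y + c.y) / 3.0 - ref_in.y;
    double gz = (a.z + b.z + c.z) / 3.0 - ref_in.z;
    if (nxn * gx + nyn * gy + nzn * gz < 0) std::swap(q, r);
    tris.push_back(p); tris.push_back(q); tris.push_back(r);
  };

  // Kuhn subdivision: 6 tets per cube, each a monotone corner path 0 -> 7
  static const int tet_corners[6][4] = {
      {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
      {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  // corner bit layout: bit0 = +x, bit1 = +y, bit2 = +z
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        uint32_t cid[8];
        for (int c = 0; c < 8; ++c)
          cid[c] = nid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
        // quick reject: all same side
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          if (f[cid[c]] < iso) any_neg = true; else any_pos = true;
        }
        if (!any_neg || !any_pos) continue;
        for (int tt = 0; tt < 6; ++tt) {
          uint32_t t0 = cid[tet_corners[tt][0]], t1 = cid[tet_corners[tt][1]],
                   t2 = cid[tet_corners[tt][2]], t3 = cid[tet_corners[tt][3]];
          uint32_t tv[4] = {t0, t1, t2, t3};
          bool neg[4];
          int nneg = 0;
          for (int c = 0; c < 4; ++c) {
            neg[c] = f[tv[c]] < iso;
            if (neg[c]) ++nneg;
          }
          if (nneg == 0 || nneg == 4) continue;
          if (nneg == 1 || nneg == 3) {
            // odd vertex alone on its side
            bool odd_is_neg = (nneg == 1);
            int oc = -1;
            for (int c = 0; c < 4; ++c)
              if (neg[c] == odd_is_neg) { oc = c; break; }
            int others[3], no = 0;
            for (int c = 0; c < 4; ++c)
              if (c != oc) others[no++] = c;
            int e0 = edge_vertex(tv[oc], tv[others[0]]);
            int e1 = edge_vertex(tv[oc], tv[others[1]]);
            int e2 = edge_vertex(tv[oc], tv[others[2]]);
            V3 ref;
            if (odd_is_neg) {
              node_pos(tv[oc], ref);
            } else {
              // inside reference: centroid of the three negative corners
              V3 p0, p1, p2;
              node_pos(tv[others[0]], p0);
              node_pos(tv[others[1]], p1);
              node_pos(tv[others[2]], p2);
              ref.x = (p0.x + p1.x + p2.x) / 3.0;
              ref.y = (p0.y + p1.y + p2.y) / 3.0;
              ref.z = (p0.z + p1.z + p2.z) / 3.0;
            }
            emit(e0, e1, e2, ref);
          } else {
            // 2-2 split: quad between the two sides
            int negs[2], poss[2], nn = 0, np = 0;
            for (int c = 0; c < 4; ++c) {
              if (neg[c]) negs[nn++] = c; else poss[np++] = c;
            }
            int eac = edge_vertex(tv[negs[0]], tv[poss[0]]);
            int ead = edge_vertex(tv[negs[0]], tv[poss[1]]);
            int ebc = edge_vertex(tv[negs[1]], tv[poss[0]]);
            int ebd = edge_vertex(tv[negs[1]], tv[poss[1]]);
            V3 pa, pb, ref;
            node_pos(tv[negs[0]], pa);
            node_pos(tv[negs[1]], pb);
            ref.x = (pa.x + pb.x) / 2.0;
            ref.y = (pa.y + pb.y) / 2.0;
            ref.z = (pa.z + pb.z) / 2.0;
            emit(eac, ead, ebd, ref);
            emit(eac, ebd, ebc, ref);
          }
        }
      }
    }
  }
  int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix Vm(nv, 3);
  for (int v = 0; v < nv; ++v) {
    Vm(v, 0) = verts[3 * v];
    Vm(v, 1) = verts[3 * v + 1];
    Vm(v, 2) = verts[3 * v + 2];
  }
  IntegerMatrix Fm(nt, 3);
  for (int t = 0; t < nt; ++t) {
    Fm(t, 0) = tris[3 * t];
    Fm(t, 1) = tris[3 * t + 1];
    Fm(t, 2) = tris[3 * t + 2];
  }
  return List::create(_["vertices"] = Vm, _["triangles"] = Fm);
}
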