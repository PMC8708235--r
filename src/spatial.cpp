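// Spatial queries and point-cloud numerics shared by the pipeline stages.
#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Balanced 3D kd-tree over row-major points. Nodes are the points themselves;
// median split by cycling axis.
struct KDTree {
  const double* P;  // n x 3, column-major from R: P[i + n*dim]
  int n;
  std::vector<int> id;  // permutation; subtree = contiguous range, root at mid

  KDTree(const double* pts, int npts) : P(pts), n(npts), id(npts) {
    for (int i = 0; i < n; ++i) id[i] = i;
    build(0, n, 0);
  }
  inline double coord(int i, int d) const { return P[i + (size_t)n * d]; }
  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2, ax = depth % 3;
    std::nth_element(id.begin() + lo, id.begin() + mid, id.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }
  inline double dist2(int i, const double* q) const {
    double dx = coord(i, 0) - q[0], dy = coord(i, 1) - q[1],
           dz = coord(i, 2) - q[2];
    return dx * dx + dy * dy + dz * dz;
  }
  // k nearest neighbors; heap holds (dist2, index)
  void knn(const double* q, int k,
           std::priority_queue<std::pair<double, int>>& heap) const {
    knn_rec(q, k, 0, n, 0, heap);
  }
  void knn_rec(const double* q, int k, int lo, int hi, int depth,
               std::priority_queue<std::pair<double, int>>& heap) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2, ax = depth % 3;
    int i = id[mid];
    double d2 = dist2(i, q);
    if ((int)heap.size() < k) heap.emplace(d2, i);
    else if (d2 < heap.top().first) { heap.pop(); heap.emplace(d2, i); }
    double diff = q[ax] - coord(i, ax);
    int nlo, nhi, flo, fhi;
    if (diff < 0) { nlo = lo; nhi = mid; flo = mid + 1; fhi = hi; }
    else          { nlo = mid + 1; nhi = hi; flo = lo; fhi = mid; }
    knn_rec(q, k, nlo, nhi, depth + 1, heap);
    if ((int)heap.size() < k || diff * diff < heap.top().first)
      knn_rec(q, k, flo, fhi, depth + 1, heap);
  }
  void radius(const double* q, double r2, std::vector<int>& out) const {
    radius_rec(q, r2, 0, n, 0, out);
  }
  void radius_rec(const double* q, double r2, int lo, int hi, int depth,
                  std::vector<int>& out) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2, ax = depth % 3;
    int i = id[mid];
    if (dist2(i, q) <= r2) out.push_back(i);
    double diff = q[ax] - coord(i, ax);
    if (diff < 0) {
      radius_rec(q, r2, lo, mid, depth + 1, out);
      if (diff * diff <= r2) radius_rec(q, r2, mid + 1, hi, depth + 1, out);
    } else {
      radius_rec(q, r2, mid + 1, hi, depth + 1, out);
      if (diff * diff <= r2) radius_rec(q, r2, lo, mid, depth + 1, out);
    }
  }
};

void heap_to_sorted(std::priority_queue<std::pair<double, int>>& heap,
                    std::vector<std::pair<double, int>>& out) {
  out.resize(heap.size());
  for (int j = (int)heap.size() - 1; j >= 0; --j) {
    out[j] = heap.top();
    heap.pop();
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_knn(NumericMatrix pts, NumericMatrix queries, int k) {
  int n = pts.nrow(), m = queries.nrow();
  if (k > n) stop("k exceeds number of points");
  KDTree tree(REAL(pts), n);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<std::pair<double, int>> nb;
  for (int i = 0; i < m; ++i) {
    double q[3] = {queries(i, 0), queries(i, 1), queries(i, 2)};
    std::priority_queue<std::pair<double, int>> heap;
    tree.knn(q, k, heap);
    heap_to_sorted(heap, nb);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = nb[j].second + 1;
      dist(i, j) = std::sqrt(nb[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Mean distance of each point to its k nearest neighbors (self excluded).
// [[Rcpp::export]]
NumericVector cpp_mean_knn_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k + 1 > n) stop("k+1 exceeds number of points");
  KDTree tree(REAL(pts), n);
  NumericVector out(n);
  std::vector<std::pair<double, int>> nb;
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    std::priority_queue<std::pair<double, int>> heap;
    tree.knn(q, k + 1, heap);
    heap_to_sorted(heap, nb);
    double s = 0; int cnt = 0; bool self_skipped = false;
    for (auto& pr : nb) {
      if (!self_skipped && pr.second == i) { self_skipped = true; continue; }
      if (cnt < k) { s += std::sqrt(pr.first); ++cnt; }
    }
    out[i] = s / cnt;
  }
  return out;
}

// Per-point normal as the smallest-eigenvalue eigenvector of the covariance
// of the k nearest neighbors (point itself included). Unoriented.
// [[Rcpp::export]]
NumericMatrix cpp_estimate_normals(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k > n) stop("k exceeds number of points");
  KDTree tree(REAL(pts), n);
  NumericMatrix out(n, 3);
  std::vector<std::pair<double, int>> nb;
  arma::mat33 C;
  arma::vec3 mu;
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    std::priority_queue<std::pair<double, int>> heap;
    tree.knn(q, k, heap);
    heap_to_sorted(heap, nb);
    mu.zeros();
    for (auto& pr : nb) {
      int j = pr.second;
      mu[0] += pts(j, 0); mu[1] += pts(j, 1); mu[2] += pts(j, 2);
    }
    mu /= (double)nb.size();
    C.zeros();
    for (auto& pr : nb) {
      int j = pr.second;
      arma::vec3 d = {pts(j, 0) - mu[0], pts(j, 1) - mu[1], pts(j, 2) - mu[2]};
      C += d * d.t();
    }
    arma::vec3 eigval;
    arma::mat33 eigvec;
    arma::eig_sym(eigval, eigvec, arma::symmatu(C));
    out(i, 0) = eigvec(0, 0);
    out(i, 1) = eigvec(1, 0);
    out(i, 2) = eigvec(2, 0);  // smallest eigenvalue first in eig_sym
  }
  return out;
}

// Moving-least-squares smoothing: project each point onto a local polynomial
// fit (degree `order`, 1 or 2) of its radius-neighborhood, expressed in the
// neighborhood's PCA frame. Points with too few neighbors pass through.
// [[Rcpp::export]]
NumericMatrix cpp_mls_smooth(NumericMatrix pts, double radius, int order) {
  int n = pts.nrow();
  KDTree tree(REAL(pts), n);
  NumericMatrix out(n, 3);
  double r2 = radius * radius;
  double h2 = (radius * radius) / 4.0;  // Gaussian weight bandwidth (r/2)^2
  int ncoef = (order >= 2) ? 6 : 3;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    nb.clear();
    tree.radius(q, r2, nb);
    int m = (int)nb.size();
    if (m < 4) {  // isolated: unchanged
      out(i, 0) = q[0]; out(i, 1) = q[1]; out(i, 2) = q[2];
      continue;
    }
    arma::vec3 mu; mu.zeros();
    for (int j : nb) { mu[0] += pts(j, 0); mu[1] += pts(j, 1); mu[2] += pts(j, 2); }
    mu /= (double)m;
    arma::mat33 C; C.zeros();
    for (int j : nb) {
      arma::vec3 d = {pts(j, 0) - mu[0], pts(j, 1) - mu[1], pts(j, 2) - mu[2]};
      C += d * d.t();
    }
    arma::vec3 eigval;
    arma::mat33 ev;
    arma::eig_sym(eigval, ev, arma::symmatu(C));
    arma::vec3 nrm = ev.col(0), e1 = ev.col(2), e2 = ev.col(1);
    int use = (m >= ncoef + 2) ? ncoef : 3;  // fall back to plane if sparse
    arma::mat A(m, use);
    arma::vec b(m), w(m);
    for (int t = 0; t < m; ++t) {
      int j = nb[t];
      arma::vec3 d = {pts(j, 0) - mu[0], pts(j, 1) - mu[1], pts(j, 2) - mu[2]};
      double u = arma::dot(d, e1), v = arma::dot(d, e2), z = arma::dot(d, nrm);
      A(t, 0) = 1.0; A(t, 1) = u; A(t, 2) = v;
      if (use == 6) { A(t, 3) = u * u; A(t, 4) = u * v; A(t, 5) = v * v; }
      b[t] = z;
      w[t] = std::exp(-(u * u + v * v) / (2.0 * h2));
    }
    arma::mat Aw = A.each_col() % w;
    arma::vec coef;
    bool ok = arma::solve(coef, Aw.t() * A, Aw.t() * b,
                          arma::solve_opts::likely_sympd);
    if (!ok) {
      out(i, 0) = q[0]; out(i, 1) = q[1]; out(i, 2) = q[2];
      continue;
    }
    arma::vec3 d0 = {q[0] - mu[0], q[1] - mu[1], q[2] - mu[2]};
    double u0 = arma::dot(d0, e1), v0 = arma::dot(d0, e2);
    double z0 = coef[0] + coef[1] * u0 + coef[2] * v0;
    if (use == 6) z0 += coef[3] * u0 * u0 + coef[4] * u0 * v0 + coef[5] * v0 * v0;
    arma::vec3 p = mu + u0 * e1 + v0 * e2 + z0 * nrm;
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
  }
  return out;
}

// Signed distance field from oriented points, sampled on a node lattice:
// weighted average over the k nearest points of the signed distance to each
// point's tangent plane (Gaussian weights, bandwidth from the neighbor
// spread). Negative inside the surface when normals point outward.
// [[Rcpp::export]]
NumericVector cpp_sdf_grid(NumericMatrix pts, NumericMatrix normals,
                           NumericVector origin, double cell,
                           IntegerVector dims, int k) {
  int n = pts.nrow();
  if (k > n) k = n;
  KDTree tree(REAL(pts), n);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector field((R_xlen_t)nx * ny * nz);
  std::vector<std::pair<double, int>> nb;
  for (int kk = 0; kk < nz; ++kk) {
    Rcpp::checkUserInterrupt();
    for (int jj = 0; jj < ny; ++jj) {
      for (int ii = 0; ii < nx; ++ii) {
        double q[3] = {origin[0] + cell * ii, origin[1] + cell * jj,
                       origin[2] + cell * kk};
        std::priority_queue<std::pair<double, int>> heap;
        tree.knn(q, k, heap);
        heap_to_sorted(heap, nb);
        double d0 = std::sqrt(nb[0].first);
        double h = std::max(d0, cell) * 1.0;
        double sw = 0, sf = 0;
        for (auto& pr : nb) {
          int j = pr.second;
          double dx = q[0] - pts(j, 0), dy = q[1] - pts(j, 1),
                 dz = q[2] - pts(j, 2);
          double sd = dx * normals(j, 0) + dy * normals(j, 1) +
                      dz * normals(j, 2);
          double w = std::exp(-pr.first / (2.0 * h * h));
          sw += w; sf += w * sd;
        }
        field[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] =
            sf / sw;
      }
    }
  }
  return field;
}

namespace {
// Ericson closest point on triangle
inline void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { std::copy(a, a + 3, out); return; }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { std::copy(b, b + 3, out); return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int t = 0; t < 3; ++t) out[t] = a[t] + v * ab[t];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { std::copy(c, c + 3, out); return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int t = 0; t < 3; ++t) out[t] = a[t] + w * ac[t];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int t = 0; t < 3; ++t) out[t] = b[t] + w * (c[t] - b[t]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int t = 0; t < 3; ++t) out[t] = a[t] + ab[t] * v + ac[t] * w;
}
}  // namespace

// Unsigned distance from each query point to a triangle mesh. Uses a kd-tree
// on triangle centroids to shortlist candidates, then exact point-triangle
// distance on the shortlist (padded by the largest triangle radius).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix V, IntegerMatrix F,
                                  NumericMatrix Q, int shortlist = 32) {
  int m = F.nrow(), nq = Q.nrow();
  NumericMatrix cent(m, 3);
  double maxrad = 0;
  for (int t = 0; t < m; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    for (int d = 0; d < 3; ++d) cent(t, d) = (V(a, d) + V(b, d) + V(c, d)) / 3.0;
    for (int vi : {a, b, c}) {
      double dd = 0;
      for (int d = 0; d < 3; ++d) {
        double e = V(vi, d) - cent(t, d);
        dd += e * e;
      }
      maxrad = std::max(maxrad, std::sqrt(dd));
    }
  }
  if (shortlist > m) shortlist = m;
  KDTree tree(REAL(cent), m);
  NumericVector out(nq);
  std::vector<std::pair<double, int>> nb;
  for (int i = 0; i < nq; ++i) {
    double q[3] = {Q(i, 0), Q(i, 1), Q(i, 2)};
    std::priority_queue<std::pair<double, int>> heap;
    tree.knn(q, shortlist, heap);
    heap_to_sorted(heap, nb);
    double best = R_PosInf;
    double bound = std::sqrt(nb.back().first) + maxrad;
    for (auto& pr : nb) {
      if (std::sqrt(pr.first) - maxrad > best) continue;
      int t = pr.second;
      int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
      double pa[3] = {V(a, 0), V(a, 1), V(a, 2)};
      double pb[3] = {V(b, 0), V(b, 1), V(b, 2)};
      double pc[3] = {V(c, 0), V(c, 1), V(c, 2)};
      double cp[3];
      closest_on_tri(q, pa, pb, pc, cp);
      double dd = 0;
      for (int d = 0; d < 3; ++d) {
        double e = q[d] - cp[d];
        dd += e * e;
      }
      best = std::min(best, std::sqrt(dd));
    }
    (void)bound;
    out[i] = best;
  }
  return out;
}
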