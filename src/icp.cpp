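// Inner loop of point-to-point ICP: correspondence search (kd-tree),
// rejection (cap, mutual-NN, trim quantile) and the closed-form rigid fit,
// iterated to convergence. The R wrapper owns staging and conventions.
#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {
struct KD2 {
  const std::vector<double>* P;
  int n;
  std::vector<int> id;
  KD2(const std::vector<double>& pts, int npts) : P(&pts), n(npts), id(npts) {
    for (int i = 0; i < n; ++i) id[i] = i;
    build(0, n, 0);
  }
  inline double coord(int i, int d) const { return (*P)[3 * i + d]; }
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
  void nn1(const double* q, int& best, double& bestd2) const {
    best = -1;
    bestd2 = R_PosInf;
    rec(q, 0, n, 0, best, bestd2);
  }
  void rec(const double* q, int lo, int hi, int depth, int& best,
           double& bestd2) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2, ax = depth % 3;
    int i = id[mid];
    double d2 = dist2(i, q);
    if (d2 < bestd2) { bestd2 = d2; best = i; }
    double diff = q[ax] - coord(i, ax);
    if (diff < 0) {
      rec(q, lo, mid, depth + 1, best, bestd2);
      if (diff * diff < bestd2) rec(q, mid + 1, hi, depth + 1, best, bestd2);
    } else {
      rec(q, mid + 1, hi, depth + 1, best, bestd2);
      if (diff * diff < bestd2) rec(q, lo, mid, depth + 1, best, bestd2);
    }
  }
};
}  // namespace

// [[Rcpp::export]]
List cpp_icp(NumericMatrix src, NumericMatrix tgt, NumericMatrix init,
             double max_corr, int max_iter, double tol, bool reciprocal,
             double trim, Nullable<NumericMatrix> src_normals = R_NilValue,
             Nullable<NumericMatrix> tgt_normals = R_NilValue,
             double normal_cos = 0.5) {
  int ns = src.nrow(), nt = tgt.nrow();
  bool use_normals = src_normals.isNotNull() && tgt_normals.isNotNull();
  NumericMatrix sN, tN;
  if (use_normals) {
    sN = NumericMatrix(src_normals);
    tN = NumericMatrix(tgt_normals);
  }
  std::vector<double> T(nt * 3);
  for (int i = 0; i < nt; ++i)
    for (int d = 0; d < 3; ++d) T[3 * i + d] = tgt(i, d);
  KD2 ttree(T, nt);

  arma::mat33 R;
  arma::vec3 tr;
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) R(r, c) = init(r, c);
    tr[r] = init(r, 3);
  }
  double rms = NA_REAL;
  int iters = 0, ncorr = 0;
  bool converged = false;
  std::vector<double> S(ns * 3);
  std::vector<int> nn(ns);
  std::vector<double> nd(ns);
  std::vector<double> dists;
  double cap2 = max_corr * max_corr;

  for (int stage = 0; stage < (reciprocal ? 2 : 1); ++stage) {
    bool recip = reciprocal && stage == 1;
    double rms_prev = R_PosInf;
    for (int it = 0; it < max_iter; ++it) {
      ++iters;
      for (int i = 0; i < ns; ++i) {
        double x = src(i, 0), y = src(i, 1), z = src(i, 2);
        S[3 * i + 0] = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + tr[0];
        S[3 * i + 1] = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + tr[1];
        S[3 * i + 2] = R(2, 0) * x + R(2, 1) * y + R(2, 2) * z + tr[2];
      }
      for (int i = 0; i < ns; ++i) {
        int b;
        double d2;
        ttree.nn1(&S[3 * i], b, d2);
        nn[i] = b;
        nd[i] = d2;
      }
      std::vector<char> ok(ns, 0);
      for (int i = 0; i < ns; ++i) ok[i] = nd[i] <= cap2;
      if (use_normals) {
        // reject pairs whose surface normals disagree (wrong-side matches
        // on thin structures, silhouette mismatches)
        for (int i = 0; i < ns; ++i) {
          if (!ok[i]) continue;
          double nx = sN(i, 0), ny = sN(i, 1), nz = sN(i, 2);
          double rx = R(0, 0) * nx + R(0, 1) * ny + R(0, 2) * nz;
          double ry = R(1, 0) * nx + R(1, 1) * ny + R(1, 2) * nz;
          double rz = R(2, 0) * nx + R(2, 1) * ny + R(2, 2) * nz;
          int j = nn[i];
          double dot = rx * tN(j, 0) + ry * tN(j, 1) + rz * tN(j, 2);
          if (dot < normal_cos) ok[i] = 0;
        }
      }
      if (recip) {
        KD2 stree(S, ns);
        for (int i = 0; i < ns; ++i) {
          if (!ok[i]) continue;
          int b;
          double d2;
          stree.nn1(&T[3 * nn[i]], b, d2);
          if (b != i) ok[i] = 0;
        }
      }
      if (trim < 1.0) {
        dists.clear();
        for (int i = 0; i < ns; ++i)
          if (ok[i]) dists.push_back(nd[i]);
        if ((int)dists.size() > 10) {
          size_t k = (size_t)(trim * (dists.size() - 1));
          std::nth_element(dists.begin(), dists.begin() + k, dists.end());
          double thr = dists[k];
          for (int i = 0; i < ns; ++i)
            if (ok[i] && nd[i] > thr) ok[i] = 0;
        }
      }
      ncorr = 0;
      arma::vec3 mp = arma::zeros(3), mq = arma::zeros(3);
      double ssq = 0;
      for (int i = 0; i < ns; ++i) {
        if (!ok[i]) continue;
        ++ncorr;
        for (int d = 0; d < 3; ++d) {
          mp[d] += S[3 * i + d];
          mq[d] += T[3 * nn[i] + d];
        }
        ssq += nd[i];
      }
      if (ncorr < 3)
        stop("icp: no correspondences within max_corr_dist; clouds do not "
             "overlap under the initial transform");
      mp /= ncorr;
      mq /= ncorr;
      rms = std::sqrt(ssq / ncorr);
      if (R_finite(rms_prev) &&
          std::fabs(rms_prev - rms) <= tol * std::max(rms_prev, 1e-12)) {
        converged = true;
        break;
      }
      rms_prev = rms;
      arma::mat33 H = arma::zeros(3, 3);
      for (int i = 0; i < ns; ++i) {
        if (!ok[i]) continue;
        arma::vec3 p = {S[3 * i] - mp[0], S[3 * i + 1] - mp[1],
                        S[3 * i + 2] - mp[2]};
        arma::vec3 q = {T[3 * nn[i]] - mq[0], T[3 * nn[i] + 1] - mq[1],
                        T[3 * nn[i] + 2] - mq[2]};
        H += p * q.t();
      }
      arma::mat U, Vm;
      arma::vec s;
      arma::svd(U, s, Vm, H);
      arma::mat33 D = arma::eye(3, 3);
      D(2, 2) = arma::det(Vm * U.t()) < 0 ? -1.0 : 1.0;
      arma::mat33 dR = Vm * D * U.t();
      arma::vec3 dt = mq - dR * mp;
      R = dR * R;
      tr = dR * tr + dt;
    }
  }
  NumericMatrix out(4, 4);
  out(3, 3) = 1;
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) out(r, c) = R(r, c);
    out(r, 3) = tr[r];
  }
  return List::create(_["transform"] = out, _["rms"] = rms,
                      _["n_corr"] = ncorr, _["iterations"] = iters,
                      _["converged"] = converged);
}
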