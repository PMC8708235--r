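# Coordinate systems and closed-form projection math.
#
# Four frames are used throughout:
#   DCS - depth-scanner coordinates, one per scan;
#   OCS - object coordinates: origin on the floor, Y up the rotation axis,
#         Z toward the front of the body;
#   CCS - camera coordinates, Z along the optical axis into the scene;
#   VCS - virtual orthographic-camera coordinates on the surface tangent
#         plane, used for orthorectification.

#' Rigid pose of a device on the rotating arm
#'
#' Describes where a camera or depth scanner sat when it acquired data: the
#' arm rotation angle `alpha` about the vertical axis, the device height `h`
#' above the floor and its distance `r` to the rotation axis.
#'
#' @param alpha Arm rotation angle. Radians unless `degrees = TRUE`.
#' @param h Device height above the floor (meters).
#' @param r Device distance to the rotation axis (meters, > 0 for a real
#'   device; 0 is tolerated for synthetic identity poses).
#' @param degrees Interpret `alpha` as degrees (the convention at the
#'   configuration boundary; radians are used internally).
#' @return An object of class `rigid_pose` with fields `alpha` (radians,
#'   normalized to `[0, 2*pi)`), `h`, `r`.
#' @examples
#' rigid_pose(45, h = 1.2, r = 0.9, degrees = TRUE)
#' @export
rigid_pose <- function(alpha, h, r, degrees = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (degrees) alpha <- alpha * pi / 180
  alpha <- alpha %% (2 * pi)
  stopifnot(is.finite(h), r >= 0)
  structure(list(alpha = alpha, h = h, r = r), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("rigid_pose: alpha = %.2f deg, h = %.3f m, r = %.3f m\n",
              x$alpha * 180 / pi, x$h, x$r))
  invisible(x)
}

#' Intrinsic calibration of a high-resolution camera
#'
#' The calibration matrix `Q` and vector `T` absorb mounting imperfections
#' (the camera sitting slightly askew or shifted on the arm); `d` is the
#' pinhole projection constant linking metric offsets on the sensor plane to
#' pixels, and `principal_point` locates the optical axis in the image.
#'
#' @param Q 3x3 calibration matrix (invertible; identity for an ideally
#'   mounted camera).
#' @param T 3-vector calibration offset (meters).
#' @param d Pinhole constant (> 0): a point at depth `z` maps to pixel
#'   offsets `x_CCS / (d * z)` from the principal point.
#' @param image_size `c(width, height)` in pixels.
#' @param principal_point 2-vector in pixels, 0-based image coordinates
#'   (origin at the top-left pixel center, x right, y down). Defaults to the
#'   image center.
#' @return An object of class `camera_calib`.
#' @export
camera_calib <- function(Q = diag(3), T = c(0, 0, 0), d, image_size,
                         principal_point = NULL) {
  Q <- as.matrix(Q)
  stopifnot(all(dim(Q) == c(3, 3)), abs(det(Q)) > 1e-12,
            length(T) == 3, d > 0, length(image_size) == 2,
            all(image_size >= 1))
  if (is.null(principal_point))
    principal_point <- (image_size - 1) / 2
  stopifnot(length(principal_point) == 2,
            principal_point[1] >= 0, principal_point[1] <= image_size[1] - 1,
            principal_point[2] >= 0, principal_point[2] <= image_size[2] - 1)
  structure(list(Q = Q, T = as.numeric(T), d = d,
                 image_size = as.integer(image_size),
                 principal_point = as.numeric(principal_point)),
            class = "camera_calib")
}

# rotation about Y by alpha: R %*% p
rot_y <- function(alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  matrix(c(ca, 0, sa,
           0, 1, 0,
           -sa, 0, ca), 3, 3)  # column-major: R = [[ca,0,-sa],[0,1,0],[sa,0,ca]]
}

as_points <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    matrix(p, 1, 3)
  } else {
    stopifnot(ncol(p) == 3)
    as.matrix(p)
  }
}

#' Transform points from scanner (DCS) to object (OCS) coordinates
#'
#' Points are first translated by the device offset `[0, h, -r]` and then
#' rotated about the vertical axis by the arm angle, so a point lying on the
#' rotation axis is invariant to `alpha`.
#'
#' @param points 3-vector or n x 3 matrix in DCS (meters).
#' @param pose A [rigid_pose()].
#' @return Points in OCS, same shape as the input.
#' @seealso [ocs_to_dcs()], [ocs_to_ccs()]
#' @export
dcs_to_ocs <- function(points, pose) {
  p <- as_points(points)
  q <- sweep(p, 2, c(0, -pose$h, pose$r))  # p + [0, h, -r]
  out <- q %*% t(rot_y(pose$alpha))
  if (is.null(dim(points))) drop(out) else out
}

#' Inverse of [dcs_to_ocs()]
#' @inheritParams dcs_to_ocs
#' @param points 3-vector or n x 3 matrix in OCS.
#' @export
ocs_to_dcs <- function(points, pose) {
  p <- as_points(points)
  out <- sweep(p %*% t(rot_y(-pose$alpha)), 2, c(0, pose$h, -pose$r))
  if (is.null(dim(points))) drop(out) else out
}

#' Transform points from object (OCS) to camera (CCS) coordinates
#'
#' `p_CCS = Q (R_y(-alpha) p_OCS - [0, h, -r]) + T`. With `Q = I`, `T = 0`
#' and a pose equal to the acquiring scanner's, this inverts [dcs_to_ocs()].
#'
#' @param points 3-vector or n x 3 matrix in OCS.
#' @param pose The camera's [rigid_pose()].
#' @param calib The camera's [camera_calib()].
#' @export
ocs_to_ccs <- function(points, pose, calib) {
  p <- as_points(points)
  q <- sweep(p %*% t(rot_y(-pose$alpha)), 2, c(0, pose$h, -pose$r))
  out <- sweep(q %*% t(calib$Q), 2, -calib$T)
  if (is.null(dim(points))) drop(out) else out
}

#' Inverse of [ocs_to_ccs()]
#' @inheritParams ocs_to_ccs
#' @param points 3-vector or n x 3 matrix in CCS.
#' @export
ccs_to_ocs <- function(points, pose, calib) {
  p <- as_points(points)
  q <- sweep(p, 2, calib$T) %*% t(solve(calib$Q))
  out <- sweep(q, 2, c(0, -pose$h, pose$r)) %*% t(rot_y(pose$alpha))
  if (is.null(dim(points))) drop(out) else out
}

#' Camera center in object coordinates
#'
#' The OCS position where `p_CCS = 0`; for `Q = I`, `T = 0` this is
#' `R_y(alpha) [0, h, -r]`.
#' @inheritParams ocs_to_ccs
#' @export
camera_center <- function(pose, calib = NULL) {
  if (is.null(calib)) calib <- camera_calib(d = 1, image_size = c(2, 2))
  ccs_to_ocs(c(0, 0, 0), pose, calib)
}

#' Pinhole projection of camera-frame points into image pixels
#'
#' `[x_t, y_t] = x_CCS[1:2] / (d * z_CCS) + principal_point`. Points at or
#' behind the camera plane (`z_CCS <= 0`) are an error unless
#' `na_behind = TRUE`, in which case they yield `NA` rows (used internally
#' by the renderer).
#'
#' @param points 3-vector or n x 3 matrix in CCS.
#' @param calib A [camera_calib()].
#' @param na_behind Return `NA` instead of erroring for `z_CCS <= 0`.
#' @return Pixel coordinates (0-based, x right / y down), same shape rule as
#'   the input.
#' @export
project_pinhole <- function(points, calib, na_behind = FALSE) {
  p <- as_points(points)
  z <- p[, 3]
  bad <- z <= 0
  if (any(bad) && !na_behind)
    stop("project_pinhole: point(s) at nonpositive depth (behind the camera)")
  out <- cbind(p[, 1] / (calib$d * z) + calib$principal_point[1],
               p[, 2] / (calib$d * z) + calib$principal_point[2])
  out[bad, ] <- NA_real_
  if (is.null(dim(points))) drop(out) else out
}

#' Unit normal of a triangle
#'
#' Direction of `(B - A) x (C - A)`, renormalized to unit length. The
#' orientation follows the winding order: counter-clockwise seen from the
#' outside gives an outward normal.
#'
#' @param A,B,C Triangle vertices (3-vectors).
#' @param tol Degeneracy tolerance on the cross-product norm.
#' @export
triangle_normal <- function(A, B, C, tol = 1e-12) {
  u <- B - A
  v <- C - A
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  if (nn <= tol) stop("triangle_normal: degenerate triangle")
  n / nn
}

#' Virtual orthographic camera frame on the tangent plane
#'
#' Builds the frame of the virtual camera used for orthorectification: its
#' optical axis `Z` is antiparallel to the surface normal, `X` is horizontal
#' (parallel to the OCS XZ plane), and `Y = X x Z` completes the
#' right-handed, row-wise orthonormal rotation `G`.
#'
#' When the normal is (numerically) parallel to the vertical axis every
#' horizontal direction is admissible for `X`; the frame then falls back to
#' `X = (1, 0, 0)` deterministically.
#'
#' @param n Unit outward surface normal at the anchor.
#' @param V Anchor point on the surface (OCS, meters).
#' @param s Scale of the orthorectified raster, pixels per meter.
#' @param tol Degeneracy tolerance for the horizontal component of `n`.
#' @return An object of class `virtual_frame` with fields `V`, `G` (rows
#'   `X`, `Y`, `Z`), `s`.
#' @export
build_virtual_frame <- function(n, V, s, tol = 1e-9) {
  stopifnot(length(n) == 3, abs(sqrt(sum(n^2)) - 1) < 1e-6, s > 0)
  Z <- -n
  hh <- Z[3]^2 + Z[1]^2  # g_zz^2 + g_zx^2
  if (hh < tol^2) {
    X <- c(1, 0, 0)
  } else {
    X <- c(Z[3], 0, -Z[1]) / sqrt(hh)
  }
  Y <- c(X[2] * Z[3] - X[3] * Z[2],
         X[3] * Z[1] - X[1] * Z[3],
         X[1] * Z[2] - X[2] * Z[1])
  G <- rbind(X, Y, Z, deparse.level = 0)
  structure(list(V = as.numeric(V), G = G, s = s), class = "virtual_frame")
}

#' @export
print.virtual_frame <- function(x, ...) {
  cat(sprintf("virtual_frame: V = (%.4f, %.4f, %.4f), s = %g px/m\n",
              x$V[1], x$V[2], x$V[3], x$s))
  invisible(x)
}

#' Transform points from object (OCS) to virtual-camera (VCS) coordinates
#'
#' `p_VCS = G (p_OCS - V)`; the anchor maps to the origin, the outward
#' normal to `(0, 0, -1)`.
#' @param points 3-vector or n x 3 matrix in OCS.
#' @param frame A [build_virtual_frame()] result.
#' @export
ocs_to_vcs <- function(points, frame) {
  p <- as_points(points)
  out <- sweep(p, 2, frame$V) %*% t(frame$G)
  if (is.null(dim(points))) drop(out) else out
}

#' Inverse of [ocs_to_vcs()] (uses `G^-1 = G^T`)
#' @inheritParams ocs_to_vcs
#' @param points 3-vector or n x 3 matrix in VCS.
#' @export
vcs_to_ocs <- function(points, frame) {
  p <- as_points(points)
  out <- sweep(p %*% frame$G, 2, -frame$V)
  if (is.null(dim(points))) drop(out) else out
}

#' Orthographic projection onto the virtual image
#'
#' `[x_g, y_g] = s * [x_VCS, y_VCS]`; depth is discarded.
#' @param points 3-vector or n x 3 matrix in VCS.
#' @param s Scale in pixels per meter.
#' @export
ortho_project <- function(points, s) {
  stopifnot(s > 0)
  p <- as_points(points)
  out <- s * p[, 1:2, drop = FALSE]
  if (is.null(dim(points))) drop(out) else out
}

#' Back-projection from virtual-image coordinates to the tangent plane
#'
#' `p_OCS = (x_g X + y_g Y) / s + V` -- the point of the tangent plane at
#' the anchor `V` that projects to `[x_g, y_g]`; `(0, 0)` maps to `V`.
#' @param xg_yg 2-vector or n x 2 matrix of virtual-image coordinates.
#' @param frame A [build_virtual_frame()] result.
#' @export
ortho_unproject <- function(xg_yg, frame) {
  p <- if (is.null(dim(xg_yg))) matrix(xg_yg, 1, 2) else as.matrix(xg_yg)
  out <- sweep(p %*% frame$G[1:2, , drop = FALSE] / frame$s, 2, -frame$V)
  if (is.null(dim(xg_yg))) drop(out) else out
}

#' Point inside a triangle from barycentric weights
#'
#' `V = (r A + g B + b C) / (r + g + b)` -- the decoding step of the
#' barycentric color shading, with the weights read off the red/green/blue
#' channels of the shaded render.
#'
#' @param w Non-negative weights `(r, g, b)` with a positive sum.
#' @param A,B,C Triangle vertices (3-vectors).
#' @export
barycentric_point <- function(w, A, B, C) {
  stopifnot(length(w) == 3, all(w >= 0))
  s <- sum(w)
  if (s <= 0) stop("barycentric_point: all-zero weights")
  (w[1] * A + w[2] * B + w[3] * C) / s
}

# small rigid-transform helpers (4x4 homogeneous)
rt_make <- function(R, t) {
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t
  M
}
rt_apply <- function(M, pts) {
  p <- as_points(pts)
  sweep(p %*% t(M[1:3, 1:3]), 2, -M[1:3, 4])
}
rt_angle <- function(M) {
  tr <- sum(diag(M[1:3, 1:3]))
  acos(min(1, max(-1, (tr - 1) / 2)))
}
rt_trans_norm <- function(M) sqrt(sum(M[1:3, 4]^2))

# SO(3) exp/log (Rodrigues)
so3_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew(w))
  K <- skew(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
so3_log <- function(R) {
  tr <- sum(diag(R))
  th <- acos(min(1, max(-1, (tr - 1) / 2)))
  if (th < 1e-12) {
    c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  } else {
    th / (2 * sin(th)) *
      c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  }
}
skew <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}
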