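# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; expensive objects are memoised.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fix)) assign(name, builder(), envir = .fix)
  get(name, envir = .fix)
}

# small markerless phantom (coarse, fast)
small_phantom <- function() fixture("small_phantom", function() {
  build_phantom(phantom_spec(), n_theta = 48, ring_step = 0.04)
})

# planar "phantom face": a textured quad with an analytic disk + checker
# texture painted in the plane's own coordinates, optionally tilted about
# the vertical axis through its center (tilt 0 faces a camera at alpha =
# 0, i.e. outward normal (0,0,-1)).
plane_phantom <- function(center = c(0, 1.0, -0.11), size = 0.3,
                          disk_r = 0.01, tilt_deg = 0) {
  h <- size / 2
  th <- tilt_deg * pi / 180
  e1 <- c(cos(th), 0, sin(th))     # in-plane horizontal axis
  e2 <- c(0, 1, 0)                 # in-plane vertical axis
  nrm <- c(sin(th), 0, -cos(th))   # outward normal
  V <- rbind(center - h * e1 - h * e2, center + h * e1 - h * e2,
             center + h * e1 + h * e2, center - h * e1 + h * e2)
  # counter-clockwise seen from the normal side
  F <- rbind(c(1, 4, 2), c(2, 4, 3))
  mesh <- tri_mesh(V, F)
  texture_fn <- function(p) {
    d <- sweep(as.matrix(p), 2, center)
    du <- as.numeric(d %*% e1)
    dv <- as.numeric(d %*% e2)
    inside <- du^2 + dv^2 <= disk_r^2
    checker <- ((floor(du / 0.02) + floor(dv / 0.02)) %% 2) == 0
    col <- matrix(0.85, nrow(d), 3)
    col[checker, ] <- 0.65
    col[inside, ] <- 0.05
    col
  }
  list(mesh = mesh, texture_fn = texture_fn, center = center,
       normal = nrm, disk_r = disk_r)
}

# independent brute-force Moller-Trumbore raycaster (R, vectorized over
# triangles per ray batch) -- the oracle for the rasterizer and for
# visibility tests; written without reference to the package's C++ path
raycast_oracle <- function(mesh, origin, dirs) {
  V <- mesh$vertices
  F <- mesh$triangles
  n <- nrow(dirs)
  best_t <- rep(Inf, n)
  best_id <- integer(n)
  O <- matrix(origin, n, 3, byrow = TRUE)
  for (t in seq_len(nrow(F))) {
    A <- V[F[t, 1], ]
    E1 <- V[F[t, 2], ] - A
    E2 <- V[F[t, 3], ] - A
    pv <- cbind(dirs[, 2] * E2[3] - dirs[, 3] * E2[2],
                dirs[, 3] * E2[1] - dirs[, 1] * E2[3],
                dirs[, 1] * E2[2] - dirs[, 2] * E2[1])
    det <- as.numeric(pv %*% E1)
    tv <- sweep(O, 2, A)
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * E1[3] - tv[, 3] * E1[2],
                tv[, 3] * E1[1] - tv[, 1] * E1[3],
                tv[, 1] * E1[2] - tv[, 2] * E1[1])
    v <- rowSums(dirs * qv) / det
    tt <- as.numeric(qv %*% E2) / det
    hit <- abs(det) > 1e-14 & u >= 0 & u <= 1 & v >= 0 & u + v <= 1 &
      tt > 1e-9 & tt < best_t
    best_t[hit] <- tt[hit]
    best_id[hit] <- t
  }
  list(t = best_t, tri = best_id)
}

# pixel-grid ray directions (OCS) for a camera view
view_rays <- function(pose, calib) {
  W <- calib$image_size[1]
  H <- calib$image_size[2]
  O <- camera_center(pose, calib)
  xt <- rep(0:(W - 1), each = H)
  yt <- rep(0:(H - 1), times = W)
  d_ccs <- cbind((xt - calib$principal_point[1]) * calib$d,
                 (yt - calib$principal_point[2]) * calib$d, 1)
  dirs <- sweep(ccs_to_ocs(d_ccs, pose, calib), 2, O)
  list(origin = O, dirs = dirs, xt = xt, yt = yt, W = W, H = H)
}

rot_angle_deg <- function(M) {
  tr <- sum(diag(M[1:3, 1:3]))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}
trans_norm_mm <- function(M) 1000 * sqrt(sum(M[1:3, 4]^2))

random_unit <- function(n) {
  u <- matrix(rnorm(3 * n), n, 3)
  u / sqrt(rowSums(u^2))
}
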