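test_that("scanner-to-object transform matches its defining geometry", {
  # identity pose
  expect_equal(dcs_to_ocs(c(1, 2, 3), rigid_pose(0, 0, 0)), c(1, 2, 3))
  # a point on the rotation axis is invariant to the arm angle
  for (al in c(0, 0.7, 2.9)) {
    p <- rigid_pose(al, h = 1.2, r = 0.7)
    expect_equal(dcs_to_ocs(c(0, 0, 0.7), p), c(0, 1.2, 0), tolerance = 1e-12)
  }
  # quarter turn about Y
  expect_equal(dcs_to_ocs(c(1, 0, 0), rigid_pose(pi / 2, 0, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  # degrees at the config boundary
  expect_equal(rigid_pose(90, 0, 1, degrees = TRUE)$alpha, pi / 2)
  expect_equal(rigid_pose(-90, 0, 1, degrees = TRUE)$alpha, 3 * pi / 2)
})

test_that("camera transform inverts the scanner transform for coincident devices", {
  cal0 <- camera_calib(d = 1, image_size = c(2, 2))
  set.seed(1)
  P <- matrix(rnorm(3000), ncol = 3)
  pose <- rigid_pose(1.1, 1.2, 0.7)
  back <- ocs_to_ccs(dcs_to_ocs(P, pose), pose, cal0)
  expect_lt(max(abs(back - P)), 1e-12)
  # camera center sits at R_y(alpha) [0, h, -r]
  expect_equal(camera_center(rigid_pose(0, 1, 2)), c(0, 1, -2),
               tolerance = 1e-12)
  a <- rigid_pose(pi / 2, 1.5, 2)
  expect_equal(camera_center(a), c(2, 1.5, 0), tolerance = 1e-12)
  # a subject point 2 m in front of the camera has z_CCS = +2
  expect_equal(ocs_to_ccs(c(0, 1, 0), rigid_pose(0, 1, 2), cal0), c(0, 0, 2),
               tolerance = 1e-12)
})

test_that("pinhole projection follows the central-projection model", {
  cal <- camera_calib(d = 1e-4, image_size = c(1000, 1000),
                      principal_point = c(0, 0))
  expect_equal(project_pinhole(c(0.02, -0.01, 0.5), cal), c(400, -200))
  # optical-axis points project to the principal point
  cal2 <- camera_calib(d = 2e-4, image_size = c(640, 480))
  for (z in c(0.3, 1, 7))
    expect_equal(project_pinhole(c(0, 0, z), cal2), (c(640, 480) - 1) / 2)
  # ray invariance: p and k p project identically
  set.seed(2)
  p <- matrix(rnorm(300), ncol = 3)
  p[, 3] <- abs(p[, 3]) + 0.1
  expect_equal(project_pinhole(p, cal2), project_pinhole(3.7 * p, cal2),
               tolerance = 1e-9)
  # behind-camera error
  expect_error(project_pinhole(c(0, 0, -1), cal2), "depth")
})

test_that("triangle normals are unit length, scale invariant and antisymmetric", {
  expect_equal(triangle_normal(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               c(0, 0, 1))
  expect_equal(triangle_normal(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0)),
               c(0, 0, 1))
  expect_equal(triangle_normal(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0)),
               c(0, 0, -1))
  expect_error(triangle_normal(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "degenerate")
})

test_that("virtual frame axes follow the tangent-plane construction", {
  f <- build_virtual_frame(c(0, 0, 1), c(0, 0, 0), 1000)
  expect_equal(f$G, rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1)))
  f2 <- build_virtual_frame(c(1, 0, 0), c(0, 0, 0), 1)
  expect_equal(f2$G, rbind(c(0, 0, 1), c(0, -1, 0), c(-1, 0, 0)))
  # degenerate (vertical) normal falls back deterministically
  f3 <- build_virtual_frame(c(0, 1, 0), c(0, 0, 0), 1)
  expect_equal(f3$G[1, ], c(1, 0, 0))
  expect_lt(max(abs(f3$G %*% t(f3$G) - diag(3))), 1e-9)
  # orthonormality and unit determinant over random normals
  set.seed(3)
  n <- random_unit(1000)
  keep <- abs(n[, 2]) < 0.999  # outside the degenerate cone
  for (i in which(keep)[1:500]) {
    G <- build_virtual_frame(n[i, ], c(0, 0, 0), 1)$G
    expect_lt(max(abs(G %*% t(G) - diag(3))), 1e-9)
    expect_equal(abs(det(G)), 1, tolerance = 1e-9)
    # X row is horizontal
    expect_equal(G[1, 2], 0)
  }
})

test_that("object/virtual-frame transforms round-trip on the tangent plane", {
  set.seed(4)
  n <- c(0.48, 0.6, 0.64)
  V <- c(0.1, 1.2, -0.1)
  f <- build_virtual_frame(n, V, 2000)
  expect_equal(ocs_to_vcs(V, f), c(0, 0, 0))
  # along the outward normal: z_VCS = -t
  expect_equal(ocs_to_vcs(V + 0.05 * n, f), c(0, 0, -0.05),
               tolerance = 1e-12)
  p <- matrix(rnorm(300), ncol = 3)
  expect_lt(max(abs(vcs_to_ocs(ocs_to_vcs(p, f), f) - p)), 1e-12)
  # orthographic projection and its inverse
  expect_equal(ortho_project(c(0.01, -0.005, 0.42), 1000), c(10, -5))
  expect_equal(ortho_unproject(c(0, 0), f), V)
  q <- matrix(rnorm(200), ncol = 2) * 20
  round_trip <- ortho_project(ocs_to_vcs(ortho_unproject(q, f), f), f$s)
  expect_lt(max(abs(round_trip - q)), 1e-9)
  # unprojected points lie on the tangent plane
  pts <- ortho_unproject(q, f)
  expect_lt(max(abs(sweep(pts, 2, V) %*% n)), 1e-12)
})

test_that("barycentric decoding reproduces points in the triangle", {
  A <- c(0, 0, 0); B <- c(1, 0, 0); C <- c(0, 1, 0)
  expect_equal(barycentric_point(c(1, 0, 0), A, B, C), A)
  expect_equal(barycentric_point(c(1, 1, 1), A, B, C), (A + B + C) / 3)
  expect_equal(barycentric_point(c(0.5, 0.5, 0), A, B, C), c(0.5, 0, 0))
  expect_equal(barycentric_point(c(2, 4, 2), A, B, C),
               barycentric_point(c(1, 2, 1), A, B, C))
  expect_error(barycentric_point(c(0, 0, 0), A, B, C), "zero")
})

test_that("forward/inverse resampling chain is self-consistent to sub-1e-6 px", {
  pose <- rigid_pose(0.5, 1.1, 0.9)
  cal <- camera_calib(d = 2.5e-4, image_size = c(960, 720))
  n <- c(0.6, 0.16, -0.784)
  n <- n / sqrt(sum(n^2))
  V <- c(0.05, 1.1, -0.12)
  f <- build_virtual_frame(n, V, 1e4)
  q <- matrix(rnorm(400), ncol = 2) * 50
  p_ocs <- ortho_unproject(q, f)
  px <- project_pinhole(ocs_to_ccs(p_ocs, pose, cal), cal)
  # analytic inverse: intersect each pixel ray with the tangent plane
  O <- camera_center(pose, cal)
  d_ccs <- cbind((px[, 1] - cal$principal_point[1]) * cal$d,
                 (px[, 2] - cal$principal_point[2]) * cal$d, 1)
  dirs <- sweep(ccs_to_ocs(d_ccs, pose, cal), 2, O)
  tt <- as.numeric((V - O) %*% n) / as.numeric(dirs %*% n)
  hit <- sweep(dirs * tt, 2, -O)
  back <- ortho_project(ocs_to_vcs(hit, f), f$s)
  expect_lt(max(abs(back - q)), 1e-6)
})
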