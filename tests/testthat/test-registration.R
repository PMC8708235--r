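make_pair_scans <- function() {
  fixture("pair_scans", function() {
    set.seed(21)
    ph <- build_phantom(body_phantom_spec(), n_theta = 48, ring_step = 0.02)
    cal <- camera_calib(d = 0.002, image_size = c(960, 720))
    s1 <- cloud_to_ocs(virtual_depth_scan(ph, rigid_pose(0, 0.95, 1.2), cal, 0))
    s2 <- cloud_to_ocs(virtual_depth_scan(ph, rigid_pose(45, 0.95, 1.2,
                                                         degrees = TRUE),
                                          cal, 0))
    s1 <- estimate_normals(s1, 10, camera_center(s1$pose))
    s2 <- estimate_normals(s2, 10, camera_center(s2$pose))
    list(s1 = s1, s2 = s2)
  })
}

test_that("ICP is exact on self-registration and its residual never exceeds the start", {
  ps <- make_pair_scans()
  r <- icp_register(ps$s1, ps$s1)
  # acos saturates around 5e-6 deg for near-identity rotations
  expect_lt(rot_angle_deg(r$transform), 1e-4)
  expect_lt(trans_norm_mm(r$transform), 1e-4)
  expect_lt(r$rms, 1e-8)
  # descent: residual after convergence <= residual of the initial guess
  r2 <- icp_register(ps$s2, ps$s1, max_corr_dist = 0.03)
  src0 <- ps$s2$points
  nn0 <- dermascan:::cpp_knn(ps$s1$points, src0, 1L)
  rms0 <- sqrt(mean(nn0$dist[nn0$dist[, 1] <= 0.03, 1]^2))
  expect_lte(r2$rms, rms0)
})

test_that("ICP recovers a known rigid transform on a dense phantom scan", {
  # target = the same scan rotated 3 degrees about Y and shifted 2 cm
  ps <- make_pair_scans()
  M <- dermascan:::rt_make(dermascan:::so3_exp(c(0, 1, 0) * 3 * pi / 180),
                           c(0.02, 0, 0))
  tgt <- ps$s1
  tgt$points <- dermascan:::rt_apply(M, ps$s1$points)
  tgt$normals <- ps$s1$normals %*% t(M[1:3, 1:3])
  r <- icp_register(ps$s1, tgt, max_corr_dist = 0.03, max_iter = 80)
  E <- solve(M) %*% r$transform
  expect_lt(rot_angle_deg(E), 0.1)
  expect_lt(trans_norm_mm(E), 1.0)
  # and a cross-view recovery stays within a few correspondence spacings
  set.seed(22)
  ax <- random_unit(1)[1, ]
  M2 <- dermascan:::rt_make(dermascan:::so3_exp(ax * 3 * pi / 180),
                            c(0.012, -0.01, 0.008))
  s2p <- ps$s2
  s2p$points <- dermascan:::rt_apply(M2, ps$s2$points)
  s2p$normals <- ps$s2$normals %*% t(M2[1:3, 1:3])
  r2 <- icp_register(ps$s1, s2p, max_corr_dist = 0.03, max_iter = 80)
  E2 <- solve(M2) %*% r2$transform
  expect_lt(rot_angle_deg(E2), 0.15)
  expect_lt(trans_norm_mm(E2), 2.5)
})

test_that("ICP errors out when clouds do not overlap within the cap", {
  set.seed(23)
  a <- point_cloud(matrix(rnorm(300), ncol = 3))
  b <- point_cloud(matrix(rnorm(300), ncol = 3) + 10)
  expect_error(icp_register(a, b, max_corr_dist = 0.02), "overlap")
})

test_that("loop closure leaves a consistent cycle unchanged and absorbs drift", {
  mk <- function(ang, ax, t)
    dermascan:::rt_make(dermascan:::so3_exp(ax * ang), t)
  E <- list(mk(0.02, c(0, 1, 0), c(0.01, 0, 0)),
            mk(-0.01, c(1, 0, 0), c(0, 0.005, 0)),
            mk(0.015, c(0, 0, 1), c(0, 0, -0.01)))
  E[[4]] <- solve(E[[3]]) %*% solve(E[[2]]) %*% solve(E[[1]])
  lc <- close_loop(E)
  # consistent cycle: edges unchanged within 1e-8, residual ~ 0
  for (i in 1:4)
    expect_lt(max(abs(lc$transforms[[i]] - E[[i]])), 1e-7)
  expect_lt(lc$residual, 1e-12)
  # objective never increases
  expect_lte(lc$residual, lc$residual0)
  # inject 2 degrees of drift into one edge
  E2 <- E
  E2[[2]] <- mk(2 * pi / 180, c(0, 1, 0), c(0, 0, 0)) %*% E2[[2]]
  lc2 <- close_loop(E2)
  cc <- compose_cycle(lc2$transforms)
  expect_lt(rot_angle_deg(cc), 0.2)
  expect_lt(trans_norm_mm(cc), 0.1)
  expect_lte(lc2$residual, lc2$residual0)
})

test_that("ring registration with loop closure composes to the identity", {
  set.seed(24)
  ph <- build_phantom(body_phantom_spec(), n_theta = 48, ring_step = 0.03)
  cal <- camera_calib(d = 0.005, image_size = c(384, 288))
  rig <- make_rig(camera_heights = numeric(0), scanner_heights = 0.95,
                  n_angles = 8, scanner_calib = cal)
  ses <- generate_session(ph, rig, noise_sigma = 0, photos = FALSE, seed = 3)
  ses <- perturb_session(ses, 2, 0.01, seed = 4)
  clouds <- lapply(ses$scans, function(s) {
    cl <- cloud_to_ocs(s)
    estimate_normals(cl, 10, camera_center(cl$pose))
  })
  rr <- register_ring(clouds, caps = c(0.03, 0.008))
  cc <- compose_cycle(rr$edges)
  expect_lt(rot_angle_deg(cc), 1e-4)
  expect_lt(trans_norm_mm(cc), 1e-6)
  expect_equal(rr$poses[[1]], diag(4))
})
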