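test_that("the phantom torso is watertight with a correct marker chart", {
  mk <- data.frame(psi_deg = c(0, 40), y = c(0.9, 1.1))
  ph <- build_phantom(phantom_spec(markers = mk), n_theta = 48,
                      ring_step = 0.04)
  expect_true(is_watertight(ph$mesh))
  expect_equal(euler_characteristic(ph$mesh), 2)
  m <- ph$markers[[1]]
  # marker center lies on the surface with a unit outward normal
  expect_lt(point_mesh_distance(ph$mesh, matrix(m$center, 1, 3)), 1e-3)
  expect_equal(sqrt(sum(m$normal^2)), 1, tolerance = 1e-9)
  expect_gt(sum(m$normal * (m$center - c(0, m$y, 0))), 0)
  # texture paints marker color iff the chart distance is below d/2
  eps <- 5e-4
  u_in <- ph$arc$arc(m$psi) + m$diameter_m / 2 - eps
  u_out <- ph$arc$arc(m$psi) + m$diameter_m / 2 + eps
  p_in <- ph$surface_point(ph$arc$inv(u_in), m$y)
  p_out <- ph$surface_point(ph$arc$inv(u_out), m$y)
  expect_equal(as.numeric(ph$texture_fn(p_in)), c(0.05, 0.05, 0.05))
  expect_false(all(ph$texture_fn(p_out) == 0.05))
  # vertical chart direction too
  p_in2 <- ph$surface_point(m$psi, m$y + m$diameter_m / 2 - eps)
  expect_equal(as.numeric(ph$texture_fn(p_in2)), c(0.05, 0.05, 0.05))
  # overlapping markers are rejected
  expect_error(build_phantom(phantom_spec(markers = data.frame(
    psi_deg = c(0, 2), y = c(1, 1)))), "overlap")
})

test_that("virtual photographs obey pinhole magnification and foreshortening", {
  mk <- data.frame(psi_deg = 0, y = 1.0)
  ph <- build_phantom(phantom_spec(markers = mk), n_theta = 96,
                      ring_step = 0.02)
  cal <- camera_calib(d = 2.5e-4, image_size = c(720, 720))
  pose <- rigid_pose(0, 1.0, 0.9)
  v <- virtual_photograph(ph, pose, cal, id = 7L)
  expect_equal(v$pose$alpha, 0)
  expect_equal(v$id, 7L)
  # frontal disk image: a circle of diameter d / (d_C * z) px
  m <- ph$markers[[1]]
  z <- ocs_to_ccs(m$center, pose, cal)[3]
  want_px <- m$diameter_m / (cal$d * z)
  pc <- project_pinhole(ocs_to_ccs(m$center, pose, cal), cal)
  Wc <- 160
  crop <- v$image[(round(pc[2]) - Wc):(round(pc[2]) + Wc) + 1,
                  (round(pc[1]) - Wc):(round(pc[1]) + Wc) + 1, ,
                  drop = FALSE]
  fit <- fit_ellipse(segment_marker(crop, center = c(Wc, Wc)))
  expect_lt(abs(2 * fit$a - want_px) / want_px, 0.03)
  expect_lt(abs(fit$ratio - 1), 0.03)
})

test_that("a marker at 60 degrees incidence images with axis ratio near 2", {
  mk <- data.frame(psi_deg = 0, y = 1.0)
  ph <- build_phantom(phantom_spec(markers = mk), n_theta = 96,
                      ring_step = 0.02)
  cal <- camera_calib(d = 2.5e-4, image_size = c(1440, 960))
  # rotate the arm until the ray-to-normal incidence at the marker is
  # closest to 60 degrees (the incidence is pure geometry, independent of
  # the imaging path under test)
  m <- ph$markers[[1]]
  incidence <- function(al) {
    O <- camera_center(rigid_pose(al, 1.0, 0.9, degrees = TRUE), cal)
    ray <- (m$center - O)
    ray <- ray / sqrt(sum(ray^2))
    acos(abs(sum(ray * m$normal))) * 180 / pi
  }
  grid <- seq(-70, -20, by = 0.5)
  al <- grid[which.min(abs(vapply(grid, incidence, 1) - 60))]
  pose <- rigid_pose(al, 1.0, 0.9, degrees = TRUE)
  inc <- incidence(al)
  expect_gt(inc, 55)
  expect_lt(inc, 65)
  v <- virtual_photograph(ph, pose, cal)
  pc <- project_pinhole(ocs_to_ccs(m$center, pose, cal), cal)
  Wc <- 140
  crop <- v$image[(round(pc[2]) - Wc):(round(pc[2]) + Wc) + 1,
                  (round(pc[1]) - Wc):(round(pc[1]) + Wc) + 1, ,
                  drop = FALSE]
  fit <- fit_ellipse(segment_marker(crop, center = c(Wc, Wc)))
  expect_lt(abs(fit$ratio - 1 / cos(inc * pi / 180)), 0.09 * fit$ratio)
})

test_that("virtual depth scans sample the true surface with the requested noise", {
  ph <- small_phantom()
  cal <- default_scanner_calib()
  pose <- rigid_pose(45, 0.95, 1.2, degrees = TRUE)
  clean <- virtual_depth_scan(ph, pose, cal, noise_sigma = 0)
  expect_equal(clean$cs, "DCS")
  ocs <- dcs_to_ocs(clean$points, clean$pose)
  expect_lt(max(point_mesh_distance(ph$mesh, ocs)), 1e-9)
  # noise model self-check: the noise acts along the ray, so the
  # point-to-surface distance matches sigma at near-normal incidence
  cal2 <- camera_calib(d = 0.0018, image_size = c(840, 630))
  O <- camera_center(pose)
  ref <- estimate_normals(cloud_to_ocs(
    virtual_depth_scan(ph, pose, cal2, noise_sigma = 0)), 15, O)
  to_cam <- sweep(-ref$points, 2, -O)
  cos_inc <- abs(rowSums(ref$normals * to_cam /
                           sqrt(rowSums(to_cam^2))))
  noisy <- virtual_depth_scan(ph, pose, cal2, noise_sigma = 0.002, seed = 9)
  expect_gt(n_points(noisy), 7e4)
  d <- point_mesh_distance(ph$mesh, dcs_to_ocs(noisy$points, pose))
  keep <- cos_inc > 0.95
  expect_gt(sum(keep), 1e4)
  expect_lt(abs(sqrt(mean(d[keep]^2)) - 0.002) / 0.002, 0.1)
  # dropout and determinism
  drop <- virtual_depth_scan(ph, pose, cal, noise_sigma = 0, dropout = 0.5,
                             seed = 10)
  expect_lt(n_points(drop), n_points(clean) * 0.6)
  again <- virtual_depth_scan(ph, pose, cal, noise_sigma = 0.002, seed = 11)
  again2 <- virtual_depth_scan(ph, pose, cal, noise_sigma = 0.002, seed = 11)
  expect_identical(again$points, again2$points)
})

test_that("sessions follow the 45-degree protocol and perturb reproducibly", {
  ph <- small_phantom()
  rig <- make_rig(camera_heights = numeric(0), scanner_heights = 0.95,
                  n_angles = 8,
                  scanner_calib = camera_calib(d = 0.01,
                                               image_size = c(80, 60)))
  expect_equal(vapply(rig$scanners, function(s) s$pose$alpha, 1) * 180 / pi,
               seq(0, 315, by = 45))
  ses <- generate_session(ph, rig, noise_sigma = 0.001, photos = FALSE,
                          seed = 12)
  expect_length(ses$scans, 8)
  expect_true(all(vapply(ses$perturbations, function(P)
    identical(P, diag(4)), TRUE)))
  # zero bounds: identity perturbations
  z <- perturb_session(ses, 0, 0, seed = 13)
  for (P in z$perturbations) {
    expect_lt(rot_angle_deg(P), 1e-9)
    expect_lt(trans_norm_mm(P), 1e-9)
  }
  p1 <- perturb_session(ses, 2, 0.01, seed = 14)
  p2 <- perturb_session(ses, 2, 0.01, seed = 14)
  expect_identical(p1$perturbations, p2$perturbations)
  expect_identical(p1$scans[[3]]$points, p2$scans[[3]]$points)
  for (P in p1$perturbations) {
    expect_lte(rot_angle_deg(P), 2)
    expect_lte(trans_norm_mm(P), 10)
  }
  # the perturbation is exactly what separates the scan from ground truth
  ocs_p <- dcs_to_ocs(p1$scans[[3]]$points, p1$scans[[3]]$pose)
  ocs_0 <- dcs_to_ocs(ses$scans[[3]]$points, ses$scans[[3]]$pose)
  back <- dermascan:::rt_apply(solve(p1$perturbations[[3]]), ocs_p)
  expect_lt(max(abs(back - ocs_0)), 1e-9)
})
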