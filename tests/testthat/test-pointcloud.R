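test_that("subject cropping keeps the closed box and preserves order", {
  b <- subject_bounds(c(-1, 0, -1), c(1, 2, 1))
  inside <- matrix(runif(30, -0.9, 0.9), ncol = 3)
  inside[, 2] <- inside[, 2] + 1
  cl <- point_cloud(inside, cs = "OCS")
  expect_equal(crop_to_subject(cl, b)$points, cl$points)
  # boundary point retained (closed box)
  edge <- rbind(c(1, 0, 1), c(-1, 2, -1))
  cl2 <- point_cloud(edge, cs = "OCS")
  expect_equal(nrow(crop_to_subject(cl2, b)$points), 2L)
  # counting: 10 inside + 5 outside
  outside <- cbind(runif(5, 1.5, 3), runif(5, 0, 2), runif(5, -0.9, 0.9))
  cl3 <- point_cloud(rbind(inside[1:10, ], outside), cs = "OCS")
  cropped <- crop_to_subject(cl3, b)
  expect_equal(cropped$points, inside[1:10, ])
  # empty result warns
  cl4 <- point_cloud(matrix(5, 1, 3), cs = "OCS")
  expect_warning(crop_to_subject(cl4, b), "no points")
  # DCS clouds are rejected
  expect_error(crop_to_subject(point_cloud(inside, cs = "DCS"), b), "OCS")
})

test_that("voxel downsampling averages voxel members", {
  cl <- point_cloud(rbind(c(0.01, 0, 0), c(0.02, 0, 0)))
  out <- voxel_downsample(cl, 0.1)
  expect_equal(out$points, matrix(c(0.015, 0, 0), 1, 3))
  # voxel below minimal gap: identity up to reordering
  set.seed(5)
  p <- matrix(runif(90), ncol = 3)
  out2 <- voxel_downsample(point_cloud(p), 1e-5)
  expect_equal(nrow(out2$points), nrow(p))
  expect_equal(out2$points[order(out2$points[, 1]), ],
               p[order(p[, 1]), ])
  # brute-force bucketing oracle
  voxel <- 0.23
  key <- paste(floor(p[, 1] / voxel), floor(p[, 2] / voxel),
               floor(p[, 3] / voxel))
  expected <- do.call(rbind, lapply(split(seq_len(nrow(p)), key), function(i)
    colMeans(p[i, , drop = FALSE])))
  got <- voxel_downsample(point_cloud(p), voxel)$points
  expect_equal(nrow(got), nrow(expected))
  o1 <- got[order(got[, 1], got[, 2]), ]
  o2 <- expected[order(expected[, 1], expected[, 2]), ]
  dimnames(o2) <- NULL
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("normal estimation recovers plane and sphere normals, oriented to the viewpoint", {
  set.seed(6)
  p <- cbind(runif(400, -1, 1), runif(400, -1, 1), 0)
  up <- estimate_normals(point_cloud(p), k = 10, viewpoint = c(0, 0, 5))
  expect_lt(max(abs(sweep(up$normals, 2, c(0, 0, 1)))), 1e-6)
  dn <- estimate_normals(point_cloud(p), k = 10, viewpoint = c(0, 0, -5))
  expect_lt(max(abs(sweep(dn$normals, 2, c(0, 0, -1)))), 1e-6)
  # sphere: normals within 5 degrees of radial for k = 10, n = 2000
  # (quasi-uniform Fibonacci sampling)
  n <- 2000
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  u <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  sp <- estimate_normals(point_cloud(u), k = 10, viewpoint = 2 * u)
  ang <- acos(pmin(1, rowSums(sp$normals * u))) * 180 / pi
  expect_lt(max(ang), 5)
  expect_error(estimate_normals(point_cloud(u[1:5, ]), k = 10),
               "fewer than k")
})

test_that("statistical outlier removal drops loose points only", {
  # grid spacing 0.125 is exactly representable, so neighbor distances tie
  g <- as.matrix(expand.grid(x = seq(0, 1, 0.125), y = seq(0, 1, 0.125),
                             z = 0))
  far <- c(0.5, 0.5, 1)
  cl <- point_cloud(rbind(g, far))
  out <- remove_outliers(cl, k = 8, std_mult = 1)
  expect_equal(nrow(out$points), nrow(g))
  expect_false(any(out$points[, 3] == 1))
  # regular grid with k = 1: all nearest-neighbor distances equal, zero
  # variance, nothing removed
  reg <- remove_outliers(point_cloud(g), k = 1, std_mult = 1)
  expect_equal(nrow(reg$points), nrow(g))
  # subset property
  set.seed(7)
  p <- matrix(rnorm(600), ncol = 3)
  out2 <- remove_outliers(point_cloud(p), k = 10, std_mult = 0.5)
  expect_lte(nrow(out2$points), nrow(p))
  keys <- apply(out2$points, 1, paste, collapse = ",")
  expect_true(all(keys %in% apply(p, 1, paste, collapse = ",")))
})

test_that("crop, downsample and outlier removal never increase point counts", {
  set.seed(8)
  p <- matrix(rnorm(3000, sd = 0.3), ncol = 3)
  cl <- point_cloud(p, cs = "OCS")
  b <- subject_bounds(c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5))
  c1 <- crop_to_subject(cl, b)
  c2 <- voxel_downsample(c1, 0.05)
  c3 <- remove_outliers(c2, k = 8)
  expect_lte(n_points(c1), n_points(cl))
  expect_lte(n_points(c2), n_points(c1))
  expect_lte(n_points(c3), n_points(c2))
})
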