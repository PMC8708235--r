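plane_view <- function(alpha_deg = 0, h = 1.0, r = 1.2, size = 0.3,
                       img = c(512, 512), d = 2.5e-4, tilt_deg = 0) {
  pp <- plane_phantom(center = c(0, 1, -0.11), size = size,
                      tilt_deg = tilt_deg)
  cal <- camera_calib(d = d, image_size = img)
  pose <- rigid_pose(alpha_deg, h, r, degrees = TRUE)
  view <- virtual_photograph(pp, pose, cal, id = 1L)
  list(pp = pp, view = view)
}

test_that("a frontal 20 mm disk rectifies to its true pixel diameter", {
  s <- plane_view()
  anchor <- list(triangle = 1L,
                 V = s$pp$center)
  patch <- orthorectify(s$view, s$pp$mesh, anchor, s = 10,
                        size = c(400, 400), normal = s$pp$normal)
  mask <- segment_marker(patch)
  fit <- fit_ellipse(mask)
  expect_lt(abs(2 * fit$a - 200), 1)   # 20 mm at 10 px/mm
  expect_lt(abs(2 * fit$b - 200), 1)
  expect_lt(abs(fit$ratio - 1), 0.01)
  # center pixel color equals the bilinear sample at V's projection
  pxV <- project_pinhole(ocs_to_ccs(s$pp$center, s$view$pose,
                                    s$view$calib), s$view$calib)
  want <- dermascan:::sample_image(s$view$image, pxV[1], pxV[2])
  ctr <- patch$image[round(patch$center[2]) + 1, round(patch$center[1]) + 1, ]
  expect_equal(as.numeric(ctr), as.numeric(want), tolerance = 1e-9)
})

test_that("rectification undoes 60-degree foreshortening of the disk", {
  # plane tilted 60 degrees about the vertical axis, camera frontal
  s <- plane_view(tilt_deg = 60)
  # source-image disk has axis ratio ~ 1/cos(60) = 2
  pc <- project_pinhole(ocs_to_ccs(s$pp$center, s$view$pose, s$view$calib),
                        s$view$calib)
  W <- 120
  r0 <- max(0, round(pc[2]) - W)
  r1 <- min(511, round(pc[2]) + W)
  c0 <- max(0, round(pc[1]) - W)
  c1 <- min(511, round(pc[1]) + W)
  crop <- s$view$image[(r0:r1) + 1, (c0:c1) + 1, , drop = FALSE]
  src_fit <- fit_ellipse(segment_marker(crop, center = c(pc[1] - c0,
                                                         pc[2] - r0)))
  expect_gt(src_fit$ratio, 1.8)
  patch <- orthorectify(s$view, s$pp$mesh, list(triangle = 1L,
                                                V = s$pp$center),
                        s = 10, size = c(400, 400), normal = s$pp$normal)
  fit <- fit_ellipse(segment_marker(patch))
  expect_lt(abs(fit$ratio - 1), 0.02)
})

test_that("patch resampling equals the closed-form plane homography below 0.5 px", {
  s <- plane_view(alpha_deg = 40)
  frame <- build_virtual_frame(s$pp$normal, s$pp$center, 10 * 1000)
  W <- 300
  cx <- (W - 1) / 2
  # chain mapping for every patch pixel
  xg <- rep(0:(W - 1), each = W) - cx
  yg <- rep(0:(W - 1), times = W) - cx
  chain <- project_pinhole(ocs_to_ccs(ortho_unproject(cbind(xg, yg), frame),
                                      s$view$pose, s$view$calib),
                           s$view$calib)
  # closed-form homography fitted from 4 corner correspondences only (DLT)
  cr <- rbind(c(-cx, -cx), c(cx, -cx), c(cx, cx), c(-cx, cx))
  crt <- project_pinhole(ocs_to_ccs(ortho_unproject(cr, frame),
                                    s$view$pose, s$view$calib), s$view$calib)
  A <- NULL
  for (i in 1:4) {
    x <- cr[i, 1]; y <- cr[i, 2]; u <- crt[i, 1]; v <- crt[i, 2]
    A <- rbind(A,
               c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u),
               c(0, 0, 0, x, y, 1, -v * x, -v * y, -v))
  }
  H <- matrix(eigen(crossprod(A))$vectors[, 9], 3, 3, byrow = TRUE)
  den <- H[3, 1] * xg + H[3, 2] * yg + H[3, 3]
  hx <- (H[1, 1] * xg + H[1, 2] * yg + H[1, 3]) / den
  hy <- (H[2, 1] * xg + H[2, 2] * yg + H[2, 3]) / den
  err <- sqrt((hx - chain[, 1])^2 + (hy - chain[, 2])^2)
  expect_lt(max(err), 0.5)
})

test_that("doubling the patch scale doubles imaged structure size", {
  s <- plane_view()
  anchor <- list(triangle = 1L, V = s$pp$center)
  p1 <- orthorectify(s$view, s$pp$mesh, anchor, s = 5, size = c(240, 240),
                     normal = s$pp$normal)
  p2 <- orthorectify(s$view, s$pp$mesh, anchor, s = 10, size = c(480, 480),
                     normal = s$pp$normal)
  a1 <- fit_ellipse(segment_marker(p1))$a
  a2 <- fit_ellipse(segment_marker(p2))$a
  expect_lt(abs(a2 / a1 - 2), 0.02)
})

test_that("samples outside the source image are masked invalid", {
  s <- plane_view(img = c(128, 128), d = 2e-3)
  # huge patch far beyond the plane and the image
  patch <- orthorectify(s$view, s$pp$mesh, list(triangle = 1L,
                                                V = s$pp$center),
                        s = 2, size = c(900, 900), normal = s$pp$normal)
  expect_true(any(!patch$valid_mask))
  expect_true(any(patch$valid_mask))
  # fully invalid patch: the anchor sits behind this camera
  behind <- camera_view(rigid_pose(0, 1.0, 0.05), s$view$calib,
                        image = s$view$image)
  expect_warning(
    orthorectify(behind, s$pp$mesh, list(triangle = 1L, V = s$pp$center),
                 s = 10, size = c(50, 50), normal = s$pp$normal),
    "invalid")
})

test_that("ground-truth landmarks transfer into patch coordinates analytically", {
  s <- plane_view(alpha_deg = 25)
  patch <- orthorectify(s$view, s$pp$mesh, list(triangle = 1L,
                                                V = s$pp$center),
                        s = 10, size = c(400, 400), normal = s$pp$normal)
  # a point 10 mm along +x on the plane must land 100 px right of center
  p3 <- s$pp$center + c(0.01, 0, 0)
  px <- project_pinhole(ocs_to_ccs(p3, s$view$pose, s$view$calib),
                        s$view$calib)
  loc <- ortho_locate(patch, s$view, px)
  expect_equal(loc[1] - patch$center[1], 100, tolerance = 0.01)
  expect_equal(loc[2] - patch$center[2], 0, tolerance = 0.01)
})
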