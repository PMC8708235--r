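single_tri_view <- function() {
  # one front-facing triangle 1 m in front of a camera at the origin pose
  mesh <- tri_mesh(rbind(c(-0.3, 0.7, -0.3), c(0, 0.7, 0.6),
                         c(0.3, 1.6, -0.3)),
                   matrix(c(1, 3, 2), 1))
  pose <- rigid_pose(0, 1.0, 1.5)
  cal <- camera_calib(d = 8e-3, image_size = c(64, 64))
  list(mesh = mesh, view = camera_view(pose, cal, id = 1L))
}

test_that("index mosaic covers the projected triangle and culls back faces", {
  s <- single_tri_view()
  buf <- render_mosaic(s$mesh, s$view)
  expect_equal(buf$index[32, 32], 1L)
  expect_equal(buf$index[1, 1], 0L)
  expect_true(all(buf$depth[buf$index > 0] > 0))
  # flipping the winding makes it back-facing: nothing rendered
  flipped <- tri_mesh(s$mesh$vertices, s$mesh$triangles[, c(1, 3, 2)])
  buf2 <- render_mosaic(flipped, s$view)
  expect_equal(sum(buf2$index), 0L)
})

test_that("z-buffer resolves occlusion toward the nearer triangle", {
  # two stacked triangles, the second 0.5 m closer to the camera
  V <- rbind(c(-0.4, 0.6, 0), c(0.4, 0.6, 0), c(0, 1.6, 0),
             c(-0.4, 0.6, -0.5), c(0.4, 0.6, -0.5), c(0, 1.6, -0.5))
  mesh <- tri_mesh(V, rbind(c(1, 3, 2), c(4, 6, 5)))
  pose <- rigid_pose(0, 1.0, 2)
  cal <- camera_calib(d = 8e-3, image_size = c(64, 64))
  buf <- render_mosaic(mesh, camera_view(pose, cal))
  covered <- buf$index[buf$index > 0]
  expect_true(all(covered == 2L))
})

test_that("rasterized indices and barycentrics agree with a ray-casting oracle", {
  ph <- small_phantom()
  pose <- rigid_pose(30, 0.95, 1.6, degrees = TRUE)
  cal <- camera_calib(d = 9e-3, image_size = c(64, 64))
  view <- camera_view(pose, cal)
  buf <- render_mosaic(ph$mesh, view)
  rays <- view_rays(pose, cal)
  orc <- raycast_oracle(ph$mesh, rays$origin, rays$dirs)
  oracle <- matrix(0L, 64, 64)
  oracle[cbind(rays$yt + 1, rays$xt + 1)] <- orc$tri
  expect_true(any(oracle > 0) && any(oracle == 0))
  expect_gt(mean(buf$index == oracle), 0.995)  # silhouette-pixel slack
  # reconstructing the surface point from the barycentric buffer and
  # reprojecting returns the pixel center within 0.51 px
  sp <- buffer_surface_points(buf, ph$mesh)
  px <- project_pinhole(ocs_to_ccs(sp$points, pose, cal), cal)
  err <- sqrt(rowSums((px - sp$pixels)^2))
  expect_lt(max(err), 0.51)
})

test_that("rendering is bit-reproducible", {
  s <- single_tri_view()
  b1 <- render_mosaic(s$mesh, s$view)
  b2 <- render_mosaic(s$mesh, s$view)
  expect_identical(b1$index, b2$index)
  expect_identical(b1$bary, b2$bary)
  expect_identical(b1$depth, b2$depth)
})

test_that("index ids encode and decode exactly through 24-bit RGB", {
  ids <- c(0L, 1L, 255L, 256L, 65535L, 65536L, 2^24 - 1L,
           sample.int(2^24 - 1, 500))
  expect_equal(decode_index_rgb(encode_index_rgb(ids)), ids)
})

test_that("shaded rendering paints surface colors at perspective-correct points", {
  s <- single_tri_view()
  img <- render_shaded(s$mesh, s$view, function(p)
    matrix(0.5, nrow(p), 3), background = c(0, 0, 0))
  buf <- render_mosaic(s$mesh, s$view)
  fg <- buf$index > 0
  expect_true(all(img[, , 1][fg] == 0.5))
  expect_true(all(img[, , 1][!fg] == 0))
  # checkerboard on a frontal quad: colors match the analytic pattern away
  # from cell borders (1 px aliasing band)
  pp <- plane_phantom(center = c(0, 1, -0.4), size = 0.4)
  pose <- rigid_pose(0, 1.0, 1.2)
  cal <- camera_calib(d = 1.2e-3, image_size = c(128, 128))
  view <- camera_view(pose, cal)
  img2 <- render_shaded(pp$mesh, view, pp$texture_fn)
  buf2 <- render_mosaic(pp$mesh, view)
  sp <- buffer_surface_points(buf2, pp$mesh)
  want <- pp$texture_fn(sp$points)
  got <- cbind(img2[, , 1][buf2$index > 0], img2[, , 2][buf2$index > 0],
               img2[, , 3][buf2$index > 0])
  expect_gt(mean(rowSums(abs(got - want)) < 1e-9), 0.97)
})

test_that("render buffers export to PNG and read back faithfully", {
  s <- single_tri_view()
  buf <- render_mosaic(s$mesh, s$view)
  tmp <- file.path(tempdir(), "buf")
  write_render_buffers(buf, tmp)
  idx <- read_index_png(paste0(tmp, "_index.png"))
  expect_equal(idx, unname(buf$index))
  bary16 <- read_image(paste0(tmp, "_bary.png"))
  fg <- buf$index > 0
  for (ch in 1:3)
    expect_lt(max(abs(bary16[, , ch][fg] - buf$bary[, , ch][fg])), 1e-4)
})

test_that("orthographic rendering picks the near surface seen along the frame axis", {
  ph <- small_phantom()
  f <- build_virtual_frame(c(0, 0, -1), c(0, 1.0, -0.11), 2000)
  ov <- ortho_view(f, size = c(64, 64))
  buf <- render_mosaic(ph$mesh, ov)
  expect_gt(sum(buf$index > 0), 2000)
  p <- pick(c(32, 32), buf, ph$mesh)
  # picked point lies near the front surface around the anchor
  expect_lt(sqrt(sum((p$V - f$V)[1:2]^2)), 0.05)
})
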