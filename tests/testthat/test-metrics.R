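raster_disk <- function(H, W, cx, cy, r, bg = 0.9, fg = 0.05) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  img <- matrix(bg, H, W)
  img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- fg
  img
}

raster_ellipse <- function(H, W, cx, cy, a, b, theta = 0) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - cx
  ys <- matrix(rep(0:(H - 1), times = W), H, W) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  img <- matrix(0.9, H, W)
  img[(u / a)^2 + (v / b)^2 <= 1] <- 0.05
  img
}

test_that("marker segmentation isolates the center-touching dark component", {
  img <- raster_disk(301, 301, 150, 150, 100)
  mask <- segment_marker(img)
  expect_lt(abs(sum(mask) - pi * 100^2) / (pi * 100^2), 0.01)
  # a detached dark speck is excluded
  img2 <- img
  img2[10:14, 10:14] <- 0.05
  mask2 <- segment_marker(img2)
  expect_false(any(mask2[10:14, 10:14]))
  # threshold equals the exhaustive between-class-variance maximizer
  set.seed(51)
  noisy <- pmin(pmax(img + rnorm(length(img), 0, 0.05), 0), 1)
  eb <- EBImage::Image(t(noisy))
  got_thr <- EBImage::otsu(eb, range = c(0, 1), levels = 256)
  breaks <- seq(0, 1, length.out = 257)
  mids <- (breaks[-1] + breaks[-257]) / 2
  counts <- as.numeric(hist(noisy, breaks = breaks, plot = FALSE)$counts)
  v <- rep(NA_real_, 255)
  for (k in 1:255) {
    w0 <- sum(counts[1:k])
    w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
    v[k] <- w0 * w1 * (m0 - m1)^2
  }
  # the objective plateaus across empty gray-level gaps: the maximizing
  # set is an interval, and the convention is its midpoint
  top <- which(v >= max(v, na.rm = TRUE) * (1 - 1e-12))
  best_t <- (mids[min(top)] + mids[max(top)]) / 2
  expect_lt(abs(got_thr - best_t), 1.5 / 255)
  # no dark component at all
  expect_error(segment_marker(matrix(1, 50, 50)), "no dark")
})

test_that("moment ellipse fitting recovers axes, ratio and rotation invariance", {
  circ <- segment_marker(raster_disk(301, 301, 150, 150, 100))
  fc <- fit_ellipse(circ)
  expect_lt(abs(fc$ratio - 1), 0.01)
  expect_lt(abs(fc$a - 100) / 100, 0.01)
  ell <- segment_marker(raster_ellipse(301, 301, 150, 150, 100, 50))
  fe <- fit_ellipse(ell)
  expect_lt(abs(fe$ratio - 2) / 2, 0.02)
  rot <- segment_marker(raster_ellipse(301, 301, 150, 150, 100, 50, 0.6))
  fr <- fit_ellipse(rot)
  expect_lt(abs(fr$ratio - fe$ratio) / fe$ratio, 0.01)
  expect_error(fit_ellipse(matrix(FALSE, 5, 5)), "empty")
})

test_that("marker areas convert pixel counts to physical units", {
  # disk of radius 10 mm at 10 px/mm
  mask <- raster_disk(301, 301, 150, 150, 100) < 0.5
  expect_lt(abs(marker_area(mask, 10) - pi) / pi, 0.015)
  expect_equal(marker_area(matrix(FALSE, 5, 5), 10), 0)
  # doubling the scale leaves the physical area unchanged
  mask2 <- raster_disk(601, 601, 300, 300, 200) < 0.5
  expect_lt(abs(marker_area(mask2, 20) - marker_area(mask, 10)) / pi, 0.01)
})

test_that("shear angle measures the deviation from a right angle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(shear_angle(sq), 0)
  th <- 15 * pi / 180
  par <- rbind(c(0, 0), c(1, 0), c(1, 0) + c(sin(th), cos(th)),
               c(sin(th), cos(th)))
  expect_equal(shear_angle(par), 15, tolerance = 1e-9)
  expect_equal(shear_angle(par * 3.7), 15, tolerance = 1e-9)
  degen <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))
  expect_error(shear_angle(degen), "collinear")
})

test_that("aggregate reports carry means and relative standard deviations", {
  m <- data.frame(marker = 1, condition = "original", angle_deg = 5,
                  ratio = 1.2, area_cm2 = 3)
  rep1 <- aggregate_report(m)
  expect_equal(rep1$table$mean, c(5, 1.2, 3))
  expect_equal(rep1$table$rel_sd, c(0, 0, 0))
  m2 <- data.frame(marker = 1:2, condition = "original",
                   area_cm2 = c(8, 12))
  rep2 <- aggregate_report(m2)
  expect_equal(rep2$table$mean, 10)
  expect_equal(rep2$table$rel_sd, sd(c(8, 12)) / 10)
  m3 <- data.frame(marker = 1:3, condition = "orthorectified",
                   ratio = c(1, 1, 1))
  rep3 <- aggregate_report(m3)
  expect_equal(rep3$table$rel_sd, 0)
  # CSV/JSON export
  tmp <- file.path(tempdir(), "report")
  write_report(rep2, tmp)
  expect_true(file.exists(paste0(tmp, ".csv")))
  expect_true(file.exists(paste0(tmp, ".json")))
})
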