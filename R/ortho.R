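# Local orthorectification of skin-image patches on the surface tangent
# plane.

# bilinear (or bicubic via Catmull-Rom) sampling of an H x W x C image at
# fractional pixel coords (0-based). Out-of-bounds queries return NA.
sample_image <- function(img, x, y, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  H <- dim(img)[1]
  W <- dim(img)[2]
  C <- if (length(dim(img)) == 3) dim(img)[3] else 1
  if (C == 1) img <- array(img, dim = c(H, W, 1))
  n <- length(x)
  out <- matrix(NA_real_, n, C)
  if (method == "bilinear") {
    ok <- !is.na(x) & !is.na(y) & x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
    if (!any(ok)) return(out)
    xs <- pmin(pmax(x[ok], 0), W - 1 - 1e-9)
    ys <- pmin(pmax(y[ok], 0), H - 1 - 1e-9)
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0;   fy <- ys - y0
    i00 <- y0 + 1 + H * x0
    i10 <- i00 + H        # x0+1
    i01 <- i00 + 1        # y0+1
    i11 <- i10 + 1
    for (ch in seq_len(C)) {
      plane <- img[, , ch]
      out[ok, ch] <- plane[i00] * (1 - fx) * (1 - fy) +
        plane[i10] * fx * (1 - fy) +
        plane[i01] * (1 - fx) * fy +
        plane[i11] * fx * fy
    }
  } else {
    # Catmull-Rom bicubic; needs a 4x4 support, clamped at borders
    ok <- !is.na(x) & !is.na(y) & x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
    if (!any(ok)) return(out)
    xs <- x[ok]; ys <- y[ok]
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0;   fy <- ys - y0
    wcr <- function(f) {
      f2 <- f * f; f3 <- f2 * f
      cbind(-0.5 * f3 + f2 - 0.5 * f,
            1.5 * f3 - 2.5 * f2 + 1,
            -1.5 * f3 + 2 * f2 + 0.5 * f,
            0.5 * f3 - 0.5 * f2)
    }
    wx <- wcr(fx); wy <- wcr(fy)
    for (ch in seq_len(C)) {
      plane <- img[, , ch]
      acc <- numeric(sum(ok))
      for (dy in -1:2) {
        rowi <- pmin(pmax(y0 + dy, 0), H - 1)
        rowacc <- numeric(sum(ok))
        for (dx in -1:2) {
          coli <- pmin(pmax(x0 + dx, 0), W - 1)
          rowacc <- rowacc + wx[, dx + 2] * plane[rowi + 1 + H * coli]
        }
        acc <- acc + wy[, dy + 2] * rowacc
      }
      out[ok, ch] <- acc
    }
  }
  out
}

#' Orthorectify an image patch around a surface point
#'
#' Resamples the source photograph onto the tangent plane at the anchor
#' point `V`, seen frontally by a virtual orthographic camera, so that the
#' patch has uniform physical scale (`s` pixels per millimeter). For every
#' output pixel, the corresponding tangent-plane point is back-projected
#' ([ortho_unproject()]), transformed into the source camera
#' ([ocs_to_ccs()]), projected ([project_pinhole()]) and the source color
#' interpolated there. The local planar approximation degrades with patch
#' size on curved anatomy; the default physical extent is capped at
#' 40 x 40 mm.
#'
#' @param view The source [camera_view()] carrying the image.
#' @param mesh The body [tri_mesh()].
#' @param anchor Either a list as returned by [pick()] (fields `triangle`,
#'   `V`), or a triangle id (the anchor is then the triangle centroid).
#' @param s Patch scale in pixels per millimeter.
#' @param size `c(width, height)` of the patch in pixels. The anchor maps
#'   to pixel `(size - 1) / 2` (the exact center pixel for odd sizes, the
#'   half-pixel center for even ones).
#' @param normal Anchor surface normal; defaults to the anchor triangle's
#'   face normal.
#' @param interp `"bilinear"` (default) or `"bicubic"`.
#' @param buffers Optional [render_mosaic()] buffers of the source view;
#'   when supplied, output pixels whose source sample lands on background
#'   (off the rendered surface) are masked invalid.
#' @return An object of class `ortho_patch`: `image` (H x W x 3),
#'   `valid_mask`, `scale` (px/mm), `frame` (the [build_virtual_frame()]),
#'   `anchor_triangle`, `source_view`, `center` (pixel of `V`).
#' @export
orthorectify <- function(view, mesh, anchor, s, size = NULL, normal = NULL,
                         interp = c("bilinear", "bicubic"), buffers = NULL) {
  interp <- match.arg(interp)
  stopifnot(inherits(view, "camera_view"), inherits(mesh, "tri_mesh"),
            s > 0)
  if (is.null(view$image))
    stop("orthorectify: source view carries no image")
  if (is.numeric(anchor) && length(anchor) == 1) {
    tid <- as.integer(anchor)
    F <- mesh$triangles[tid, ]
    V <- colMeans(mesh$vertices[F, , drop = FALSE])
  } else {
    tid <- anchor$triangle
    V <- anchor$V
    F <- mesh$triangles[tid, ]
  }
  if (is.null(normal))
    normal <- triangle_normal(mesh$vertices[F[1], ], mesh$vertices[F[2], ],
                              mesh$vertices[F[3], ])
  if (is.null(size)) size <- c(ceiling(40 * s), ceiling(40 * s))
  s_m <- s * 1000  # px per meter
  frame <- build_virtual_frame(normal, V, s_m)
  W <- as.integer(size[1])
  H <- as.integer(size[2])
  cx <- (W - 1) / 2
  cy <- (H - 1) / 2
  xg <- rep(0:(W - 1), each = H) - cx
  yg <- rep(0:(H - 1), times = W) - cy
  pts <- ortho_unproject(cbind(xg, yg), frame)
  ccs <- ocs_to_ccs(pts, view$pose, view$calib)
  px <- project_pinhole(ccs, view$calib, na_behind = TRUE)
  cols <- sample_image(view$image, px[, 1], px[, 2], interp)
  valid <- !is.na(cols[, 1])
  if (!is.null(buffers)) {
    cb <- round(px[, 1])
    rb <- round(px[, 2])
    Hs <- nrow(buffers$index)
    Ws <- ncol(buffers$index)
    inb <- !is.na(cb) & cb >= 0 & cb <= Ws - 1 & rb >= 0 & rb <= Hs - 1
    onsurf <- rep(FALSE, length(cb))
    onsurf[inb] <- buffers$index[rb[inb] + 1 + Hs * cb[inb]] > 0
    valid <- valid & onsurf
  }
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    plane[cbind(yg + cy + 1, xg + cx + 1)] <- ifelse(is.na(cols[, ch]), 0,
                                                     cols[, ch])
    img[, , ch] <- plane
  }
  mask <- matrix(FALSE, H, W)
  mask[cbind(yg + cy + 1, xg + cx + 1)] <- valid
  if (!any(mask))
    warning("orthorectify: fully invalid patch (anchor not visible?)")
  structure(list(image = img, valid_mask = mask, scale = s, frame = frame,
                 anchor_triangle = tid, source_view = view$id,
                 center = c(cx, cy)),
            class = "ortho_patch")
}

#' @export
print.ortho_patch <- function(x, ...) {
  cat(sprintf(
    "ortho_patch: %d x %d px at %g px/mm (%.1f x %.1f mm), %0.f%% valid\n",
    ncol(x$valid_mask), nrow(x$valid_mask), x$scale,
    ncol(x$valid_mask) / x$scale, nrow(x$valid_mask) / x$scale,
    100 * mean(x$valid_mask)))
  invisible(x)
}

#' Locate a source-image pixel inside an orthorectified patch
#'
#' The analytic inverse of the patch resampling chain for points on the
#' tangent plane: casts the source-camera ray through the given source
#' pixel, intersects it with the patch's tangent plane, and returns the
#' patch pixel coordinates of the intersection. Used to transfer
#' ground-truth landmarks (marker centers, tag corners) into patch
#' coordinates without a corner detector.
#'
#' @param patch An [orthorectify()] result.
#' @param view The source [camera_view()] the patch was resampled from.
#' @param pixel `c(x_t, y_t)` source-image pixel (or n x 2 matrix).
#' @return Patch pixel coordinates (same shape rule as input).
#' @export
ortho_locate <- function(patch, view, pixel) {
  p <- if (is.null(dim(pixel))) matrix(pixel, 1, 2) else as.matrix(pixel)
  O <- camera_center(view$pose, view$calib)
  # ray direction in CCS through pixel, to OCS
  d_ccs <- cbind((p[, 1] - view$calib$principal_point[1]) * view$calib$d,
                 (p[, 2] - view$calib$principal_point[2]) * view$calib$d,
                 1)
  ends <- ccs_to_ocs(d_ccs, view$pose, view$calib)
  dirs <- sweep(ends, 2, O)
  n <- -patch$frame$G[3, ]  # outward normal
  V <- patch$frame$V
  denom <- dirs %*% n
  t <- as.numeric(((V - O) %*% n)) / as.numeric(denom)
  hit <- sweep(dirs * t, 2, -O)
  g <- ortho_project(ocs_to_vcs(hit, patch$frame), patch$frame$s)
  out <- cbind(g[, 1] + patch$center[1], g[, 2] + patch$center[2])
  if (is.null(dim(pixel))) drop(out) else out
}

#' Write an orthorectified patch to PNG plus a JSON sidecar
#'
#' The sidecar records the anchor `V`, outward normal, frame rotation `G`,
#' scale, source view and anchor triangle, so the patch's physical geometry
#' is self-describing.
#' @param patch An [orthorectify()] result.
#' @param prefix Output path prefix (writes `<prefix>.png`,
#'   `<prefix>.json`).
#' @export
write_ortho_patch <- function(patch, prefix) {
  png_path <- paste0(prefix, ".png")
  write_image(patch$image, png_path, bits = 8)
  meta <- list(V = patch$frame$V, n = -patch$frame$G[3, ],
               G = patch$frame$G, s_px_per_mm = patch$scale,
               source_view = patch$source_view,
               anchor_triangle = patch$anchor_triangle)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(png_path, paste0(prefix, ".json")))
}
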