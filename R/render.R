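# Software rasterizer: triangle-index mosaics, barycentric shading and
# textured renders used for visibility testing, picking and the synthetic
# camera.

#' High-resolution camera view
#'
#' Bundles one photograph with the pose and calibration under which it was
#' taken.
#'
#' @param pose The camera's [rigid_pose()].
#' @param calib The camera's [camera_calib()].
#' @param image Optional H x W x 3 array in `[0, 1]` (row = y, col = x).
#' @param id Optional integer view id.
#' @export
camera_view <- function(pose, calib, image = NULL, id = NA_integer_) {
  stopifnot(inherits(pose, "rigid_pose"), inherits(calib, "camera_calib"))
  if (!is.null(image)) {
    stopifnot(length(dim(image)) == 3,
              dim(image)[1] == calib$image_size[2],
              dim(image)[2] == calib$image_size[1])
  }
  structure(list(pose = pose, calib = calib, image = image,
                 id = as.integer(id)),
            class = "camera_view")
}

#' @export
print.camera_view <- function(x, ...) {
  cat(sprintf(
    "camera_view%s: alpha = %.1f deg, h = %.2f m, r = %.2f m, %dx%d px%s\n",
    if (is.na(x$id)) "" else sprintf(" [%d]", x$id),
    x$pose$alpha * 180 / pi, x$pose$h, x$pose$r,
    x$calib$image_size[1], x$calib$image_size[2],
    if (is.null(x$image)) " (no image)" else ""))
  invisible(x)
}

# Project mesh vertices for a view; returns list(px = n x 2 pixel coords,
# z = view depth, keep = per-triangle front-facing & renderable mask).
project_mesh <- function(mesh, view, cull_backfaces = TRUE) {
  V <- mesh$vertices
  F <- mesh$triangles
  if (inherits(view, "camera_view")) {
    ccs <- ocs_to_ccs(V, view$pose, view$calib)
    z <- ccs[, 3]
    px <- project_pinhole(ccs, view$calib, na_behind = TRUE)
    # front-facing: outward normal (in CCS) points back toward the camera
    # at the origin, i.e. dot(normal_ccs, centroid_ccs) < 0
    A <- ccs[F[, 1], , drop = FALSE]
    u <- ccs[F[, 2], , drop = FALSE] - A
    v <- ccs[F[, 3], , drop = FALSE] - A
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    cen <- (ccs[F[, 1], , drop = FALSE] + ccs[F[, 2], , drop = FALSE] +
            ccs[F[, 3], , drop = FALSE]) / 3
    front <- rowSums(n * cen) < 0
    infront <- z[F[, 1]] > 1e-9 & z[F[, 2]] > 1e-9 & z[F[, 3]] > 1e-9
    keep <- infront & (front | !cull_backfaces)
    list(px = px, z = z, keep = keep, perspective = TRUE,
         W = view$calib$image_size[1], H = view$calib$image_size[2])
  } else if (inherits(view, "ortho_view")) {
    vcs <- ocs_to_vcs(V, view$frame)
    g <- ortho_project(vcs, view$frame$s)
    px <- cbind(g[, 1] + view$center[1], g[, 2] + view$center[2])
    z <- vcs[, 3]
    A <- vcs[F[, 1], , drop = FALSE]
    u <- vcs[F[, 2], , drop = FALSE] - A
    v <- vcs[F[, 3], , drop = FALSE] - A
    nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    # viewer looks along +Z_VCS; front-facing normals have negative z
    front <- nz < 0
    keep <- front | !cull_backfaces
    list(px = px, z = z, keep = keep, perspective = FALSE,
         W = view$size[1], H = view$size[2])
  } else {
    stop("project_mesh: view must be a camera_view or ortho_view")
  }
}

#' Orthographic viewer over a virtual frame
#'
#' Wraps a [build_virtual_frame()] result with a raster size so the
#' renderer can produce index/barycentric buffers from the virtual
#' orthographic camera's point of view.
#'
#' @param frame A [build_virtual_frame()] result.
#' @param size `c(width, height)` of the raster in pixels.
#' @param center Pixel of the frame anchor; defaults to the raster center
#'   `(size - 1) / 2`.
#' @export
ortho_view <- function(frame, size, center = NULL) {
  stopifnot(inherits(frame, "virtual_frame"), length(size) == 2)
  if (is.null(center)) center <- (size - 1) / 2
  structure(list(frame = frame, size = as.integer(size),
                 center = as.numeric(center)),
            class = "ortho_view")
}

#' Render the triangle-index mosaic and barycentric buffers
#'
#' Rasterizes the mesh from the given viewpoint into three aligned buffers:
#' `index` holds, per pixel, the id of the nearest front-facing triangle
#' whose projection covers the pixel center (0 = background); `bary` holds
#' the perspective-correct barycentric weights of the pixel center within
#' that triangle; `depth` the view depth. Back-facing triangles are culled;
#' depth ties go to the lower triangle id. Rendering is deterministic.
#'
#' @param mesh A [tri_mesh()].
#' @param view A [camera_view()] (perspective) or [ortho_view()]
#'   (orthographic).
#' @param perspective_correct Use perspective-correct barycentric
#'   interpolation (ignored for orthographic views); screen-space linear
#'   interpolation is available for fidelity experiments.
#' @return An object of class `render_buffers` with `index` (H x W integer
#'   matrix), `bary` (H x W x 3), `depth` (H x W), and the `view`.
#' @export
render_mosaic <- function(mesh, view, perspective_correct = TRUE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  pr <- project_mesh(mesh, view)
  res <- cpp_rasterize(pr$px, pr$z, mesh$triangles - 1L, pr$keep,
                       pr$W, pr$H, pr$perspective && perspective_correct)
  structure(list(index = res$index, bary = res$bary, depth = res$depth,
                 view = view),
            class = "render_buffers")
}

#' @export
print.render_buffers <- function(x, ...) {
  cat(sprintf("render_buffers: %d x %d px, %d covered\n",
              ncol(x$index), nrow(x$index), sum(x$index > 0)))
  invisible(x)
}

#' Surface points seen by each foreground pixel
#'
#' Decodes each nonzero-index pixel of a render into its 3D surface point
#' via the barycentric combination of the winning triangle's vertices.
#'
#' @param buffers A [render_mosaic()] result.
#' @param mesh The rendered [tri_mesh()].
#' @return List with `pixels` (n x 2, 0-based x/y), `tri` (n), `points`
#'   (n x 3 OCS).
#' @export
buffer_surface_points <- function(buffers, mesh) {
  idx <- buffers$index
  sel <- which(idx > 0)
  tri <- idx[sel]
  H <- nrow(idx)
  px <- cbind((sel - 1) %/% H, (sel - 1) %% H)  # x = col, y = row (0-based)
  b <- matrix(c(buffers$bary[, , 1][sel], buffers$bary[, , 2][sel],
                buffers$bary[, , 3][sel]), ncol = 3)
  F <- mesh$triangles
  V <- mesh$vertices
  pts <- b[, 1] * V[F[tri, 1], , drop = FALSE] +
         b[, 2] * V[F[tri, 2], , drop = FALSE] +
         b[, 3] * V[F[tri, 3], , drop = FALSE]
  list(pixels = px, tri = tri, points = pts, bary = b)
}

#' Render a shaded image from a surface color function
#'
#' Produces the image a camera would capture of a surface whose color is an
#' analytic function of position: each foreground pixel is colored by
#' `texture_fn` evaluated at the perspective-correct surface point of the
#' winning triangle.
#'
#' @param mesh A [tri_mesh()].
#' @param view A [camera_view()] or [ortho_view()].
#' @param texture_fn Function taking an n x 3 matrix of OCS surface points
#'   and returning an n x 3 matrix of RGB colors in `[0, 1]`.
#' @param background Background color (RGB in `[0, 1]`).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
render_shaded <- function(mesh, view, texture_fn,
                          background = c(0, 0, 0)) {
  buf <- render_mosaic(mesh, view)
  H <- nrow(buf$index)
  W <- ncol(buf$index)
  img <- array(rep(background, each = H * W), dim = c(H, W, 3))
  sp <- buffer_surface_points(buf, mesh)
  if (nrow(sp$points) > 0) {
    cols <- texture_fn(sp$points)
    sel <- which(buf$index > 0)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Encode / decode triangle ids as 24-bit RGB
#'
#' The mosaic convention: id 0 is background (black); a triangle with index
#' `i` (1-based) is encoded as `R + 256 G + 65536 B = i`. Round-trips
#' exactly for ids up to `2^24 - 1`.
#'
#' @param id Integer vector of triangle ids (0 = background).
#' @return `encode_index_rgb`: n x 3 integer matrix of 8-bit channels;
#'   `decode_index_rgb`: integer vector of ids.
#' @export
encode_index_rgb <- function(id) {
  stopifnot(all(id >= 0), all(id < 2^24))
  cbind(r = id %% 256L, g = (id %/% 256L) %% 256L, b = id %/% 65536L)
}

#' @rdname encode_index_rgb
#' @param rgb n x 3 integer matrix of 8-bit channel values.
#' @export
decode_index_rgb <- function(rgb) {
  rgb <- matrix(as.integer(round(rgb)), ncol = 3)
  rgb[, 1] + 256L * rgb[, 2] + 65536L * rgb[, 3]
}

#' Export render buffers as PNG images
#'
#' Writes the index buffer as an 8-bit RGB PNG with the 24-bit id encoding
#' of [encode_index_rgb()], and the barycentric buffer as a 16-bit RGB PNG
#' (weights scaled by 65535; 8-bit quantization would dominate the picking
#' error budget).
#'
#' @param buffers A [render_mosaic()] result.
#' @param prefix Output path prefix; writes `<prefix>_index.png` and
#'   `<prefix>_bary.png`.
#' @return Invisibly, the two file paths.
#' @export
write_render_buffers <- function(buffers, prefix) {
  idx <- buffers$index
  H <- nrow(idx)
  W <- ncol(idx)
  rgb <- encode_index_rgb(as.vector(idx))
  img <- array(rgb / 255, dim = c(H, W, 3))
  f1 <- paste0(prefix, "_index.png")
  write_image(img, f1, bits = 8)
  b <- buffers$bary
  b[is.na(b)] <- 0
  f2 <- paste0(prefix, "_bary.png")
  write_image(b, f2, bits = 16)
  invisible(c(f1, f2))
}

#' Read an exported index PNG back into an id matrix
#' @param path PNG path written by [write_render_buffers()].
#' @export
read_index_png <- function(path) {
  img <- read_image(path)
  H <- dim(img)[1]
  W <- dim(img)[2]
  matrix(decode_index_rgb(matrix(round(img * 255), ncol = 3)), H, W)
}
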