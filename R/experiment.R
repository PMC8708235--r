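# Marker measurement experiment: quantify each ground-truth marker in its
# source photograph and in the orthorectified patch, for the
# before/after-rectification comparison.

# nearest mesh triangle to a 3D point (by centroid)
nearest_triangle <- function(mesh, point) {
  F <- mesh$triangles
  V <- mesh$vertices
  cen <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3
  nn <- cpp_knn(cen, matrix(point, 1, 3), 1L)
  nn$idx[1, 1]
}

#' Measure session markers before and after orthorectification
#'
#' For every ground-truth marker: project its center and tag corners into
#' the chosen source photograph, segment the marker disk in a local crop
#' and fit the moment ellipse (original-image measurement, with the pixel
#' scale taken at the marker's depth); then orthorectify a patch anchored
#' at the marker and repeat the measurement in true physical scale. Tag
#' shear angles use the ground-truth corners projected into the image and,
#' for the rectified condition, transferred into the patch analytically
#' ([ortho_locate()]), avoiding a corner-detector dependency.
#'
#' @param mesh The body [tri_mesh()] (ground truth or reconstructed).
#' @param views List of [camera_view()]s with images.
#' @param markers Ground-truth marker list from [build_phantom()].
#' @param s Patch scale, pixels per millimeter.
#' @param view_ids Optional explicit source view per marker; defaults to
#'   the view assigned to the marker's anchor triangle by
#'   [assign_textures()] (the largest-projected-area rule).
#' @param patch_mm Physical patch size (square, millimeters).
#' @return Data frame with one row per marker and condition (`original`,
#'   `orthorectified`): `marker`, `condition`, `view`, `angle_deg`,
#'   `ratio`, `area_cm2`.
#' @export
measure_session_markers <- function(mesh, views, markers, s = 10,
                                    view_ids = NULL, patch_mm = 36) {
  stopifnot(length(markers) >= 1)
  assignment <- NULL
  if (is.null(view_ids))
    assignment <- assign_textures(mesh, views)
  rows <- list()
  for (i in seq_along(markers)) {
    m <- markers[[i]]
    tid <- nearest_triangle(mesh, m$center)
    vid <- if (!is.null(view_ids)) view_ids[i] else assignment$view[tid]
    if (is.na(vid)) next
    view <- views[[vid]]
    ccs <- ocs_to_ccs(m$center, view$pose, view$calib)
    if (ccs[3] <= 0) next
    pc <- project_pinhole(ccs, view$calib)
    pcorn <- project_pinhole(ocs_to_ccs(m$corners, view$pose, view$calib),
                             view$calib)

    # original-image measurement in a crop around the tag
    W <- view$calib$image_size[1]
    H <- view$calib$image_size[2]
    ext <- apply(pcorn, 2, range)
    pad <- 0.35 * max(ext[2, ] - ext[1, ])
    c0 <- max(0, floor(ext[1, 1] - pad))
    c1 <- min(W - 1, ceiling(ext[2, 1] + pad))
    r0 <- max(0, floor(ext[1, 2] - pad))
    r1 <- min(H - 1, ceiling(ext[2, 2] + pad))
    orig <- list(ratio = NA_real_, area = NA_real_, angle = NA_real_)
    if (c1 - c0 > 4 && r1 - r0 > 4) {
      crop <- view$image[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), ,
                         drop = FALSE]
      mask <- tryCatch(
        segment_marker(crop, center = c(pc[1] - c0, pc[2] - r0)),
        error = function(e) NULL)
      if (!is.null(mask) && sum(mask) >= 9) {
        fit <- fit_ellipse(mask)
        mm_per_px <- view$calib$d * ccs[3] * 1000
        orig$ratio <- fit$ratio
        orig$area <- sum(mask) * mm_per_px^2 / 100
      }
      orig$angle <- shear_angle(pcorn)
    }

    # orthorectified measurement
    size <- rep(ceiling(patch_mm * s), 2)
    patch <- orthorectify(view, mesh, list(triangle = tid, V = m$center),
                          s = s, size = size)
    rect <- list(ratio = NA_real_, area = NA_real_, angle = NA_real_)
    mask <- tryCatch(segment_marker(patch), error = function(e) NULL)
    if (!is.null(mask) && sum(mask) >= 9) {
      fit <- fit_ellipse(mask)
      rect$ratio <- fit$ratio
      rect$area <- marker_area(mask, s)
    }
    rcorn <- ortho_locate(patch, view, pcorn)
    rect$angle <- shear_angle(rcorn)

    rows[[length(rows) + 1]] <- data.frame(
      marker = m$id, condition = "original", view = vid,
      angle_deg = orig$angle, ratio = orig$ratio, area_cm2 = orig$area)
    rows[[length(rows) + 1]] <- data.frame(
      marker = m$id, condition = "orthorectified", view = vid,
      angle_deg = rect$angle, ratio = rect$ratio, area_cm2 = rect$area)
  }
  if (!length(rows))
    stop("measure_session_markers: no marker was measurable")
  do.call(rbind, rows)
}
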