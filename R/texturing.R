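# Per-triangle texture-image selection and picking from rendered buffers.

# Projected pixel coordinates of every triangle corner in a view, plus the
# signed projected area. Returns list(px = n x 2 vertex pixels, area = m,
# keep = triangle projectable mask).
triangle_projections <- function(mesh, view) {
  pr <- project_mesh(mesh, view, cull_backfaces = TRUE)
  F <- mesh$triangles
  x <- matrix(pr$px[F, 1], ncol = 3)
  y <- matrix(pr$px[F, 2], ncol = 3)
  area <- 0.5 * abs((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
                    (y[, 2] - y[, 1]) * (x[, 3] - x[, 1]))
  list(px = pr$px, xs = x, ys = y, area = area, keep = pr$keep,
       W = pr$W, H = pr$H)
}

#' Visibility of mesh triangles in a rendered view
#'
#' A triangle passes the visibility test for a view when the index mosaic
#' rendered from that view shows the triangle's own id at four sampled
#' interior points of its projection: the centroid and the three edge
#' midpoints, the latter pulled halfway toward the centroid so the samples
#' are strictly interior (a sample exactly on a shared edge would read the
#' neighbor's id on one side of the edge). All four must match. Occluded
#' triangles show another triangle's id there and fail; triangles
#' projecting (partly) off-image or covering no pixel center fail as well.
#'
#' @param mesh A [tri_mesh()].
#' @param view A [camera_view()].
#' @param buffers Optional [render_mosaic()] buffers for `view`; rendered
#'   on the fly when omitted.
#' @return Logical vector, one entry per triangle.
#' @export
triangle_visibility <- function(mesh, view, buffers = NULL) {
  if (is.null(buffers)) buffers <- render_mosaic(mesh, view)
  tp <- triangle_projections(mesh, view)
  idx <- buffers$index
  H <- nrow(idx)
  W <- ncol(idx)
  m <- nrow(mesh$triangles)
  xs <- tp$xs
  ys <- tp$ys
  # sample points: centroid + 3 edge midpoints pulled inward to the
  # centroid (strictly interior samples)
  cxm <- (xs[, 1] + xs[, 2] + xs[, 3]) / 3
  cym <- (ys[, 1] + ys[, 2] + ys[, 3]) / 3
  mid <- function(m, a, b, c) ((m[, a] + m[, b]) / 2 + c) / 2
  sx <- cbind(cxm, mid(xs, 1, 2, cxm), mid(xs, 2, 3, cxm),
              mid(xs, 3, 1, cxm))
  sy <- cbind(cym, mid(ys, 1, 2, cym), mid(ys, 2, 3, cym),
              mid(ys, 3, 1, cym))
  col <- round(sx)
  row <- round(sy)
  inimg <- col >= 0 & col <= W - 1 & row >= 0 & row <= H - 1
  ok <- tp$keep & rowSums(inimg) == 4 &
    rowSums(!is.na(sx)) == 4
  vis <- rep(FALSE, m)
  cand <- which(ok)
  if (length(cand) > 0) {
    match_all <- rep(TRUE, length(cand))
    for (s in 1:4) {
      lin <- row[cand, s] + 1 + H * col[cand, s]
      match_all <- match_all & (idx[lin] == cand)
    }
    vis[cand] <- match_all
  }
  vis
}

#' Assign to every triangle its best source image
#'
#' For each triangle, among the views where it passes the visibility test,
#' the view with the largest projected area -- the one picturing the skin
#' fragment at the highest resolution -- is selected. Area ties break to
#' the lowest view id. Triangles visible nowhere are left unassigned.
#'
#' @param mesh A [tri_mesh()].
#' @param views List of [camera_view()] objects.
#' @return An object of class `texture_assignment`: a data frame with one
#'   row per triangle (`triangle`, `view` (NA = unassigned), `area_px2`,
#'   and per-corner texture coordinates `u1,v1,u2,v2,u3,v3` in the assigned
#'   view).
#' @export
assign_textures <- function(mesh, views) {
  stopifnot(length(views) >= 1)
  m <- nrow(mesh$triangles)
  nv <- length(views)
  areas <- matrix(0, m, nv)
  uv <- vector("list", nv)
  for (v in seq_len(nv)) {
    buf <- render_mosaic(mesh, views[[v]])
    vis <- triangle_visibility(mesh, views[[v]], buf)
    tp <- triangle_projections(mesh, views[[v]])
    a <- tp$area
    a[!vis | !is.finite(a)] <- 0
    areas[, v] <- a
    uv[[v]] <- cbind(tp$xs[, 1], tp$ys[, 1], tp$xs[, 2], tp$ys[, 2],
                     tp$xs[, 3], tp$ys[, 3])
  }
  best <- max.col(areas, ties.method = "first")
  assigned <- areas[cbind(seq_len(m), best)] > 0
  view_id <- ifelse(assigned, best, NA_integer_)
  out <- data.frame(triangle = seq_len(m), view = view_id,
                    area_px2 = ifelse(assigned,
                                      areas[cbind(seq_len(m), best)],
                                      NA_real_))
  uvm <- matrix(NA_real_, m, 6,
                dimnames = list(NULL, c("u1", "v1", "u2", "v2", "u3", "v3")))
  for (v in seq_len(nv)) {
    rows <- which(assigned & best == v)
    if (length(rows)) uvm[rows, ] <- uv[[v]][rows, , drop = FALSE]
  }
  out <- cbind(out, as.data.frame(uvm))
  class(out) <- c("texture_assignment", class(out))
  out
}

#' Pick a surface point from a rendered view
#'
#' The mouse-picking primitive: reads the triangle id under the given pixel
#' from the index mosaic, the barycentric weights from the shaded buffer,
#' and reconstructs the 3D surface point as the weighted combination of the
#' triangle's vertices.
#'
#' @param pixel `c(x, y)` pixel coordinates (0-based, x right / y down).
#' @param buffers [render_mosaic()] buffers of the view being picked.
#' @param mesh The rendered [tri_mesh()].
#' @return List with `triangle` (id), `weights` (barycentric), `V` (3D
#'   point, OCS).
#' @export
pick <- function(pixel, buffers, mesh) {
  stopifnot(length(pixel) == 2)
  col <- round(pixel[1])
  row <- round(pixel[2])
  H <- nrow(buffers$index)
  W <- ncol(buffers$index)
  if (col < 0 || col > W - 1 || row < 0 || row > H - 1)
    stop("pick: pixel outside the image")
  id <- buffers$index[row + 1, col + 1]
  if (id == 0)
    stop("pick: no surface under cursor (background pixel)")
  w <- c(buffers$bary[row + 1, col + 1, 1],
         buffers$bary[row + 1, col + 1, 2],
         buffers$bary[row + 1, col + 1, 3])
  F <- mesh$triangles
  V <- barycentric_point(w, mesh$vertices[F[id, 1], ],
                         mesh$vertices[F[id, 2], ],
                         mesh$vertices[F[id, 3], ])
  list(triangle = id, weights = w, V = V)
}

#' Persist a texture assignment as JSON
#'
#' One record per assigned triangle: `triangle_id`, `view_id`, `uv`
#' (3 corners x 2), `area_px2`.
#' @param assignment An [assign_textures()] result.
#' @param path Output JSON path.
#' @export
write_assignment <- function(assignment, path) {
  rows <- assignment[!is.na(assignment$view), , drop = FALSE]
  recs <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    list(triangle_id = r$triangle, view_id = r$view,
         uv = matrix(c(r$u1, r$v1, r$u2, r$v2, r$u3, r$v3), 3, 2,
                     byrow = TRUE),
         area_px2 = r$area_px2)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a texture assignment written by [write_assignment()]
#' @param path JSON path.
#' @param n_triangles Total triangle count of the mesh.
#' @export
read_assignment <- function(path, n_triangles) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- data.frame(triangle = seq_len(n_triangles), view = NA_integer_,
                    area_px2 = NA_real_, u1 = NA_real_, v1 = NA_real_,
                    u2 = NA_real_, v2 = NA_real_, u3 = NA_real_,
                    v3 = NA_real_)
  if (length(recs)) {
    ids <- recs$triangle_id
    out$view[ids] <- recs$view_id
    out$area_px2[ids] <- recs$area_px2
    uv <- recs$uv
    for (i in seq_along(ids)) {
      u <- uv[[i]]
      out[ids[i], c("u1", "v1", "u2", "v2", "u3", "v3")] <-
        c(t(u))
    }
  }
  class(out) <- c("texture_assignment", class(out))
  out
}
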