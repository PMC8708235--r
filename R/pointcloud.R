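# Point-cloud container and the per-cloud preprocessing stages.

#' Point cloud container
#'
#' A set of 3D surface samples from a depth scanner, with an optional unit
#' normal per point and the rigid pose of the acquiring device.
#'
#' @param points n x 3 matrix of coordinates (meters).
#' @param normals Optional n x 3 matrix of unit normals.
#' @param pose Optional [rigid_pose()] of the acquiring scanner.
#' @param cs Coordinate system the points live in: `"DCS"` or `"OCS"`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, pose = NULL,
                        cs = c("DCS", "OCS")) {
  cs <- match.arg(cs)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(all(dim(normals) == dim(points)))
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6))
      stop("point_cloud: normals must be unit length")
  }
  structure(list(points = points, normals = normals, pose = pose, cs = cs),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points in %s%s%s\n", nrow(x$points), x$cs,
              if (!is.null(x$normals)) ", with normals" else "",
              if (!is.null(x$pose))
                sprintf(", pose alpha = %.1f deg", x$pose$alpha * 180 / pi)
              else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A [point_cloud()].
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Axis-aligned crop box around the scanned subject
#'
#' @param min,max 3-vectors, the lower and upper corners (OCS, meters).
#' @export
subject_bounds <- function(min, max) {
  stopifnot(length(min) == 3, length(max) == 3, all(min < max))
  structure(list(min = as.numeric(min), max = as.numeric(max)),
            class = "subject_bounds")
}

#' Keep only the points inside the subject box
#'
#' The box is closed: points exactly on a face are retained. Point order is
#' preserved. An empty result raises a warning, as it usually signals
#' mis-set bounds.
#'
#' @param cloud A [point_cloud()] in OCS.
#' @param bounds A [subject_bounds()].
#' @export
crop_to_subject <- function(cloud, bounds) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(bounds, "subject_bounds"))
  if (cloud$cs != "OCS")
    stop("crop_to_subject: cloud must be in OCS")
  p <- cloud$points
  keep <- p[, 1] >= bounds$min[1] & p[, 1] <= bounds$max[1] &
          p[, 2] >= bounds$min[2] & p[, 2] <= bounds$max[2] &
          p[, 3] >= bounds$min[3] & p[, 3] <= bounds$max[3]
  if (!any(keep))
    warning("crop_to_subject: no points inside the subject bounds")
  subset_cloud(cloud, keep)
}

subset_cloud <- function(cloud, keep) {
  cloud$points <- cloud$points[keep, , drop = FALSE]
  if (!is.null(cloud$normals))
    cloud$normals <- cloud$normals[keep, , drop = FALSE]
  if (!is.null(cloud$viewpoints))
    cloud$viewpoints <- cloud$viewpoints[keep, , drop = FALSE]
  cloud
}

#' Voxel-grid downsampling
#'
#' Buckets points into an axis-aligned voxel grid anchored at the global
#' origin (`floor(coordinate / voxel)`) and replaces each non-empty voxel by
#' the spatial average of its members. Normals, if present, are averaged and
#' renormalized the same way. Output voxels are ordered by first appearance
#' of a member in the input.
#'
#' @param cloud A [point_cloud()].
#' @param voxel Voxel edge length (meters, > 0).
#' @export
voxel_downsample <- function(cloud, voxel) {
  stopifnot(inherits(cloud, "point_cloud"), voxel > 0)
  p <- cloud$points
  if (nrow(p) == 0) return(cloud)
  key <- paste(floor(p[, 1] / voxel), floor(p[, 2] / voxel),
               floor(p[, 3] / voxel))
  f <- factor(key, levels = unique(key))
  cnt <- as.vector(table(f))
  avg <- rowsum(p, f, reorder = FALSE) / cnt
  cloud$points <- unname(avg)
  if (!is.null(cloud$normals)) {
    nv <- rowsum(cloud$normals, f, reorder = FALSE) / cnt
    nn <- sqrt(rowSums(nv^2))
    nn[nn == 0] <- 1
    cloud$normals <- unname(nv / nn)
  }
  if (!is.null(cloud$viewpoints)) {
    vv <- rowsum(cloud$viewpoints, f, reorder = FALSE) / cnt
    cloud$viewpoints <- unname(vv)
  }
  cloud
}

#' Estimate oriented point normals by local covariance analysis
#'
#' Each point's normal is the eigenvector with the smallest eigenvalue of
#' the covariance of its `k` nearest neighbors (the local surface's minor
#' principal axis), sign-flipped to point toward the viewpoint -- i.e.
#' outward, toward the device that saw the point.
#'
#' @param cloud A [point_cloud()] with at least `k` points.
#' @param k Neighborhood size (>= 3).
#' @param viewpoint Either a single 3-vector (one scanner position) or an
#'   n x 3 matrix of per-point viewpoints (for merged multi-view clouds).
#' @return The cloud with a `normals` field.
#' @export
estimate_normals <- function(cloud, k = 30, viewpoint = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 3)
  p <- cloud$points
  if (nrow(p) < k)
    stop("estimate_normals: cloud has fewer than k points")
  nrm <- cpp_estimate_normals(p, as.integer(k))
  vp <- if (is.null(dim(viewpoint)))
    matrix(viewpoint, nrow(p), 3, byrow = TRUE) else as.matrix(viewpoint)
  stopifnot(nrow(vp) == nrow(p))
  flip <- rowSums(nrm * (vp - p)) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  cloud$normals <- nrm
  cloud
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `k` nearest neighbors and
#' removes the points whose mean distance exceeds
#' `mean + std_mult * sd` of those distances over the whole cloud. The
#' default multiplier of 1 removes loose points while keeping cloud edges.
#' A second pass may remove further points (the filter is not idempotent).
#'
#' @param cloud A [point_cloud()].
#' @param k Number of neighbors (>= 1).
#' @param std_mult Threshold multiplier on the standard deviation.
#' @export
remove_outliers <- function(cloud, k = 20, std_mult = 1.0) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 1)
  p <- cloud$points
  if (nrow(p) <= k) return(cloud)
  md <- cpp_mean_knn_dist(p, as.integer(k))
  s <- sd(md)
  keep <- if (s == 0) rep(TRUE, length(md)) else md <= mean(md) + std_mult * s
  subset_cloud(cloud, keep)
}

#' Merge clouds in a common coordinate system
#'
#' Concatenates points (and normals when all clouds carry them). When poses
#' are attached, a per-point `viewpoints` matrix records each point's
#' acquiring-device center, which [estimate_normals()] can use to orient
#' normals in merged clouds.
#'
#' @param clouds List of [point_cloud()] objects in OCS.
#' @export
merge_clouds <- function(clouds) {
  stopifnot(length(clouds) >= 1, all(vapply(clouds, inherits, TRUE,
                                            "point_cloud")))
  if (any(vapply(clouds, function(cl) cl$cs, "") != "OCS"))
    stop("merge_clouds: all clouds must be in OCS")
  pts <- do.call(rbind, lapply(clouds, function(cl) cl$points))
  out <- point_cloud(pts, cs = "OCS")
  if (all(vapply(clouds, function(cl) !is.null(cl$normals), TRUE)))
    out$normals <- do.call(rbind, lapply(clouds, function(cl) cl$normals))
  vps <- lapply(clouds, function(cl) {
    if (!is.null(cl$viewpoints)) return(cl$viewpoints)
    if (is.null(cl$pose)) return(NULL)
    matrix(camera_center(cl$pose), nrow(cl$points), 3, byrow = TRUE)
  })
  if (!any(vapply(vps, is.null, TRUE)))
    out$viewpoints <- do.call(rbind, vps)
  out
}

#' Transform a DCS cloud into OCS using its pose
#' @param cloud A [point_cloud()] in DCS with a pose.
#' @export
cloud_to_ocs <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$cs == "OCS") return(cloud)
  if (is.null(cloud$pose)) stop("cloud_to_ocs: cloud has no pose")
  cloud$points <- dcs_to_ocs(cloud$points, cloud$pose)
  if (!is.null(cloud$normals))
    cloud$normals <- cloud$normals %*% t(rot_y(cloud$pose$alpha))
  cloud$cs <- "OCS"
  cloud
}
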