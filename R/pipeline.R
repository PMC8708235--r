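# End-to-end model building and the command-style entry points behind the
# CLI script.

#' Default pipeline parameters
#'
#' Every stage's tunable in one list: the 45-degree arm step and device
#' geometry live in [make_rig()]; here are the processing defaults --
#' voxel size 1 cm, ICP correspondence cap 2 cm, statistical outlier
#' threshold at 1 standard deviation, MLS radius 5 cm, reconstruction
#' depth 7.
#' @export
default_pipeline_params <- function() {
  list(voxel = 0.01,
       icp_caps = c(0.02, 0.008),
       icp_max_iter = 50,
       icp_tol = 1e-6,
       icp_normals_k = 10,
       outlier_k = 20,
       outlier_std_mult = 1.0,
       mls_radius = 0.05,
       mls_order = 2,
       normals_k = 30,
       depth = 7,
       sdf_k = 10,
       skip_mls = FALSE,
       skip_loop_closure = FALSE)
}

#' Build the body mesh from a set of depth scans
#'
#' Runs the full reconstruction chain: transform each scan to object
#' coordinates, crop to the subject box, voxel-downsample, pairwise ICP
#' around the ring of views, loop-closure pose-graph correction, merge,
#' statistical outlier removal, MLS smoothing, normal estimation oriented
#' toward each point's acquiring scanner, and implicit surface
#' reconstruction. Per-stage point counts and residuals are logged.
#'
#' @param scans List of [point_cloud()]s in DCS with poses (or a
#'   `scan_session`).
#' @param bounds A [subject_bounds()] crop box.
#' @param params Parameter list, see [default_pipeline_params()].
#' @param verbose Emit per-stage messages.
#' @return List with `mesh` (a [tri_mesh()]), `cloud` (the processed
#'   merged cloud), `corrections` (per-view 4x4 applied after loop
#'   closure), `log` (data frame of stage, points, residual).
#' @export
build_model <- function(scans, bounds = NULL, params = list(),
                        verbose = TRUE) {
  if (inherits(scans, "scan_session")) {
    if (is.null(bounds)) bounds <- scans$bounds
    scans <- scans$scans
  }
  p <- utils::modifyList(default_pipeline_params(), params)
  nv <- length(scans)
  stopifnot(nv >= 1)
  log <- list()
  note <- function(stage, points, residual = NA_real_) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, points = points,
                                          residual = residual)
    if (verbose)
      message(sprintf("[%s] points = %d%s", stage, points,
                      if (is.na(residual)) ""
                      else sprintf(", residual = %.3g", residual)))
  }

  clouds <- lapply(scans, cloud_to_ocs)
  note("to_ocs", sum(vapply(clouds, n_points, 1L)))
  if (!is.null(bounds)) {
    clouds <- lapply(clouds, crop_to_subject, bounds = bounds)
    note("crop", sum(vapply(clouds, n_points, 1L)))
  }
  clouds <- lapply(clouds, voxel_downsample, voxel = p$voxel)
  note("downsample", sum(vapply(clouds, n_points, 1L)))

  # attach per-point viewpoints (device centers) before any merging
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    cl$viewpoints <- matrix(camera_center(cl$pose), n_points(cl), 3,
                            byrow = TRUE)
    clouds[[i]] <- cl
  }

  # all devices at one arm stop move rigidly with the arm: group the scans
  # per stop (arm angle) and register the ring of stops
  akey <- vapply(scans, function(s) round(s$pose$alpha * 180 / pi, 3), 1)
  stops <- sort(unique(akey))
  groups <- lapply(stops, function(a) {
    members <- which(akey == a)
    g <- clouds[[members[1]]]
    for (m in members[-1]) {
      g$points <- rbind(g$points, clouds[[m]]$points)
      g$viewpoints <- rbind(g$viewpoints, clouds[[m]]$viewpoints)
    }
    g$pose <- NULL
    g
  })
  ng <- length(groups)

  corrections <- rep(list(diag(4)), ng)
  if (ng >= 3 && !p$skip_loop_closure) {
    groups <- lapply(groups, function(g) {
      if (n_points(g) > p$icp_normals_k * 3)
        estimate_normals(g, k = p$icp_normals_k, viewpoint = g$viewpoints)
      else g
    })
    rr <- register_ring(groups, caps = p$icp_caps,
                        max_iter = p$icp_max_iter, tol = p$icp_tol)
    corrections <- rr$poses
    note("icp", sum(vapply(groups, n_points, 1L)), mean(rr$rms))
    cc <- compose_cycle(rr$edges)
    note("loop_closure", sum(vapply(groups, n_points, 1L)),
         rt_angle(cc) + rt_trans_norm(cc))
    groups <- lapply(groups, function(g) {
      g$normals <- NULL  # re-estimated on the merged cloud later
      g
    })
  } else if (ng >= 2) {
    # sequential chaining without loop closure
    rms <- numeric(ng - 1)
    for (i in seq_len(ng - 1)) {
      reg <- icp_register(groups[[i + 1]], groups[[i]],
                          max_corr_dist = p$icp_caps[1],
                          max_iter = p$icp_max_iter, tol = p$icp_tol)
      corrections[[i + 1]] <- corrections[[i]] %*% reg$transform
      rms[i] <- reg$rms
    }
    note("icp", sum(vapply(groups, n_points, 1L)), mean(rms))
  }
  if (ng >= 2) {
    for (i in seq_len(ng)) {
      g <- groups[[i]]
      g$points <- rt_apply(corrections[[i]], g$points)
      g$viewpoints <- rt_apply(corrections[[i]], g$viewpoints)
      groups[[i]] <- g
    }
  }

  merged <- point_cloud(do.call(rbind, lapply(groups, function(g) g$points)),
                        cs = "OCS")
  merged$viewpoints <- do.call(rbind,
                               lapply(groups, function(g) g$viewpoints))
  note("merge", n_points(merged))
  merged <- remove_outliers(merged, k = p$outlier_k,
                            std_mult = p$outlier_std_mult)
  note("outliers", n_points(merged))
  if (!p$skip_mls) {
    merged <- mls_smooth(merged, radius = p$mls_radius, order = p$mls_order)
    note("mls", n_points(merged))
  }
  merged <- estimate_normals(merged, k = p$normals_k,
                             viewpoint = merged$viewpoints)
  note("normals", n_points(merged))
  mesh <- reconstruct_surface(merged, depth = p$depth, k = p$sdf_k)
  note("reconstruct", nrow(mesh$vertices))
  list(mesh = mesh, cloud = merged, corrections = corrections,
       log = do.call(rbind, log))
}

#' RMS distance from a mesh to a reference surface
#'
#' Root-mean-square of the distances from the mesh vertices to the nearest
#' point of the reference mesh; the standard fidelity summary against a
#' known ground-truth surface. With `align = TRUE` the mesh is first
#' rigidly registered onto the reference (removing the global gauge
#' freedom a multi-view registration cannot observe) before measuring.
#'
#' @param mesh Reconstructed [tri_mesh()].
#' @param reference Ground-truth [tri_mesh()].
#' @param align Remove a global rigid offset by ICP before measuring.
#' @export
mesh_rms_distance <- function(mesh, reference, align = FALSE) {
  v <- mesh$vertices
  if (align) {
    ref_pts <- sample_mesh_points(reference, min(30000, 4 * nrow(v)))
    reg <- icp_register(point_cloud(v, cs = "OCS"),
                        point_cloud(ref_pts, cs = "OCS"),
                        max_corr_dist = 0.1, reciprocal = FALSE)
    v <- rt_apply(reg$transform, v)
  }
  sqrt(mean(point_mesh_distance(reference, v)^2))
}

read_config <- function(config) {
  if (is.list(config)) return(config)
  if (grepl("\\.json$", config)) return(jsonlite::read_json(config,
                                                            simplifyVector = TRUE))
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    return(yaml::read_yaml(config))
  }
  stop("config must be a list, .json or .yaml file")
}

#' Generate and write a synthetic scan session (CLI: `synth`)
#'
#' @param config List (or JSON/YAML path) with optional fields `markers`
#'   (data frame columns `psi_deg`, `y`, ...), `noise_sigma`, `dropout`,
#'   `seed`, `camera_heights`, `scanner_heights`, `n_angles`, `photos`,
#'   `n_theta`, `ring_step`.
#' @param out_dir Output session directory.
#' @return The session directory, invisibly.
#' @export
cmd_synth <- function(config = list(), out_dir) {
  cfg <- read_config(config)
  spec <- phantom_spec(markers = cfg$markers)
  phantom <- build_phantom(spec,
                           n_theta = cfg$n_theta %||% 96,
                           ring_step = cfg$ring_step %||% 0.02)
  rig <- make_rig(camera_heights = cfg$camera_heights %||% c(0.5, 0.9, 1.3),
                  scanner_heights = cfg$scanner_heights %||% c(0.5, 0.95, 1.4),
                  n_angles = cfg$n_angles %||% 8)
  session <- generate_session(phantom, rig,
                              noise_sigma = cfg$noise_sigma %||% 0.002,
                              dropout = cfg$dropout %||% 0,
                              photos = cfg$photos %||% TRUE,
                              seed = cfg$seed %||% 1)
  write_session(session, out_dir)
  invisible(out_dir)
}

#' Build the body mesh from a written session (CLI: `build-model`)
#'
#' @param session_dir Session directory (see [write_session()]).
#' @param out_mesh Output mesh path (`.ply` or `.obj`).
#' @param params Pipeline parameter overrides.
#' @param log_json Optional path for the JSON run log.
#' @return The [build_model()] result, invisibly.
#' @export
cmd_build_model <- function(session_dir, out_mesh, params = list(),
                            log_json = NULL) {
  ses <- read_session(session_dir)
  res <- build_model(ses$scans, ses$bounds, params)
  if (grepl("\\.obj$", out_mesh)) write_obj(res$mesh, out_mesh)
  else write_ply(res$mesh, out_mesh)
  if (!is.null(log_json))
    jsonlite::write_json(res$log, log_json, auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Assign source images to mesh triangles (CLI: `texture`)
#'
#' @param mesh A [tri_mesh()] or mesh file path.
#' @param session_dir Session directory with `rig.json` and images.
#' @param out_prefix Output prefix for the assignment JSON and textured
#'   OBJ/MTL.
#' @return The assignment, invisibly.
#' @export
cmd_texture <- function(mesh, session_dir, out_prefix) {
  if (is.character(mesh)) mesh <- read_ply(mesh)
  views <- read_rig_json(file.path(session_dir, "rig.json"), session_dir)
  assignment <- assign_textures(mesh, views)
  write_assignment(assignment, paste0(out_prefix, "_assignment.json"))
  recs <- jsonlite::read_json(file.path(session_dir, "rig.json"),
                              simplifyVector = TRUE)
  write_textured_obj(mesh, assignment, recs$image_path,
                     lapply(views, function(v) v$calib$image_size),
                     out_prefix)
  invisible(assignment)
}

#' Orthorectify a patch around an anchor (CLI: `ortho`)
#'
#' @param mesh A [tri_mesh()] or mesh file path.
#' @param session_dir Session directory with views.
#' @param anchor_triangle Anchor triangle id (the patch is centered at its
#'   centroid).
#' @param s Patch scale, pixels per millimeter.
#' @param size Patch size `c(width, height)` in pixels.
#' @param out_prefix Output prefix for PNG + JSON sidecar.
#' @param view_id Source view; defaults to the view assigned to the anchor
#'   triangle by [assign_textures()].
#' @return The patch, invisibly.
#' @export
cmd_ortho <- function(mesh, session_dir, anchor_triangle, s = 10,
                      size = c(400, 400), out_prefix, view_id = NULL) {
  if (is.character(mesh)) mesh <- read_ply(mesh)
  views <- read_rig_json(file.path(session_dir, "rig.json"), session_dir)
  if (is.null(view_id)) {
    assignment <- assign_textures(mesh, views)
    view_id <- assignment$view[anchor_triangle]
    if (is.na(view_id))
      stop("cmd_ortho: anchor triangle has no assigned view")
  }
  patch <- orthorectify(views[[view_id]], mesh, anchor_triangle, s, size)
  write_ortho_patch(patch, out_prefix)
  invisible(patch)
}

#' Marker-morphology report for a session (CLI: `metrics`)
#'
#' Measures every ground-truth marker of a synthetic session in its best
#' source image (ellipse axis ratio, area, tag shear angle) and in the
#' orthorectified patch, and aggregates the comparison. See
#' [measure_session_markers()].
#'
#' @param session_dir Session directory with ground truth.
#' @param mesh Optional mesh (defaults to the session's ground-truth
#'   mesh).
#' @param out_prefix Output prefix for the CSV/JSON report.
#' @param s Patch scale (px/mm).
#' @return The [aggregate_report()], invisibly.
#' @export
cmd_metrics <- function(session_dir, mesh = NULL, out_prefix, s = 10) {
  ses <- read_session(session_dir)
  gt <- jsonlite::read_json(file.path(session_dir, "ground_truth.json"),
                            simplifyVector = FALSE)
  markers <- lapply(gt$markers, function(m)
    list(id = m$id, psi = m$psi_deg * pi / 180, y = m$y,
         diameter_m = m$diameter_m, tag_m = unlist(m$tag_m),
         center = unlist(m$center), normal = unlist(m$normal),
         corners = matrix(unlist(m$corners), ncol = 3)))
  if (is.null(mesh)) mesh <- ses$truth_mesh
  meas <- measure_session_markers(mesh, ses$views, markers, s = s)
  report <- aggregate_report(meas)
  write_report(report, out_prefix)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
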