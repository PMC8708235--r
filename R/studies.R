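# Canned validation studies: the quantitative experiments that verify the
# pipeline on synthetic sessions with known ground truth. Each study fixes
# its conditions (phantom, rig, noise) and returns the measured numbers.

#' Marker rectification study
#'
#' Reproduces the marker experiment synthetically: twelve 2 cm circular
#' markers printed on the phantom torso at surface tilts from 0 to about
#' 60 degrees relative to their source camera and at varied distances
#' (three height rows, cameras offset from each row). Every marker is
#' measured in the source photograph and in the orthorectified patch;
#' correct rectification drives the fitted axis ratio to 1 and the area to
#' `pi` cm^2 regardless of tilt and distance.
#'
#' @param seed Seed for the session generation.
#' @param s Patch scale, pixels per millimeter.
#' @return List: `measurements` (per marker and condition),
#'   `report` (the [aggregate_report()]), `mean_original_ratio`,
#'   `mean_ortho_ratio`, `mean_ortho_area_cm2`, `mean_original_area_cm2`,
#'   `n_markers`.
#' @export
marker_rectification_study <- function(seed = 1, s = 10) {
  set.seed(seed)
  psis <- (0:11) * 70 / 11
  rows <- rep(c(0.8, 1.05, 1.3), 4)
  spec <- phantom_spec(markers = data.frame(psi_deg = psis, y = rows))
  ph <- build_phantom(spec, n_theta = 96, ring_step = 0.015)
  cal <- camera_calib(d = 2.5e-4, image_size = c(1440, 960))
  heights <- c(0.85, 1.0, 1.25)
  views <- lapply(seq_along(heights), function(i)
    virtual_photograph(ph, rigid_pose(0, heights[i], 0.9), cal,
                       id = as.integer(i)))
  view_ids <- match(rows, c(0.8, 1.05, 1.3))
  meas <- measure_session_markers(ph$mesh, views, ph$markers, s = s,
                                  view_ids = view_ids)
  orig <- meas[meas$condition == "original", ]
  rect <- meas[meas$condition == "orthorectified", ]
  list(measurements = meas,
       report = aggregate_report(meas),
       mean_original_ratio = mean(orig$ratio, na.rm = TRUE),
       mean_ortho_ratio = mean(rect$ratio, na.rm = TRUE),
       mean_original_area_cm2 = mean(orig$area_cm2, na.rm = TRUE),
       mean_ortho_area_cm2 = mean(rect$area_cm2, na.rm = TRUE),
       n_markers = length(ph$markers))
}

#' Registration recovery study
#'
#' Injects random rigid pose errors (up to 3 degrees / 2 cm) into the
#' eight depth scans of a body-phantom session, registers the ring of
#' views with coarse-to-fine pairwise ICP plus loop closure, and compares
#' every recovered pairwise transform with the injected ground truth (a
#' gauge-free, per-edge comparison: a ring of views determines absolute
#' poses only up to one global rigid motion). Dense scans are used; the
#' correspondence discretization error scales with the scan spacing.
#'
#' @param seed Seed for session generation and perturbations.
#' @return List: `edge_rot_err_deg`, `edge_trans_err_mm` (per edge),
#'   `max_rot_err_deg`, `max_trans_err_mm`, `loop_rot_err_deg`,
#'   `loop_trans_err_mm` (closed-loop composition error),
#'   `raw_loop_rot_err_deg` (before closure), `n_points_per_scan`.
#' @export
registration_recovery_study <- function(seed = 1) {
  set.seed(seed)
  ph <- build_phantom(body_phantom_spec(), n_theta = 72, ring_step = 0.015)
  rig <- make_rig(camera_heights = numeric(0), scanner_heights = 0.95,
                  n_angles = 8,
                  scanner_calib = camera_calib(d = 0.0025,
                                               image_size = c(768, 576)))
  ses <- generate_session(ph, rig, noise_sigma = 0, photos = FALSE)
  ses <- perturb_session(ses, max_rot_deg = 3, max_trans_m = 0.02)
  clouds <- lapply(ses$scans, function(sc) {
    cl <- cloud_to_ocs(sc)
    estimate_normals(cl, k = 10, viewpoint = camera_center(cl$pose))
  })
  nv <- length(clouds)
  # raw single-round ring for the pre-closure loop error
  sub <- lapply(clouds, subsample_cloud, n_max = 20000)
  raw_edges <- vector("list", nv)
  for (i in seq_len(nv)) {
    j <- i %% nv + 1
    raw_edges[[i]] <- icp_register(sub[[j]], clouds[[i]],
                                   max_corr_dist = 0.03)$transform
  }
  raw_cc <- compose_cycle(raw_edges)
  lc1 <- close_loop(raw_edges)
  # refinement rounds starting from the closed first round
  X <- lc1$poses
  for (cap in c(0.008, 0.005)) {
    cur <- lapply(seq_len(nv), function(i) {
      cl <- clouds[[i]]
      cl$points <- rt_apply(X[[i]], cl$points)
      cl$normals <- cl$normals %*% t(X[[i]][1:3, 1:3])
      cl
    })
    edges <- vector("list", nv)
    for (i in seq_len(nv)) {
      j <- i %% nv + 1
      src <- cur[[j]]
      if (n_points(src) > 20000) {
        idx <- sample.int(n_points(src), 20000)
        src <- subset_cloud(src, idx)
      }
      edges[[i]] <- icp_register(src, cur[[i]],
                                 max_corr_dist = cap)$transform
    }
    lc <- close_loop(edges)
    X <- lapply(seq_len(nv), function(i) lc$poses[[i]] %*% X[[i]])
  }
  final_edges <- lapply(seq_len(nv), function(i) {
    j <- i %% nv + 1
    solve(X[[i]]) %*% X[[j]]
  })
  P <- ses$perturbations
  errs <- vapply(seq_len(nv), function(i) {
    j <- i %% nv + 1
    E <- solve(P[[i]] %*% solve(P[[j]])) %*% final_edges[[i]]
    c(rt_angle(E) * 180 / pi, 1000 * rt_trans_norm(E))
  }, numeric(2))
  cc <- compose_cycle(final_edges)
  list(edge_rot_err_deg = errs[1, ],
       edge_trans_err_mm = errs[2, ],
       max_rot_err_deg = max(errs[1, ]),
       max_trans_err_mm = max(errs[2, ]),
       loop_rot_err_deg = rt_angle(cc) * 180 / pi,
       loop_trans_err_mm = 1000 * rt_trans_norm(cc),
       raw_loop_rot_err_deg = rt_angle(raw_cc) * 180 / pi,
       n_points_per_scan = mean(vapply(clouds, n_points, 1L)))
}

subsample_cloud <- function(cl, n_max) {
  if (n_points(cl) <= n_max) return(cl)
  subset_cloud(cl, sample.int(n_points(cl), n_max))
}

#' Reconstruction fidelity study
#'
#' Generates a noisy (sigma = 2 mm) 8-view depth-scan session of the body
#' phantom, runs the full reconstruction pipeline (5 cm MLS radius,
#' lattice depth 7) and measures the RMS distance from the reconstructed
#' mesh to the true phantom surface.
#'
#' @param seed Session seed.
#' @param noise_sigma Depth noise (meters).
#' @param depth Reconstruction lattice depth.
#' @return List: `rms_mm`, `watertight`, `n_triangles`, `log`.
#' @export
reconstruction_fidelity_study <- function(seed = 1, noise_sigma = 0.002,
                                          depth = 7) {
  set.seed(seed)
  ph <- build_phantom(body_phantom_spec(), n_theta = 72, ring_step = 0.015)
  rig <- make_rig(camera_heights = numeric(0), scanner_heights = 0.95,
                  n_angles = 8,
                  scanner_calib = camera_calib(d = 0.004,
                                               image_size = c(480, 360)))
  ses <- generate_session(ph, rig, noise_sigma = noise_sigma,
                          photos = FALSE)
  res <- build_model(ses, params = list(depth = depth, voxel = 0.005),
                     verbose = FALSE)
  list(rms_mm = 1000 * mesh_rms_distance(res$mesh, ph$mesh),
       watertight = is_watertight(res$mesh),
       n_triangles = n_triangles(res$mesh),
       log = res$log)
}
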