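# Fully synthetic scan sessions: a body phantom with printed markers,
# virtual high-resolution cameras and virtual depth scanners. Every session
# carries its own ground truth, so expected metric values are known
# analytically.

#' Specification of the body phantom
#'
#' The phantom torso is an elliptic cylinder (semi-axes `a` along X and `b`
#' along Z) capped by half-ellipsoids -- smooth, body-like, and with a
#' non-circular cross-section so that rigid registration has no rotational
#' ambiguity. Markers (a black disk of given diameter on a light
#' rectangular tag, emulating printed tags stuck to the skin) live on the
#' cylindrical part, where the surface is developable and chart distances
#' are exact geodesics. Optional vertical arm cylinders create occlusions.
#'
#' @param semi_axes `c(a, b)` torso cross-section semi-axes (meters).
#' @param y_range `c(y0, y1)` vertical extent of the cylindrical part.
#' @param cap_height Vertical semi-axis of the end caps (meters).
#' @param markers Data frame with columns `psi_deg` (azimuth of the marker
#'   center; 0 faces the camera parked at arm angle 0), `y` (height),
#'   `diameter_mm` (disk diameter, default 20: a 2 cm circle), `tag_w_mm`,
#'   `tag_h_mm` (tag rectangle).
#' @param arms Optional list of arm cylinders, each
#'   `list(x, z, radius, y = c(lo, hi))`.
#' @param waist `c(amplitude, center_y, sigma)`: a smooth Gaussian waist
#'   indentation of the torso profile (fractional radius reduction),
#'   giving the registration problem the vertical shape cues a real torso
#'   has. Amplitude 0 (default) keeps the cylindrical part developable,
#'   which is required when markers are present (their printed geometry is
#'   defined by exact geodesic distances in the unrolled chart).
#' @param lobes `c(amplitude, order, phase)`: low-order azimuthal
#'   modulation of the cross-section radius,
#'   `1 + amplitude * cos(order * psi + phase)` -- torso-like departures
#'   from a pure ellipse that make the azimuth observable to registration.
#'   The surface stays a generalized cylinder (constant cross-section
#'   along y), hence developable, so marker geodesics remain exact.
#' @param skin_color,tag_color,marker_color RGB triples in `[0, 1]`.
#' @export
phantom_spec <- function(semi_axes = c(0.15, 0.11),
                         y_range = c(0.45, 1.45),
                         cap_height = 0.3,
                         markers = NULL,
                         arms = NULL,
                         waist = c(0, 1.0, 0.12),
                         lobes = c(0.07, 3, 0.6),
                         skin_color = c(0.85, 0.70, 0.60),
                         tag_color = c(0.97, 0.97, 0.97),
                         marker_color = c(0.05, 0.05, 0.05)) {
  stopifnot(length(semi_axes) == 2, all(semi_axes > 0),
            y_range[1] < y_range[2], cap_height > 0,
            length(waist) == 3, waist[1] >= 0, waist[1] < 0.5,
            length(lobes) == 3, lobes[1] >= 0, lobes[1] < 0.3)
  if (!is.null(markers)) {
    markers <- as.data.frame(markers)
    if (is.null(markers$diameter_mm)) markers$diameter_mm <- 20
    if (is.null(markers$tag_w_mm)) markers$tag_w_mm <- 36
    if (is.null(markers$tag_h_mm)) markers$tag_h_mm <- 28
    stopifnot(all(c("psi_deg", "y") %in% names(markers)),
              all(markers$diameter_mm > 0))
  }
  if (!is.null(markers) && waist[1] > 0)
    stop("phantom_spec: markers require a developable torso (waist 0)")
  structure(list(semi_axes = semi_axes, y_range = y_range,
                 cap_height = cap_height, markers = markers, arms = arms,
                 waist = waist, lobes = lobes, skin_color = skin_color,
                 tag_color = tag_color, marker_color = marker_color),
            class = "phantom_spec")
}

#' Body-like phantom for registration and reconstruction studies
#'
#' The capped elliptic torso with a pronounced waist and two arm
#' cylinders: the elliptic cross-section, the waist and the arms make all
#' six rigid degrees of freedom observable to surface registration, the
#' way a real body's shape does. (Marker sessions use the plain
#' developable torso instead, see [phantom_spec()].)
#' @param with_arms Include the two arm cylinders.
#' @export
body_phantom_spec <- function(with_arms = TRUE) {
  phantom_spec(
    arms = if (with_arms)
      list(list(x = 0.24, z = 0, radius = 0.045, y = c(0.5, 1.4)),
           list(x = -0.24, z = 0, radius = 0.045, y = c(0.5, 1.4))),
    waist = c(0.3, 1.0, 0.08))
}

# Torso cross-section curve in the xz-plane:
#   x(psi) =  a m(psi) sin(psi),  z(psi) = -b m(psi) cos(psi),
#   m(psi) = 1 + amp cos(order psi + phase).
# Star-shaped around the axis, so psi is recoverable from a surface point
# as atan2(x/a, -z/b). Returns closures for points, outward 2D normals and
# the arc length from psi = 0 (valid on (-2pi, 2pi)) with its inverse.
cross_section_fun <- function(a, b, lobes, n = 16384) {
  amp <- lobes[1]
  ord <- lobes[2]
  ph <- lobes[3]
  mfun <- function(psi) 1 + amp * cos(ord * psi + ph)
  mder <- function(psi) -amp * ord * sin(ord * psi + ph)
  xy <- function(psi, sc = 1) {
    m <- mfun(psi)
    cbind(a * sc * m * sin(psi), -b * sc * m * cos(psi))
  }
  deriv <- function(psi) {
    m <- mfun(psi)
    md <- mder(psi)
    cbind(a * (md * sin(psi) + m * cos(psi)),
          -b * (md * cos(psi) - m * sin(psi)))
  }
  normal2d <- function(psi) {
    d <- deriv(psi)
    n <- cbind(d[, 2], -d[, 1])
    n / sqrt(rowSums(n^2))
  }
  psig <- seq(-2 * pi, 2 * pi, length.out = n + 1)
  f <- sqrt(rowSums(deriv(psig)^2))
  cum <- c(0, cumsum((f[-1] + f[-(n + 1)]) / 2 * diff(psig)))
  cum <- cum - cum[which.min(abs(psig))]  # zero at psi = 0
  list(xy = xy, deriv = deriv, normal2d = normal2d,
       arc = stats::approxfun(psig, cum), inv = stats::approxfun(cum, psig))
}

# closed cylinder mesh (side + cap fans) for phantom arms
cylinder_mesh <- function(cx, cz, radius, ylo, yhi, n_theta = 24,
                          n_y = 8) {
  psi <- 2 * pi * (0:(n_theta - 1)) / n_theta
  ys <- seq(ylo, yhi, length.out = n_y + 1)
  verts <- do.call(rbind, lapply(ys, function(y)
    cbind(cx + radius * sin(psi), y, cz - radius * cos(psi))))
  verts <- rbind(verts, c(cx, ylo, cz), c(cx, yhi, cz))
  blo <- nrow(verts) - 1
  bhi <- nrow(verts)
  tris <- list()
  for (r in seq_len(n_y)) {
    lo <- (r - 1) * n_theta
    hi <- r * n_theta
    for (k in seq_len(n_theta)) {
      k2 <- k %% n_theta + 1
      tris[[length(tris) + 1]] <- c(lo + k, lo + k2, hi + k2)
      tris[[length(tris) + 1]] <- c(lo + k, hi + k2, hi + k)
    }
  }
  for (k in seq_len(n_theta)) {
    k2 <- k %% n_theta + 1
    tris[[length(tris) + 1]] <- c(blo, k2, k)               # bottom fan
    tris[[length(tris) + 1]] <- c(bhi, n_y * n_theta + k,
                                  n_y * n_theta + k2)       # top fan
  }
  F <- do.call(rbind, tris)
  # enforce outward winding (check a side triangle against its radial)
  A <- verts[F[1, 1], ]
  u <- verts[F[1, 2], ] - A
  v <- verts[F[1, 3], ] - A
  n1 <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  cen <- (A + verts[F[1, 2], ] + verts[F[1, 3], ]) / 3
  if (sum(n1 * (cen - c(cx, cen[2], cz))) < 0) F <- F[, c(1, 3, 2)]
  list(vertices = verts, triangles = F)
}

#' Build the phantom mesh and its analytic texture function
#'
#' Triangulates the capped elliptic cylinder (plus optional arms) and
#' returns, along with the mesh, a closed-form surface-color function that
#' paints the skin albedo, the light tag rectangles and the black marker
#' disks at their true geodesic sizes -- the markers are functions of
#' position, not raster textures, so no resampling error enters the ground
#' truth. The construction carries its own ground truth: marker centers,
#' normals and tag corners in 3D.
#'
#' @param spec A [phantom_spec()].
#' @param n_theta Number of azimuthal subdivisions.
#' @param ring_step Approximate vertical ring spacing (meters).
#' @param n_cap Number of latitude rings per end cap.
#' @return List with `mesh` (a watertight [tri_mesh()] for the torso;
#'   arms, when present, are appended as further closed components),
#'   `texture_fn(points)`, `markers` (ground-truth list), `surface_point
#'   (psi, y)`, `spec`.
#' @export
build_phantom <- function(spec, n_theta = 96, ring_step = 0.02,
                          n_cap = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$semi_axes[1]
  b <- spec$semi_axes[2]
  y0 <- spec$y_range[1]
  y1 <- spec$y_range[2]
  ch <- spec$cap_height
  cs <- cross_section_fun(a, b, spec$lobes)

  # profile from bottom pole to top pole: (y, scale); the cylindrical part
  # carries the optional waist modulation
  wa <- spec$waist[1]
  wprof <- function(y) 1 - wa * exp(-0.5 * ((y - spec$waist[2]) /
                                              spec$waist[3])^2)
  phis <- (seq_len(n_cap - 1) / n_cap) * (pi / 2)
  ycyl <- seq(y0, y1, length.out = max(2, ceiling((y1 - y0) / ring_step) + 1))
  prof_y <- c(y0 - ch,
              y0 - ch * sin(rev(phis)),
              ycyl,
              y1 + ch * sin(phis),
              y1 + ch)
  prof_s <- c(0,
              cos(rev(phis)) * wprof(y0),
              wprof(ycyl),
              cos(phis) * wprof(y1),
              0)
  nr <- length(prof_y)
  psi <- -pi + 2 * pi * (0:(n_theta - 1)) / n_theta
  verts <- rbind(
    c(0, prof_y[1], 0),
    do.call(rbind, lapply(2:(nr - 1), function(i) {
      r <- cs$xy(psi, prof_s[i])
      cbind(r[, 1], prof_y[i], r[, 2])
    })),
    c(0, prof_y[nr], 0))
  ring_off <- function(i) 2 + (i - 2) * n_theta  # first vertex of ring i
  tris <- vector("list", 4 * n_theta * nr)
  ti <- 0
  add <- function(tr) {
    ti <<- ti + 1
    tris[[ti]] <<- tr
  }
  for (k in seq_len(n_theta)) {           # bottom pole fan
    k2 <- k %% n_theta + 1
    add(c(1, ring_off(2) + k - 1, ring_off(2) + k2 - 1))
  }
  for (i in 2:(nr - 2)) {                 # quad strips
    lo <- ring_off(i)
    hi <- ring_off(i + 1)
    for (k in seq_len(n_theta)) {
      k2 <- k %% n_theta + 1
      add(c(lo + k - 1, hi + k2 - 1, lo + k2 - 1))
      add(c(lo + k - 1, hi + k - 1, hi + k2 - 1))
    }
  }
  top <- nrow(verts)
  for (k in seq_len(n_theta)) {           # top pole fan
    k2 <- k %% n_theta + 1
    add(c(top, ring_off(nr - 1) + k2 - 1, ring_off(nr - 1) + k - 1))
  }
  F <- do.call(rbind, tris[seq_len(ti)])
  mesh <- tri_mesh(verts, F)
  # enforce outward orientation (compare face normals with radial dir)
  nrm <- mesh_triangle_normals(mesh)
  cen <- (verts[F[, 1], ] + verts[F[, 2], ] + verts[F[, 3], ]) / 3
  rad <- cbind(cen[, 1], cen[, 2] - (y0 + y1) / 2, cen[, 3])
  if (mean(rowSums(nrm * rad) > 0) < 0.5)
    mesh$triangles <- F[, c(1, 3, 2)]

  # arms as extra closed components
  if (!is.null(spec$arms)) {
    for (arm in spec$arms) {
      cm <- cylinder_mesh(arm$x, arm$z, arm$radius, arm$y[1], arm$y[2])
      off <- nrow(mesh$vertices)
      mesh <- tri_mesh(rbind(mesh$vertices, cm$vertices),
                       rbind(mesh$triangles, cm$triangles + off))
    }
  }

  # ground-truth marker geometry on the developable cylinder part
  surface_point <- function(p, y) {
    r <- cs$xy(p)
    cbind(r[, 1], y, r[, 2])
  }
  surface_normal <- function(p) {
    n2 <- cs$normal2d(p)
    cbind(n2[, 1], 0, n2[, 2])
  }
  markers <- list()
  if (!is.null(spec$markers)) {
    mk <- spec$markers
    for (i in seq_len(nrow(mk))) {
      pc <- mk$psi_deg[i] * pi / 180
      yc <- mk$y[i]
      d <- mk$diameter_mm[i] / 1000
      tw <- mk$tag_w_mm[i] / 1000
      th <- mk$tag_h_mm[i] / 1000
      if (yc - th / 2 < y0 || yc + th / 2 > y1)
        stop("build_phantom: marker tag leaves the cylindrical part")
      u0 <- cs$arc(pc)
      cornu <- c(-1, 1, 1, -1) * tw / 2 + u0
      cornv <- c(-1, -1, 1, 1) * th / 2 + yc
      corners <- surface_point(cs$inv(cornu), cornv)
      markers[[i]] <- list(id = i, psi = pc, y = yc, diameter_m = d,
                           tag_m = c(tw, th),
                           center = drop(surface_point(pc, yc)),
                           normal = drop(surface_normal(pc)),
                           corners = corners)
    }
    # tag-rectangle overlap check in the chart
    if (length(markers) > 1) {
      for (i in seq_along(markers)) {
        for (j in seq_along(markers)) {
          if (j <= i) next
          du <- abs(cs$arc(markers[[i]]$psi) - cs$arc(markers[[j]]$psi))
          dv <- abs(markers[[i]]$y - markers[[j]]$y)
          if (du < (markers[[i]]$tag_m[1] + markers[[j]]$tag_m[1]) / 2 &&
              dv < (markers[[i]]$tag_m[2] + markers[[j]]$tag_m[2]) / 2)
            stop("build_phantom: overlapping markers")
        }
      }
    }
  }

  skin <- spec$skin_color
  tagc <- spec$tag_color
  mkc <- spec$marker_color
  texture_fn <- function(points) {
    p <- as_points(points)
    n <- nrow(p)
    col <- matrix(rep(skin, each = n), n, 3)
    if (length(markers)) {
      amp <- spec$lobes[1]
      r2 <- (p[, 1] / a)^2 + (p[, 3] / b)^2
      on_cyl <- p[, 2] >= y0 & p[, 2] <= y1 &
        r2 > (1 - amp)^2 * 0.95 & r2 < (1 + amp)^2 * 1.05
      pp <- atan2(p[, 1] / a, -p[, 3] / b)
      for (m in markers) {
        dpsi <- ((pp - m$psi + pi) %% (2 * pi)) - pi
        du <- cs$arc(m$psi + dpsi) - cs$arc(m$psi)
        dv <- p[, 2] - m$y
        tag <- on_cyl & abs(du) <= m$tag_m[1] / 2 & abs(dv) <= m$tag_m[2] / 2
        col[tag, 1] <- tagc[1]; col[tag, 2] <- tagc[2]; col[tag, 3] <- tagc[3]
        disk <- on_cyl & (du^2 + dv^2) <= (m$diameter_m / 2)^2
        col[disk, 1] <- mkc[1]; col[disk, 2] <- mkc[2]; col[disk, 3] <- mkc[3]
      }
    }
    col
  }

  list(mesh = mesh,
       texture_fn = texture_fn,
       markers = markers,
       surface_point = surface_point,
       surface_normal = surface_normal,
       arc = cs,
       spec = spec)
}

#' Default intrinsics of the virtual high-resolution cameras
#'
#' Chosen so a 2 cm marker spans well over 100 px at 0.8 m subject
#' distance.
#' @param image_size `c(width, height)` pixels.
#' @param d Pinhole constant.
#' @export
default_camera_calib <- function(image_size = c(720, 960), d = 2.5e-4) {
  camera_calib(d = d, image_size = image_size)
}

#' Default intrinsics of the virtual depth scanners
#' @param image_size `c(width, height)` pixels.
#' @param d Pinhole constant (wide field of view).
#' @export
default_scanner_calib <- function(image_size = c(160, 120), d = 0.01) {
  camera_calib(d = d, image_size = image_size)
}

#' Acquisition rig: device poses on the rotating arm
#'
#' Mirrors the prototype geometry: the arm stops every 45 degrees (8
#' orientations), carrying high-resolution cameras at several heights and
#' depth scanners at several heights.
#'
#' @param camera_heights Heights of the cameras (meters above floor).
#' @param scanner_heights Heights of the depth scanners.
#' @param n_angles Number of arm stops over the full turn.
#' @param r_camera,r_scanner Device distances to the rotation axis.
#' @param camera_calib,scanner_calib Shared intrinsics.
#' @return List with `cameras` and `scanners`, each a list of
#'   `list(id, pose, calib)`.
#' @export
make_rig <- function(camera_heights = c(0.5, 0.9, 1.3),
                     scanner_heights = c(0.5, 0.95, 1.4),
                     n_angles = 8,
                     r_camera = 0.9, r_scanner = 1.2,
                     camera_calib = default_camera_calib(),
                     scanner_calib = default_scanner_calib()) {
  alphas <- 360 * (0:(n_angles - 1)) / n_angles
  cams <- list()
  for (h in camera_heights)
    for (al in alphas)
      cams[[length(cams) + 1]] <-
        list(id = length(cams) + 1L,
             pose = rigid_pose(al, h = h, r = r_camera, degrees = TRUE),
             calib = camera_calib)
  scans <- list()
  for (h in scanner_heights)
    for (al in alphas)
      scans[[length(scans) + 1]] <-
        list(id = length(scans) + 1L,
             pose = rigid_pose(al, h = h, r = r_scanner, degrees = TRUE),
             calib = scanner_calib)
  list(cameras = cams, scanners = scans, n_angles = n_angles)
}

#' Photograph the phantom with a virtual camera
#'
#' Renders the analytically textured phantom through the full projection
#' chain of the real cameras and records the exact pose and calibration.
#'
#' @param phantom A [build_phantom()] result.
#' @param pose Camera [rigid_pose()].
#' @param calib Camera [camera_calib()].
#' @param id View id stored on the result.
#' @param background Background color.
#' @return A [camera_view()] with the rendered image attached.
#' @export
virtual_photograph <- function(phantom, pose, calib, id = NA_integer_,
                               background = c(0, 0, 0)) {
  view <- camera_view(pose, calib, id = id)
  img <- render_shaded(phantom$mesh, view, phantom$texture_fn, background)
  view$image <- img
  view
}

#' Scan the phantom with a virtual depth scanner
#'
#' Casts a ray through every scanner pixel, adds Gaussian depth noise along
#' the ray and random dropout, and returns the surviving samples as a point
#' cloud in the scanner's own coordinate system (DCS) with the scanner's
#' pose attached -- exactly what a structured-light depth device would
#' deliver.
#'
#' @param phantom A [build_phantom()] result.
#' @param pose Scanner [rigid_pose()].
#' @param calib Scanner [camera_calib()].
#' @param noise_sigma Depth noise standard deviation (meters).
#' @param dropout Fraction of returns discarded at random.
#' @param clutter Number of background clutter points added uniformly in a
#'   box outside the subject area.
#' @param seed Optional seed for reproducible noise.
#' @return A [point_cloud()] in DCS.
#' @export
virtual_depth_scan <- function(phantom, pose, calib, noise_sigma = 0.002,
                               dropout = 0, clutter = 0, seed = NULL) {
  stopifnot(noise_sigma >= 0, dropout >= 0, dropout < 1)
  if (!is.null(seed)) set.seed(seed)
  W <- calib$image_size[1]
  H <- calib$image_size[2]
  O <- camera_center(pose, calib)
  xt <- rep(0:(W - 1), each = H)
  yt <- rep(0:(H - 1), times = W)
  d_ccs <- cbind((xt - calib$principal_point[1]) * calib$d,
                 (yt - calib$principal_point[2]) * calib$d, 1)
  ends <- ccs_to_ocs(d_ccs, pose, calib)
  dirs <- sweep(ends, 2, O)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rc <- cpp_raycast(phantom$mesh$vertices, phantom$mesh$triangles,
                    matrix(O, nrow(dirs), 3, byrow = TRUE), dirs)
  hit <- rc$tri > 0
  t <- rc$t[hit]
  if (noise_sigma > 0) t <- t + rnorm(length(t), 0, noise_sigma)
  pts <- sweep(dirs[hit, , drop = FALSE] * t, 2, -O)
  if (dropout > 0) {
    keep <- runif(nrow(pts)) >= dropout
    pts <- pts[keep, , drop = FALSE]
  }
  if (clutter > 0) {
    ext <- apply(phantom$mesh$vertices, 2, range)
    cl <- cbind(runif(clutter, ext[2, 1] + 0.3, ext[2, 1] + 0.8),
                runif(clutter, ext[1, 2], ext[2, 2]),
                runif(clutter, ext[1, 3], ext[2, 3]))
    pts <- rbind(pts, cl)
  }
  point_cloud(ocs_to_dcs(pts, pose), pose = pose, cs = "DCS")
}

#' Generate a complete synthetic scan session
#'
#' Produces the 8-view (per device height) set of photographs and noisy
#' depth scans of a phantom, together with all ground truth needed to
#' verify downstream processing analytically. Image and depth generation
#' share one geometry core, so a marker's position in a photograph and in a
#' scan agree by construction.
#'
#' @param phantom A [build_phantom()] result.
#' @param rig A [make_rig()] result.
#' @param noise_sigma Depth noise (meters; default 2 mm).
#' @param dropout Depth dropout fraction.
#' @param photos Render the camera images (set `FALSE` for
#'   registration-only studies).
#' @param seed Seed for all randomness in the session.
#' @return An object of class `scan_session`: `views` (camera views),
#'   `scans` (DCS point clouds), `phantom`, `rig`, `bounds` (subject crop
#'   box), `perturbations` (per-scan 4x4, identity until
#'   [perturb_session()]).
#' @export
generate_session <- function(phantom, rig, noise_sigma = 0.002,
                             dropout = 0, photos = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  views <- list()
  if (photos)
    views <- lapply(rig$cameras, function(cm)
      virtual_photograph(phantom, cm$pose, cm$calib, id = cm$id))
  scans <- lapply(rig$scanners, function(sc)
    virtual_depth_scan(phantom, sc$pose, sc$calib, noise_sigma = noise_sigma,
                       dropout = dropout))
  ext <- apply(phantom$mesh$vertices, 2, range)
  margin <- 0.1
  bounds <- subject_bounds(ext[1, ] - margin, ext[2, ] + margin)
  structure(list(views = views, scans = scans, phantom = phantom,
                 rig = rig, bounds = bounds,
                 noise_sigma = noise_sigma,
                 perturbations = rep(list(diag(4)), length(scans))),
            class = "scan_session")
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("scan_session: %d photographs, %d depth scans, %d markers\n",
              length(x$views), length(x$scans),
              length(x$phantom$markers)))
  invisible(x)
}

#' Inject pose errors into a session's depth scans
#'
#' Emulates arm-mounting inaccuracy: each scan's placement in OCS is
#' perturbed by a random rigid motion (rotation angle and translation
#' magnitude drawn uniformly within the bounds), realized by remapping the
#' stored DCS points so that the nominal pose transform reproduces the
#' perturbed placement. The exact perturbations are recorded for
#' registration-recovery tests.
#'
#' @param session A [generate_session()] result.
#' @param max_rot_deg Rotation bound (degrees).
#' @param max_trans_m Translation bound (meters).
#' @param seed Optional seed.
#' @return The session with perturbed scans and `perturbations` filled in.
#' @export
perturb_session <- function(session, max_rot_deg, max_trans_m,
                            seed = NULL) {
  stopifnot(inherits(session, "scan_session"),
            max_rot_deg >= 0, max_trans_m >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(session$scans)) {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, max_rot_deg) * pi / 180
    tdir <- rnorm(3)
    tdir <- tdir / sqrt(sum(tdir^2))
    tr <- tdir * runif(1, 0, max_trans_m)
    P <- rt_make(so3_exp(ax * ang), tr)
    cl <- session$scans[[i]]
    ocs <- dcs_to_ocs(cl$points, cl$pose)
    cl$points <- ocs_to_dcs(rt_apply(P, ocs), cl$pose)
    session$scans[[i]] <- cl
    session$perturbations[[i]] <- P
  }
  session
}
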