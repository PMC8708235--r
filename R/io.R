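# File formats: PLY point clouds and meshes, OBJ/MTL export, PNG images,
# JSON manifests for rigs and scan sessions.

#' Write a point cloud or mesh as ASCII PLY
#'
#' @param x A [point_cloud()] or [tri_mesh()].
#' @param path Output path.
#' @param comment Optional header comment line.
#' @export
write_ply <- function(x, path, comment = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con, sep = "\n")
  if (inherits(x, "point_cloud")) {
    p <- x$points
    has_n <- !is.null(x$normals)
    hdr <- c("ply", "format ascii 1.0",
             if (!is.null(comment)) paste("comment", comment),
             sprintf("element vertex %d", nrow(p)),
             "property float x", "property float y", "property float z",
             if (has_n) c("property float nx", "property float ny",
                          "property float nz"),
             "end_header")
    wl(hdr)
    dat <- if (has_n) cbind(p, x$normals) else p
    wl(apply(format(dat, digits = 9, scientific = FALSE, trim = TRUE), 1,
             paste, collapse = " "))
  } else if (inherits(x, "tri_mesh")) {
    hdr <- c("ply", "format ascii 1.0",
             if (!is.null(comment)) paste("comment", comment),
             sprintf("element vertex %d", nrow(x$vertices)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(x$triangles)),
             "property list uchar int vertex_indices", "end_header")
    wl(hdr)
    wl(apply(format(x$vertices, digits = 9, scientific = FALSE, trim = TRUE),
             1, paste, collapse = " "))
    wl(paste(3, x$triangles[, 1] - 1, x$triangles[, 2] - 1,
             x$triangles[, 3] - 1))
  } else stop("write_ply: unsupported object")
  invisible(path)
}

#' Read an ASCII or binary-little-endian PLY file
#'
#' Supports float/double vertex properties (x, y, z and optional
#' nx, ny, nz) and triangular faces; returns a [point_cloud()] when the
#' file has no faces, a [tri_mesh()] otherwise.
#'
#' @param path PLY path.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fmt <- NULL
  nvert <- 0L
  nface <- 0L
  vprops <- character()
  vtypes <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, 1)
    if (!length(line)) stop("read_ply: truncated header")
    tk <- strsplit(trimws(line), "\\s+")[[1]]
    if (tk[1] == "format") fmt <- tk[2]
    else if (tk[1] == "element") {
      in_vertex <- tk[2] == "vertex"
      if (tk[2] == "vertex") nvert <- as.integer(tk[3])
      if (tk[2] == "face") nface <- as.integer(tk[3])
    } else if (tk[1] == "property" && in_vertex && tk[2] != "list") {
      vtypes <- c(vtypes, tk[2])
      vprops <- c(vprops, tk[3])
    } else if (tk[1] == "end_header") break
  }
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
             short = 2L, ushort = 2L, int = 4L, int32 = 4L,
             uint = 4L, uint32 = 4L)
  if (fmt == "ascii") {
    vl <- readLines(con, nvert)
    vm <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                 nvert, length(vprops), byrow = TRUE)
    colnames(vm) <- vprops
    faces <- NULL
    if (nface > 0) {
      fl <- readLines(con, nface)
      fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
                   nface, 4, byrow = TRUE)
      stopifnot(all(fm[, 1] == 3))
      faces <- fm[, 2:4, drop = FALSE] + 1L
    }
  } else if (fmt == "binary_little_endian") {
    vm <- matrix(0, nvert, length(vprops))
    colnames(vm) <- vprops
    for (i in seq_len(nvert))
      for (j in seq_along(vprops)) {
        sz <- sizes[[vtypes[j]]]
        vm[i, j] <- readBin(con, if (sz >= 4 &&
                                     grepl("float|double", vtypes[j]))
          "numeric" else "integer", 1, size = sz, endian = "little")
      }
    faces <- NULL
    if (nface > 0) {
      faces <- matrix(0L, nface, 3)
      for (i in seq_len(nface)) {
        cnt <- readBin(con, "integer", 1, size = 1, endian = "little")
        stopifnot(cnt == 3)
        faces[i, ] <- readBin(con, "integer", 3, size = 4,
                              endian = "little") + 1L
      }
    }
  } else stop("read_ply: unsupported format ", fmt)
  pts <- unname(vm[, c("x", "y", "z"), drop = FALSE])
  if (!is.null(faces)) return(tri_mesh(pts, faces))
  normals <- if (all(c("nx", "ny", "nz") %in% vprops)) {
    nm <- unname(vm[, c("nx", "ny", "nz"), drop = FALSE])
    nn <- sqrt(rowSums(nm^2))
    nn[nn == 0] <- 1
    nm / nn
  } else NULL
  point_cloud(pts, normals = normals)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9f %.9f %.9f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

#' Export a textured model as OBJ + MTL
#'
#' Per-corner texture coordinates (adjacent triangles may use different
#' source views), grouped by source view with one material per view, for
#' inspection in standard mesh viewers. Unassigned triangles are written
#' without texture coordinates under a `none` material.
#'
#' @param mesh A [tri_mesh()].
#' @param assignment An [assign_textures()] result.
#' @param image_paths Character vector of texture image paths, one per
#'   view id (relative paths are kept as-is in the MTL).
#' @param image_sizes List (per view) of `c(width, height)` used to
#'   normalize pixel texture coordinates.
#' @param prefix Output prefix; writes `<prefix>.obj` and `<prefix>.mtl`.
#' @export
write_textured_obj <- function(mesh, assignment, image_paths, image_sizes,
                               prefix) {
  obj <- paste0(prefix, ".obj")
  mtl <- paste0(prefix, ".mtl")
  conm <- file(mtl, "w")
  for (v in sort(unique(stats::na.omit(assignment$view)))) {
    writeLines(c(sprintf("newmtl view%d", v), "Ka 1 1 1", "Kd 1 1 1",
                 sprintf("map_Kd %s", image_paths[v])), conm)
  }
  writeLines(c("newmtl none", "Kd 0.5 0.5 0.5"), conm)
  close(conm)
  con <- file(obj, "w")
  on.exit(close(con))
  writeLines(sprintf("mtllib %s", basename(mtl)), con)
  writeLines(sprintf("v %.9f %.9f %.9f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  vt_count <- 0L
  for (v in c(sort(unique(stats::na.omit(assignment$view))), NA)) {
    rows <- if (is.na(v)) which(is.na(assignment$view))
            else which(assignment$view == v)
    if (!length(rows)) next
    writeLines(sprintf("usemtl %s",
                       if (is.na(v)) "none" else sprintf("view%d", v)), con)
    if (is.na(v)) {
      tr <- mesh$triangles[rows, , drop = FALSE]
      writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
    } else {
      sz <- image_sizes[[v]]
      for (r in rows) {
        u <- c(assignment$u1[r], assignment$u2[r], assignment$u3[r])
        vv <- c(assignment$v1[r], assignment$v2[r], assignment$v3[r])
        # OBJ vt origin is bottom-left
        writeLines(sprintf("vt %.6f %.6f", u / (sz[1] - 1),
                           1 - vv / (sz[2] - 1)), con)
        tr <- mesh$triangles[r, ]
        writeLines(sprintf("f %d/%d %d/%d %d/%d", tr[1], vt_count + 1,
                           tr[2], vt_count + 2, tr[3], vt_count + 3), con)
        vt_count <- vt_count + 3L
      }
    }
  }
  invisible(c(obj, mtl))
}

#' Write an image array as PNG
#'
#' @param img H x W (gray) or H x W x 3 array in `[0, 1]` (row = y).
#' @param path Output path.
#' @param bits 8 or 16 bits per channel (16-bit files are written by the
#'   package's own PNG encoder).
#' @export
write_image <- function(img, path, bits = 8) {
  img <- pmin(pmax(img, 0), 1)
  if (bits == 16) return(write_png16(img, path))
  eb <- if (length(dim(img)) == 3)
    EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  else EBImage::Image(t(img))
  EBImage::writeImage(eb, path, type = "png", bits = bits)
  invisible(path)
}

#' Read a PNG image into an H x W (x C) array in `[0, 1]`
#' @param path PNG path.
#' @export
read_image <- function(path) {
  eb <- EBImage::readImage(path)
  d <- EBImage::imageData(eb)
  if (length(dim(d)) == 3) {
    d <- d[, , 1:min(3, dim(d)[3]), drop = FALSE]
    aperm(d, c(2, 1, 3))
  } else t(d)
}

#' Write a camera-rig description as JSON
#'
#' One record per view: `alpha_deg`, `h`, `r`, `Q` (row-major, 9 floats),
#' `T`, `d`, `principal_point`, `image_size`, `image_path`.
#' @param views List of [camera_view()] objects.
#' @param path JSON path.
#' @param image_paths Optional character vector of image paths per view.
#' @export
write_rig_json <- function(views, path, image_paths = NULL) {
  recs <- lapply(seq_along(views), function(i) {
    v <- views[[i]]
    list(view_id = if (is.na(v$id)) i else v$id,
         alpha_deg = v$pose$alpha * 180 / pi,
         h = v$pose$h, r = v$pose$r,
         Q = as.numeric(t(v$calib$Q)), T = v$calib$T, d = v$calib$d,
         principal_point = v$calib$principal_point,
         image_size = v$calib$image_size,
         image_path = if (is.null(image_paths)) NA else image_paths[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a camera rig JSON back into camera views
#'
#' @param path JSON written by [write_rig_json()].
#' @param dir Base directory for relative image paths; images are loaded
#'   when present.
#' @export
read_rig_json <- function(path, dir = dirname(path)) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    calib <- camera_calib(Q = matrix(unlist(r$Q), 3, 3, byrow = TRUE),
                          T = unlist(r$T), d = r$d,
                          image_size = unlist(r$image_size),
                          principal_point = unlist(r$principal_point))
    pose <- rigid_pose(r$alpha_deg, h = r$h, r = r$r, degrees = TRUE)
    img <- NULL
    if (!is.null(r$image_path) && !is.na(r$image_path)) {
      f <- file.path(dir, r$image_path)
      if (file.exists(f)) img <- read_image(f)
    }
    camera_view(pose, calib, image = img, id = r$view_id)
  })
}

#' Write a scan session to a directory
#'
#' Layout: `manifest.json` (per-scan `view_id`, `alpha_deg`, `h_D`, `r_D`,
#' `ply_path`), `rig.json` (cameras), `scans/*.ply`, `images/*.png`,
#' `ground_truth.json` (marker geometry and injected perturbations) and
#' `ground_truth_mesh.ply` (the true phantom surface).
#'
#' @param session A [generate_session()] result.
#' @param dir Output directory (created).
#' @export
write_session <- function(session, dir) {
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  manifest <- list()
  for (i in seq_along(session$scans)) {
    cl <- session$scans[[i]]
    ply <- sprintf("scans/scan_%02d.ply", i)
    write_ply(cl, file.path(dir, ply))
    manifest[[i]] <- list(view_id = i,
                          alpha_deg = cl$pose$alpha * 180 / pi,
                          h_D = cl$pose$h, r_D = cl$pose$r, ply_path = ply)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  image_paths <- character(length(session$views))
  for (i in seq_along(session$views)) {
    image_paths[i] <- sprintf("images/view_%02d.png", i)
    write_image(session$views[[i]]$image, file.path(dir, image_paths[i]))
  }
  if (length(session$views))
    write_rig_json(session$views, file.path(dir, "rig.json"), image_paths)
  gt <- list(
    markers = lapply(session$phantom$markers, function(m)
      list(id = m$id, psi_deg = m$psi * 180 / pi, y = m$y,
           diameter_m = m$diameter_m, tag_m = m$tag_m, center = m$center,
           normal = m$normal, corners = m$corners)),
    perturbations = lapply(session$perturbations, function(P)
      as.numeric(t(P))),
    bounds = list(min = session$bounds$min, max = session$bounds$max),
    noise_sigma = session$noise_sigma)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_ply(session$phantom$mesh, file.path(dir, "ground_truth_mesh.ply"),
            comment = "synthetic phantom surface (ground truth)")
  invisible(dir)
}

#' Read the depth scans of a written session
#'
#' @param dir Session directory written by [write_session()].
#' @return List with `scans` (DCS point clouds with poses), `bounds`,
#'   `views` (camera views with images, when present), `truth_mesh`,
#'   `perturbations`.
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  scans <- lapply(manifest, function(r) {
    cl <- read_ply(file.path(dir, r$ply_path))
    cl$pose <- rigid_pose(r$alpha_deg, h = r$h_D, r = r$r_D, degrees = TRUE)
    cl$cs <- "DCS"
    cl
  })
  gt_path <- file.path(dir, "ground_truth.json")
  bounds <- NULL
  perturbations <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
    bounds <- subject_bounds(unlist(gt$bounds$min), unlist(gt$bounds$max))
    perturbations <- lapply(gt$perturbations, function(v)
      matrix(unlist(v), 4, 4, byrow = TRUE))
  }
  views <- NULL
  if (file.exists(file.path(dir, "rig.json")))
    views <- read_rig_json(file.path(dir, "rig.json"), dir)
  truth <- NULL
  if (file.exists(file.path(dir, "ground_truth_mesh.ply")))
    truth <- read_ply(file.path(dir, "ground_truth_mesh.ply"))
  list(scans = scans, bounds = bounds, views = views, truth_mesh = truth,
       perturbations = perturbations)
}
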