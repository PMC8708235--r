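# Triangle-mesh container and topology checks.

#' Triangle mesh container
#'
#' @param vertices n x 3 matrix of vertex coordinates (OCS, meters).
#' @param triangles m x 3 integer matrix of 1-based vertex indices;
#'   counter-clockwise winding seen from outside (outward normals).
#' @export
tri_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, all(is.finite(vertices)),
            all(triangles >= 1), all(triangles <= nrow(vertices)))
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Number of triangles
#' @param mesh A [tri_mesh()].
#' @export
n_triangles <- function(mesh) nrow(mesh$triangles)

mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
}

#' Watertightness check
#'
#' A mesh is watertight (closed, 2-manifold and consistently oriented along
#' edges) when every undirected edge is shared by exactly two triangles and
#' traversed once in each direction.
#'
#' @param mesh A [tri_mesh()].
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (!all(cnt == 2)) return(FALSE)
  dkey <- paste(e[, 1], e[, 2])
  all(table(dkey) == 1)
}

#' Euler characteristic `V - E + F`
#'
#' Equals 2 for a closed surface of genus 0 (a topological sphere).
#' @param mesh A [tri_mesh()].
#' @export
euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - length(key) + nrow(mesh$triangles)
}

#' Per-triangle unit normals (vectorized)
#' @param mesh A [tri_mesh()].
#' @export
mesh_triangle_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$triangles
  A <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - A
  v <- V[F[, 3], , drop = FALSE] - A
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nn <- sqrt(rowSums(n^2))
  nn[nn == 0] <- 1
  n / nn
}

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted triangle choice followed by uniform barycentric sampling;
#' used for surface-distance measurements against a reference mesh.
#'
#' @param mesh A [tri_mesh()].
#' @param n Number of samples.
#' @export
sample_mesh_points <- function(mesh, n) {
  V <- mesh$vertices
  F <- mesh$triangles
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  u <- B - A
  v <- C - A
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  idx <- sample.int(nrow(F), n, replace = TRUE, prob = area)
  r1 <- sqrt(runif(n))
  r2 <- runif(n)
  w1 <- 1 - r1
  w2 <- r1 * (1 - r2)
  w3 <- r1 * r2
  A[idx, ] * w1 + B[idx, ] * w2 + C[idx, ] * w3
}

#' Distance from points to a mesh surface
#'
#' Exact point-to-triangle distances, accelerated by a centroid kd-tree
#' shortlist.
#' @param mesh A [tri_mesh()].
#' @param points n x 3 query points.
#' @export
point_mesh_distance <- function(mesh, points) {
  cpp_point_mesh_dist(mesh$vertices, mesh$triangles, as_points(points))
}
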