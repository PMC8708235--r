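# Pairwise ICP registration and loop-closure pose-graph optimization.

#' Iterative closest point (point-to-point) registration
#'
#' Refines a rigid transform aligning `source` onto `target` by alternating
#' nearest-neighbor correspondence search (capped at `max_corr_dist`) with
#' the closed-form least-squares rigid fit (SVD of the cross-covariance).
#' The RMS of correspondence distances is non-increasing over iterations up
#' to correspondence-set changes; iteration stops when its relative change
#' drops below `tol` or after `max_iter` iterations.
#'
#' Correspondence rejection: pairs farther apart than `max_corr_dist` are
#' always discarded. With `reciprocal = TRUE` (default) the iteration runs
#' in two stages: a first pass with all capped pairs (full restoring force,
#' needed to pull large misalignments in), then a refinement pass keeping
#' only mutual nearest-neighbor pairs, which removes the drag exerted by
#' regions one view covers and the other does not (coverage silhouettes) --
#' a bias worth several millimeters on partially overlapping scans. `trim`
#' additionally keeps only the given distance quantile of accepted pairs.
#'
#' @param source,target [point_cloud()] objects in the same coordinate
#'   system (points are used; normals are ignored).
#' @param init Initial 4x4 rigid transform applied to `source`.
#' @param max_corr_dist Maximum correspondence distance (meters).
#' @param max_iter Iteration cap.
#' @param tol Relative RMS-change convergence tolerance.
#' @param reciprocal Run the mutual-nearest-neighbor refinement stage.
#' @param trim Distance quantile of accepted pairs kept per iteration
#'   (1 = no trimming).
#' @param normal_max_angle When both clouds carry normals, pairs whose
#'   normals disagree by more than this angle (degrees) are rejected --
#'   this stops wrong-side matches across thin structures such as arms.
#'   Set `NULL` to ignore normals.
#' @return A list with `transform` (4x4, maps source points onto target),
#'   `rms` (final RMS residual, meters), `n_corr`, `iterations` (total
#'   over both stages), `converged`.
#' @export
icp_register <- function(source, target, init = diag(4),
                         max_corr_dist = 0.02, max_iter = 50, tol = 1e-6,
                         reciprocal = TRUE, trim = 1.0,
                         normal_max_angle = 60) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"),
            max_corr_dist > 0, max_iter >= 1, trim > 0, trim <= 1)
  use_n <- !is.null(normal_max_angle) && !is.null(source$normals) &&
    !is.null(target$normals)
  res <- cpp_icp(source$points, target$points, init, max_corr_dist,
                 as.integer(max_iter), tol, reciprocal, trim,
                 if (use_n) source$normals else NULL,
                 if (use_n) target$normals else NULL,
                 if (use_n) cos(normal_max_angle * pi / 180) else 0.5)
  res$transform <- matrix(res$transform, 4, 4)
  res
}

#' Loop-closure pose-graph optimization over a cycle of registrations
#'
#' Takes the sequential pairwise transforms around the ring of views (edge
#' `i` maps view `i+1` onto view `i`; the last edge maps view 1 onto the
#' last view, closing the loop) and distributes the cycle-closure error by
#' Gauss-Newton over per-view correction poses (view 1 held fixed),
#' minimizing the squared SE(3) log of each edge's residual. The corrected
#' edges compose exactly to the identity around the loop.
#'
#' @param pairwise List of 4x4 rigid transforms forming a cycle.
#' @param max_iter Gauss-Newton iteration cap.
#' @param tol Convergence tolerance on the summed squared residual.
#' @return A list with `transforms` (corrected edges), `poses` (per-view
#'   4x4 corrections `X_i`, `X_1 = I`), `residual0` and `residual` (summed
#'   squared edge residuals before/after).
#' @export
close_loop <- function(pairwise, max_iter = 50, tol = 1e-12) {
  nv <- length(pairwise)
  stopifnot(nv >= 2)
  # edge i: view i -> view j = i %% nv + 1, measurement Z_ij = A_ij with
  # A_ij p_j ~ p_i, so ideally X_i^-1 X_j = Z_ij... with our convention
  # A maps j-frame points into i-frame: X_i A_ij = X_j => residual
  # log( (X_i Z_ij)^-1 X_j )
  Z <- pairwise
  X <- rep(list(diag(4)), nv)

  pack <- function(X) unlist(lapply(X[-1], function(M)
    c(so3_log(M[1:3, 1:3]), M[1:3, 4])))
  unpack <- function(th) {
    out <- rep(list(diag(4)), nv)
    for (i in 2:nv) {
      v <- th[(6 * (i - 2) + 1):(6 * (i - 2) + 6)]
      out[[i]] <- rt_make(so3_exp(v[1:3]), v[4:6])
    }
    out
  }
  resid <- function(th) {
    X <- unpack(th)
    r <- numeric(0)
    for (i in seq_len(nv)) {
      j <- i %% nv + 1
      E <- solve(X[[i]] %*% Z[[i]]) %*% X[[j]]
      r <- c(r, so3_log(E[1:3, 1:3]), E[1:3, 4])
    }
    r
  }
  th <- pack(X)
  r <- resid(th)
  residual0 <- sum(r^2)
  best <- residual0
  lambda <- 1e-6
  for (it in seq_len(max_iter)) {
    # numeric Jacobian (small problem: 6*(nv-1) params, 6*nv residuals)
    J <- matrix(0, length(r), length(th))
    h <- 1e-7
    for (p in seq_along(th)) {
      tp <- th
      tp[p] <- tp[p] + h
      J[, p] <- (resid(tp) - r) / h
    }
    step <- tryCatch(
      solve(t(J) %*% J + lambda * diag(ncol(J)), -t(J) %*% r),
      error = function(e) NULL)
    if (is.null(step)) break
    th_new <- th + as.numeric(step)
    r_new <- resid(th_new)
    if (sum(r_new^2) < best) {
      th <- th_new
      r <- r_new
      best <- sum(r^2)
      lambda <- max(lambda / 2, 1e-10)
      if (best < tol) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  X <- unpack(th)
  corrected <- lapply(seq_len(nv), function(i) {
    j <- i %% nv + 1
    solve(X[[i]]) %*% X[[j]]
  })
  list(transforms = corrected, poses = X, residual0 = residual0,
       residual = best)
}

#' Ring registration of a cycle of views with loop closure
#'
#' Registers the closed ring of views (each view against its successor,
#' the last against the first) with pairwise ICP, closes the loop by pose-
#' graph optimization, and repeats coarse-to-fine: each round applies the
#' current corrections and re-registers with a tighter correspondence cap,
#' so residual per-edge biases shrink toward the aligned-start level.
#'
#' @param clouds List of [point_cloud()]s in a common coordinate system,
#'   ordered around the ring.
#' @param caps Correspondence-distance cap per round (meters); the length
#'   gives the number of rounds.
#' @param source_max Per-registration cap on source points (the
#'   correspondence discretization error is set by the target density, so
#'   sources can be subsampled for speed without losing accuracy).
#' @param ... Further arguments passed to [icp_register()].
#' @return List with `poses` (per-view corrections, view 1 = identity),
#'   `edges` (corrected pairwise transforms, composing exactly to the
#'   identity around the ring), `rms` (per-edge final ICP residuals of the
#'   last round).
#' @export
register_ring <- function(clouds, caps = c(0.02, 0.008, 0.005),
                          source_max = 30000, ...) {
  nv <- length(clouds)
  stopifnot(nv >= 3)
  sub <- lapply(clouds, function(cl) {
    if (n_points(cl) <= source_max) return(cl)
    idx <- sample.int(n_points(cl), source_max)
    subset_cloud(cl, idx)
  })
  X <- rep(list(diag(4)), nv)
  rms <- rep(NA_real_, nv)
  for (cap in caps) {
    cur <- lapply(seq_len(nv), function(i) {
      cl <- clouds[[i]]
      cl$points <- rt_apply(X[[i]], cl$points)
      if (!is.null(cl$normals))
        cl$normals <- cl$normals %*% t(X[[i]][1:3, 1:3])
      cl
    })
    cur_sub <- lapply(seq_len(nv), function(i) {
      cl <- sub[[i]]
      cl$points <- rt_apply(X[[i]], cl$points)
      if (!is.null(cl$normals))
        cl$normals <- cl$normals %*% t(X[[i]][1:3, 1:3])
      cl
    })
    edges <- vector("list", nv)
    for (i in seq_len(nv)) {
      j <- i %% nv + 1
      reg <- icp_register(cur_sub[[j]], cur[[i]], max_corr_dist = cap, ...)
      edges[[i]] <- reg$transform
      rms[i] <- reg$rms
    }
    lc <- close_loop(edges)
    X <- lapply(seq_len(nv), function(i) lc$poses[[i]] %*% X[[i]])
  }
  edges <- lapply(seq_len(nv), function(i) {
    j <- i %% nv + 1
    solve(X[[i]]) %*% X[[j]]
  })
  list(poses = X, edges = edges, rms = rms)
}

#' Compose the transforms around a cycle
#'
#' Utility for loop-consistency checks: returns
#' `T[[1]] %*% T[[2]] %*% ... %*% T[[n]]`, which is the identity for a
#' perfectly consistent ring of pairwise registrations.
#' @param transforms List of 4x4 transforms.
#' @export
compose_cycle <- function(transforms) {
  Reduce(`%*%`, transforms, accumulate = FALSE)
}
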