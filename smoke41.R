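library(dermascan)
set.seed(4)
ph <- build_phantom(phantom_spec(), n_theta = 10, ring_step = 0.4)  # coarse ~ 50-100 tris
cat("ntri:", n_triangles(ph$mesh), "\n")
pose <- rigid_pose(0, 0.95, 0.9)
cal <- camera_calib(d = 2e-3, image_size = c(64, 64))
view <- camera_view(pose, cal, id = 1L)
buf <- render_mosaic(ph$mesh, view)
# R raycast oracle (independent: Moller-Trumbore in R)
O <- camera_center(pose, cal)
xt <- rep(0:63, each = 64); yt <- rep(0:63, times = 64)
d_ccs <- cbind((xt - cal$principal_point[1]) * cal$d,
               (yt - cal$principal_point[2]) * cal$d, 1)
ends <- ccs_to_ocs(d_ccs, pose, cal)
dirs <- sweep(ends, 2, O)
V <- ph$mesh$vertices; F <- ph$mesh$triangles
best_t <- rep(Inf, nrow(dirs)); best_id <- integer(nrow(dirs))
for (t in seq_len(nrow(F))) {
  A <- V[F[t,1],]; E1 <- V[F[t,2],]-A; E2 <- V[F[t,3],]-A
  pv <- cbind(dirs[,2]*E2[3]-dirs[,3]*E2[2], dirs[,3]*E2[1]-dirs[,1]*E2[3], dirs[,1]*E2[2]-dirs[,2]*E2[1])
  det <- pv %*% E1
  tv <- sweep(matrix(O,nrow(dirs),3,byrow=TRUE), 2, A)
  u <- rowSums(tv*pv)/det
  qv <- cbind(tv[,2]*E1[3]-tv[,3]*E1[2], tv[,3]*E1[1]-tv[,1]*E1[3], tv[,1]*E1[2]-tv[,2]*E1[1])
  v <- rowSums(dirs*qv)/det
  tt <- (qv %*% E2)/det
  hit <- abs(det) > 1e-14 & u >= 0 & u <= 1 & v >= 0 & u+v <= 1 & tt > 1e-9 & tt < best_t
  best_t[hit] <- tt[hit]; best_id[hit] <- t
}
oracle <- matrix(0L, 64, 64)
oracle[cbind(yt+1, xt+1)] <- best_id
agree <- mean(buf$index == oracle)
cat("index agreement:", agree, " fg px:", sum(oracle>0), "\n")
disg <- which(buf$index != oracle)
cat("disagreements:", length(disg), "\n")
# pick -> reproject
sel <- which(buf$index > 0)
err <- c()
for (k in sample(sel, 200)) {
  x <- (k-1) %/% 64; y <- (k-1) %% 64
  p <- pick(c(x, y), buf, ph$mesh)
  px <- project_pinhole(ocs_to_ccs(p$V, pose, cal), cal)
  err <- c(err, sqrt(sum((px - c(x,y))^2)))
}
cat("pick reproject: max err px:", max(err), "\n")
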