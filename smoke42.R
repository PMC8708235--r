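library(dermascan)
set.seed(2)
psis <- (0:11) * 68 / 11
rows <- rep(c(0.8, 1.05, 1.3), 4)
mk <- data.frame(psi_deg = psis, y = rows)
spec <- phantom_spec(markers = mk)
ph <- build_phantom(spec, n_theta = 96, ring_step = 0.015)
cal <- camera_calib(d = 2.5e-4, image_size = c(1440, 960))
hs <- c(0.85, 1.0, 1.25)
t0 <- Sys.time()
views <- lapply(1:3, function(i)
  virtual_photograph(ph, rigid_pose(0, hs[i], 0.9), cal, id = i))
cat("render:", format(Sys.time()-t0), "\n")
vids <- match(rows, c(0.8, 1.05, 1.3))
t0 <- Sys.time()
meas <- measure_session_markers(ph$mesh, views, ph$markers, s = 10, view_ids = vids)
cat("measure:", format(Sys.time()-t0), "\n")
print(meas[, c("marker","condition","ratio","area_cm2","angle_deg")])
orig <- meas[meas$condition=="original",]
rect <- meas[meas$condition=="orthorectified",]
cat("mean original ratio:", mean(orig$ratio, na.rm=TRUE),
    "; mean ortho ratio:", mean(rect$ratio, na.rm=TRUE), "\n")
cat("mean ortho area:", mean(rect$area_cm2, na.rm=TRUE), "(pi =", pi, ")\n")
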