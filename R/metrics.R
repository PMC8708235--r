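# Marker-morphology metrics for quantitative assessment of rectification.

#' Segment the central dark marker disk in a patch
#'
#' Thresholds the patch by maximizing between-class variance (Otsu) on its
#' gray-level histogram, labels dark connected components, keeps the one
#' covering (or nearest to) the patch center, and fills its holes.
#' Deterministic given the patch.
#'
#' @param patch An [orthorectify()] result, an H x W gray matrix, or an
#'   H x W x 3 array in `[0, 1]`.
#' @param center `c(x, y)` pixel the marker must touch; defaults to the
#'   image center.
#' @return Logical H x W mask.
#' @export
segment_marker <- function(patch, center = NULL) {
  img <- if (inherits(patch, "ortho_patch")) patch$image else patch
  gray <- if (length(dim(img)) == 3)
    (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
  gray <- pmin(pmax(gray, 0), 1)
  H <- nrow(gray)
  W <- ncol(gray)
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)
  eb <- EBImage::Image(t(gray))  # EBImage stores images x-major
  thr <- EBImage::otsu(eb, range = c(0, 1), levels = 256)
  mask <- gray < thr
  if (!any(mask)) stop("segment_marker: no dark component found")
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labm <- t(EBImage::imageData(lab))  # back to row = y
  crow <- round(center[2]) + 1
  ccol <- round(center[1]) + 1
  id <- labm[crow, ccol]
  if (id == 0) {
    # nearest labelled pixel to the center
    sel <- which(labm > 0)
    rows <- (sel - 1) %% H + 1
    cols <- (sel - 1) %/% H + 1
    d2 <- (rows - crow)^2 + (cols - ccol)^2
    id <- labm[sel[which.min(d2)]]
  }
  comp <- labm == id
  filled <- EBImage::fillHull(EBImage::Image(t(comp)))
  t(EBImage::imageData(filled)) > 0
}

#' Fit an ellipse to a binary mask by second central moments
#'
#' Semi-axes are derived from the eigenvalues of the covariance of the mask
#' pixel coordinates (`a = 2 sqrt(lambda1)`, `b = 2 sqrt(lambda2)`), which
#' is exact for a filled ellipse. Moment-based fitting is deterministic and
#' has no iterative failure modes.
#'
#' @param mask Logical matrix (row = y, col = x).
#' @return List with `a`, `b` (semi-axes, pixels, `a >= b`), `ratio`
#'   (`a/b`), `center` (`c(x, y)`, 0-based), `angle` (major-axis
#'   orientation, radians).
#' @export
fit_ellipse <- function(mask) {
  sel <- which(mask)
  if (length(sel) == 0) stop("fit_ellipse: empty mask")
  H <- nrow(mask)
  ys <- (sel - 1) %% H
  xs <- (sel - 1) %/% H
  n <- length(sel)
  mx <- mean(xs)
  my <- mean(ys)
  cxx <- sum((xs - mx)^2) / n
  cyy <- sum((ys - my)^2) / n
  cxy <- sum((xs - mx) * (ys - my)) / n
  C <- matrix(c(cxx, cxy, cxy, cyy), 2, 2)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] <= 0) stop("fit_ellipse: degenerate (zero-variance) mask")
  a <- 2 * sqrt(e$values[1])
  b <- 2 * sqrt(e$values[2])
  list(a = a, b = b, ratio = a / b, center = c(mx, my),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

#' Physical marker area from a mask
#'
#' Pixel count divided by the squared scale, in cm^2. For an ideal 2 cm
#' diameter disk the true value is `pi * 1^2 = pi` cm^2.
#'
#' @param mask Logical matrix.
#' @param scale Scale in pixels per millimeter (> 0).
#' @export
marker_area <- function(mask, scale) {
  stopifnot(scale > 0)
  sum(mask) / scale^2 / 100  # px -> mm^2 -> cm^2
}

#' Shear angle of a rectangular tag
#'
#' The deviation from a right angle between the two tag edges meeting at
#' the first corner: `|angle - 90|` in degrees. Zero for an unsheared
#' rectangle; invariant to uniform scaling.
#'
#' @param corners 4 x 2 matrix of corner coordinates ordered around the
#'   tag.
#' @export
shear_angle <- function(corners) {
  corners <- as.matrix(corners)
  stopifnot(all(dim(corners) == c(4, 2)))
  e1 <- corners[2, ] - corners[1, ]
  e2 <- corners[4, ] - corners[1, ]
  n1 <- sqrt(sum(e1^2))
  n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0 || abs(abs(sum(e1 * e2)) - n1 * n2) < 1e-12)
    stop("shear_angle: collinear corners")
  ang <- acos(min(1, max(-1, sum(e1 * e2) / (n1 * n2)))) * 180 / pi
  abs(ang - 90)
}

#' Aggregate per-marker measurements into a comparison report
#'
#' Computes, per condition (original vs orthorectified) and attribute, the
#' mean and the relative standard deviation (sd/mean), mirroring the layout
#' used to compare marker morphology before and after rectification.
#'
#' @param measurements Data frame with columns `marker`, `condition`, and
#'   one or more of `angle_deg`, `ratio`, `area_cm2`.
#' @return An object of class `marker_report`: list with `table` (one row
#'   per attribute x condition: `mean`, `rel_sd`) and the raw
#'   `measurements`.
#' @export
aggregate_report <- function(measurements) {
  stopifnot(nrow(measurements) >= 1,
            all(c("marker", "condition") %in% names(measurements)))
  attrs <- intersect(c("angle_deg", "ratio", "area_cm2"),
                     names(measurements))
  rows <- list()
  for (cond in unique(measurements$condition)) {
    sub <- measurements[measurements$condition == cond, , drop = FALSE]
    for (at in attrs) {
      v <- sub[[at]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      m <- mean(v)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, attribute = at, mean = m,
        rel_sd = if (length(v) > 1 && m != 0) sd(v) / m else 0,
        n = length(v))
    }
  }
  structure(list(table = do.call(rbind, rows), measurements = measurements),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("marker_report (mean, relative sd in brackets):\n")
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-15s %-10s %8.3f (%.3f)  n=%d\n", tb$condition[i],
                tb$attribute[i], tb$mean[i], tb$rel_sd[i], tb$n[i]))
  invisible(x)
}

#' Write a marker report as CSV and JSON
#'
#' CSV holds one row per marker per condition; the JSON summary mirrors the
#' aggregate table.
#' @param report An [aggregate_report()] result.
#' @param prefix Output path prefix.
#' @export
write_report <- function(report, prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  write.csv(report$measurements, csv, row.names = FALSE)
  jsonlite::write_json(report$table, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
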