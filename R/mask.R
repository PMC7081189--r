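#' Detect stationary tissue for background fitting
#'
#' Reproduces the clinical workflow for stationary-tissue background
#' correction: include as much static tissue as possible by thresholding
#' the per-pixel phase deviation, then exclude non-static regions (lungs,
#' major vessels) with exclusion ROIs.
#'
#' A pixel is static iff all of the following hold:
#' \itemize{
#'   \item the temporal standard deviation of its velocity across frames is
#'     at most `sd_threshold` (the "phase deviation threshold", cm/s);
#'   \item its time-averaged magnitude is at least `mag_threshold` times the
#'     median time-averaged magnitude over the image (guards against
#'     air/lung where phase is pure noise);
#'   \item it lies outside every exclusion ROI and every vessel ROI.
#' }
#'
#' @param series a [pc_series()] with at least 2 frames.
#' @param sd_threshold phase deviation threshold, cm/s: temporal SD of
#'   velocity above this excludes the pixel. Raising it only ever adds
#'   pixels.
#' @param mag_threshold magnitude gate as a fraction of the image-median
#'   time-averaged magnitude.
#' @param exclusion_rois list of ROIs to exclude; each either a polygon
#'   (n x 2 matrix of `(row, col)` pixel coordinates, 1-based) or a logical
#'   matrix of the image size.
#' @param vessel_rois list of vessel ROIs, same forms; always excluded from
#'   the static mask.
#'
#' @return An object of class `static_mask`: list with `mask` (logical
#'   matrix), the thresholds, the ROIs, and `n_static`.
#' @seealso [fit_background()], [point_in_polygon()]
#' @export
detect_static <- function(series, sd_threshold = 2, mag_threshold = 0.3,
                          exclusion_rois = list(), vessel_rois = list()) {
  stopifnot(inherits(series, "pc_series"))
  if (n_frames(series) < 2L)
    stop("need at least 2 frames to measure phase deviation")
  if (sd_threshold <= 0 || mag_threshold <= 0)
    stop("thresholds must be positive")

  d <- dim(series$velocity)
  sd_map <- temporal_sd(series$velocity)
  mean_mag <- apply(series$magnitude, c(1L, 2L), mean)
  mag_ref <- stats::median(mean_mag)

  pass_sd <- sd_map <= sd_threshold
  pass_mag <- mean_mag >= mag_threshold * mag_ref
  excl <- roi_union(c(exclusion_rois, vessel_rois), d[1L], d[2L])

  mask <- pass_sd & pass_mag & !excl
  if (!any(mask)) {
    culprit <- if (!any(pass_sd)) "the phase deviation threshold"
    else if (!any(pass_sd & pass_mag)) "the magnitude threshold"
    else "the exclusion/vessel ROIs"
    stop("static mask is empty: ", culprit, " removed the last pixels")
  }
  structure(
    list(mask = mask, sd_threshold = sd_threshold,
         mag_threshold = mag_threshold,
         exclusion_rois = exclusion_rois, vessel_rois = vessel_rois,
         n_static = sum(mask)),
    class = "static_mask"
  )
}

#' @export
print.static_mask <- function(x, ...) {
  cat(sprintf(
    "Static-tissue mask: %d pixels (%.0f%% of image); SD <= %.2g cm/s, magnitude >= %.2g x median\n",
    x$n_static, 100 * mean(x$mask), x$sd_threshold, x$mag_threshold))
  invisible(x)
}

# per-pixel temporal SD across frames, vectorized over the pixel grid
temporal_sd <- function(v) {
  d <- dim(v)
  m <- matrix(v, d[1L] * d[2L], d[3L])
  mu <- rowMeans(m)
  matrix(sqrt(rowSums((m - mu)^2) / (d[3L] - 1L)), d[1L], d[2L])
}

# union of ROIs (polygons or logical matrices) as one logical matrix
roi_union <- function(rois, n_rows, n_cols) {
  out <- matrix(FALSE, n_rows, n_cols)
  for (roi in rois) {
    if (is.logical(roi)) {
      if (!identical(dim(roi), c(n_rows, n_cols)))
        stop("logical ROI dimensions do not match the image")
      out <- out | roi
    } else {
      out <- out | polygon_mask(roi, n_rows, n_cols)
    }
  }
  out
}

# rasterize a polygon to the pixel grid via point_in_polygon on centers
polygon_mask <- function(polygon, n_rows, n_cols) {
  polygon <- as.matrix(polygon)
  rows <- matrix(seq_len(n_rows), n_rows, n_cols)
  cols <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  # restrict the test to the polygon's bounding box
  out <- matrix(FALSE, n_rows, n_cols)
  in_box <- rows >= floor(min(polygon[, 1L])) & rows <= ceiling(max(polygon[, 1L])) &
    cols >= floor(min(polygon[, 2L])) & cols <= ceiling(max(polygon[, 2L]))
  idx <- which(in_box)
  if (length(idx))
    out[idx] <- point_in_polygon(cbind(rows[idx], cols[idx]), polygon)
  out
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Even-odd (ray-crossing) membership test used to rasterize exclusion and
#' vessel ROIs. Points on a polygon edge or vertex count as inside.
#'
#' @param points numeric vector `c(row, col)` or an n x 2 matrix of points.
#' @param polygon m x 2 matrix of vertices (m >= 3), implicitly closed.
#' @return logical vector, one entry per point.
#' @export
point_in_polygon <- function(points, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    stop("polygon must have at least 3 vertices")
  if (max(abs(polygon[1L, ] - polygon[nrow(polygon), ])) < 1e-12)
    polygon <- polygon[-nrow(polygon), , drop = FALSE]
  if (nrow(polygon) < 3L || nrow(unique(polygon)) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)

  px <- points[, 1L]; py <- points[, 2L]
  n <- nrow(polygon)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1L]; yi <- polygon[i, 2L]
    xj <- polygon[j, 1L]; yj <- polygon[j, 2L]
    # boundary: point collinear with and between the segment endpoints
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    dot <- (px - xi) * (xj - xi) + (py - yi) * (yj - yi)
    on_edge <- on_edge |
      (abs(cross) <= 1e-9 * max(1, sqrt(seg_len2)) &
         dot >= -1e-9 & dot <= seg_len2 + 1e-9)
    # even-odd crossing of a horizontal ray in +col direction
    crosses <- ((yi > py) != (yj > py)) &
      (px < xi + (xj - xi) * (py - yi) / (yj - yi))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}
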