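# Small, fast phantom used throughout the unit tests: 32 x 32 grid at 5 mm
# spacing (160 mm FOV), 10 frames. Same anatomy as the default geometry.
tiny_params <- function(...) {
  phantom_params(grid_rows = 32, grid_cols = 32, pixel_spacing = 5,
                 n_frames = 10, ...)
}

# standard mask for a phantom: simulator labels supply the reader's ROIs
phantom_mask <- function(ph, sd_threshold = 2, mag_threshold = 0.3) {
  detect_static(ph$series, sd_threshold, mag_threshold,
                exclusion_rois = list(ph$truth$lung_mask),
                vessel_rois = ph$truth$vessel_masks)
}

# independent brute-force OLS oracle: explicit normal equations, with the
# design built pixel by pixel (no shared code with fit_background)
ols_oracle <- function(vbar, mask, order) {
  nr <- nrow(vbar); nc <- ncol(vbar)
  rows <- NULL
  y <- c()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    x <- if (nc > 1) 2 * (j - 1) / (nc - 1) - 1 else 0
    yy <- if (nr > 1) 2 * (i - 1) / (nr - 1) - 1 else 0
    r <- c(1, x, yy)
    if (order == 2) r <- c(r, x^2, yy^2, x * yy)
    rows <- rbind(rows, r)
    y <- c(y, vbar[i, j])
  }
  solve(t(rows) %*% rows, t(rows) %*% y)[, 1]
}

# draw reproducibly without disturbing the ambient RNG stream
with_seed_keep <- function(seed, code) pcflow:::with_seed(seed, code)

# winding-number (angle-sum) point-in-polygon oracle for simple polygons;
# only valid for points off the boundary
winding_inside <- function(pt, polygon) {
  v <- sweep(rbind(polygon, polygon[1, ]), 2, pt)
  ang <- atan2(v[, 2], v[, 1])
  d <- diff(ang)
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi
}
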