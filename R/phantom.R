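#' Parameters for a synthetic phase-contrast phantom
#'
#' Describes a through-plane phase-contrast cine acquisition of a chest
#' slice containing two circular vessels (ascending aorta and main
#' pulmonary artery) with pulsatile parabolic flow, surrounded by static
#' tissue, with low-magnitude/high-phase-noise lung fields laterally, and an
#' additive spatially smooth background velocity offset modelling
#' eddy-current phase errors.
#'
#' Vessel centers and lung extents are given as fractions of the image so
#' the same geometry holds at any matrix size. Vessel membership is by
#' pixel-center-in-circle with no partial-volume weighting; the flow ROI
#' used downstream is the identical pixel set, so the discrete ground-truth
#' stroke volume is exact.
#'
#' The temporal waveform is a half-sinusoid systolic ejection over the
#' first `systole_fraction` of the cycle plus a small constant diastolic
#' component (`diastolic_level` relative to unit systolic peak); the peak
#' velocity is scaled so the discrete pixel sum hits the target stroke
#' volume exactly.
#'
#' Phase noise is independent Gaussian on velocity with per-pixel SD
#' `venc / (pi * snr_tissue * m_rel)` where `m_rel` is the local magnitude
#' relative to tissue: noise inflates where magnitude is low (lung), which
#' is exactly what the exclusion-ROI step of static-tissue correction
#' exists to handle. Lung magnitude is `snr_lung / snr_tissue`, so lung
#' pixels have velocity-noise SD `venc / (pi * snr_lung)`.
#'
#' @param grid_rows,grid_cols image matrix size in pixels.
#' @param pixel_spacing in-plane pixel spacing, mm.
#' @param n_frames cine frames per cardiac cycle (>= 8).
#' @param rr_interval mean R-R interval, ms.
#' @param venc velocity-encoding limit, cm/s; must exceed the peak
#'   noise-free velocity (no aliasing).
#' @param vessels named list of vessel specifications, each a list with
#'   `center` (fractional `c(row, col)` position), `radius` (mm) and
#'   `stroke_volume` (ml net per cycle).
#' @param systole_fraction fraction of the cycle occupied by the
#'   half-sinusoid systolic ejection.
#' @param diastolic_level constant diastolic flow component relative to
#'   the unit systolic peak.
#' @param background_order polynomial order of the background velocity
#'   offset: 0 (constant), 1 (linear) or 2 (quadratic).
#' @param background_coeffs background polynomial coefficients in cm/s, in
#'   normalized image coordinates `x, y` in `[-1, 1]`: `(a00)` for order 0,
#'   `(a00, a10, a01)` for order 1, `(a00, a10, a01, a20, a02, a11)` for
#'   order 2 (basis `1, x, y, x^2, y^2, xy`).
#' @param snr_tissue magnitude signal-to-noise ratio of static tissue; may
#'   be `Inf` for a noise-free phantom.
#' @param snr_lung magnitude SNR of lung; sets lung magnitude relative to
#'   tissue.
#' @param lung_rows,lung_cols fractional extents of the two lateral lung
#'   fields: rows `c(from, to)` shared by both lungs, cols `c(width_left,
#'   start_right)` — the left lung spans columns `[0, width_left]`, the
#'   right `[start_right, 1]`.
#' @param rr_series beat-to-beat R-R intervals (ms) recorded during the
#'   acquisition; defaults to a constant series at `rr_interval`.
#' @param seed integer seed fixing all randomness in [make_phantom()].
#'
#' @return A validated list of class `phantom_params`.
#' @seealso [make_phantom()], [make_cohort()]
#' @export
phantom_params <- function(grid_rows = 96, grid_cols = 96,
                           pixel_spacing = 2.5,
                           n_frames = 30, rr_interval = 1000, venc = 150,
                           vessels = list(
                             aorta = list(center = c(0.45, 0.40),
                                          radius = 15, stroke_volume = 90),
                             pa = list(center = c(0.40, 0.63),
                                       radius = 16, stroke_volume = 90)
                           ),
                           systole_fraction = 0.4, diastolic_level = 0.05,
                           background_order = 1,
                           background_coeffs = c(0, 0, 0),
                           snr_tissue = 30, snr_lung = 3,
                           lung_rows = c(0.15, 0.85),
                           lung_cols = c(0.18, 0.82),
                           rr_series = NULL, seed = 1L) {
  p <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pixel_spacing = pixel_spacing, n_frames = as.integer(n_frames),
    rr_interval = rr_interval, venc = venc, vessels = vessels,
    systole_fraction = systole_fraction, diastolic_level = diastolic_level,
    background_order = as.integer(background_order),
    background_coeffs = background_coeffs,
    snr_tissue = snr_tissue, snr_lung = snr_lung,
    lung_rows = lung_rows, lung_cols = lung_cols,
    rr_series = if (is.null(rr_series)) rep(rr_interval, 117L) else rr_series,
    seed = as.integer(seed)
  )
  validate_phantom_params(p)
  class(p) <- "phantom_params"
  p
}

n_background_coeffs <- function(order) c(1L, 3L, 6L)[order + 1L]

validate_phantom_params <- function(p) {
  if (p$n_frames < 8L)
    stop("`n_frames` must be >= 8")
  if (p$grid_rows < 8L || p$grid_cols < 8L)
    stop("grid must be at least 8 x 8")
  if (!p$background_order %in% 0:2)
    stop("`background_order` must be 0, 1 or 2")
  if (length(p$background_coeffs) != n_background_coeffs(p$background_order))
    stop(sprintf("order %d background needs %d coefficients, got %d",
                 p$background_order,
                 n_background_coeffs(p$background_order),
                 length(p$background_coeffs)))
  if (length(p$vessels) < 1L || is.null(names(p$vessels)))
    stop("`vessels` must be a named list")
  for (nm in names(p$vessels)) {
    v <- p$vessels[[nm]]
    if (v$radius <= 2 * p$pixel_spacing)
      stop(sprintf("vessel '%s': radius must exceed 2 * pixel_spacing", nm))
    if (v$stroke_volume <= 0)
      stop(sprintf("vessel '%s': stroke volume must be positive", nm))
  }
  if (!(p$snr_tissue > 0) || !(p$snr_lung > 0))
    stop("SNR values must be positive")
  if (p$systole_fraction <= 0 || p$systole_fraction >= 1)
    stop("`systole_fraction` must be in (0, 1)")
  invisible(p)
}

# pulsatile waveform (unit systolic peak) sampled at the frame times
phantom_waveform <- function(p) {
  t_frac <- (seq_len(p$n_frames) - 1L) / p$n_frames
  s <- ifelse(t_frac < p$systole_fraction,
              sin(pi * t_frac / p$systole_fraction), 0)
  s + p$diastolic_level
}

# evaluate the background polynomial (cm/s) on the full grid
background_surface <- function(coeffs, order, n_rows, n_cols) {
  co <- normalized_coords(n_rows, n_cols)
  b <- matrix(coeffs[1L], n_rows, n_cols)
  if (order >= 1L) b <- b + coeffs[2L] * co$x + coeffs[3L] * co$y
  if (order >= 2L) b <- b + coeffs[4L] * co$x^2 + coeffs[5L] * co$y^2 +
      coeffs[6L] * co$x * co$y
  b
}

#' Generate a synthetic phase-contrast phantom with exact ground truth
#'
#' Builds the cine series described by a [phantom_params()] object:
#' velocity = vessel parabolic pulsatile profile (zero outside vessels)
#' + background polynomial + zero-mean Gaussian phase noise, together with
#' the ground truth needed to test every downstream stage (true background
#' coefficients, exact per-vessel net stroke volumes, true Qp/Qs, and the
#' static / vessel / lung label maps).
#'
#' The ground-truth net volume of each vessel is, by construction, the
#' discrete sum over that vessel's labelled pixels of the noise-free,
#' background-free velocity times pixel area times frame duration — so
#' [flow_curve()] on a noise-free, background-free phantom recovers it to
#' floating-point precision.
#'
#' @param params a [phantom_params()] object.
#' @return A list of class `pc_phantom` with elements `series` (a
#'   [pc_series()]) and `truth` (list: `background_coeffs`,
#'   `background_order`, `stroke_volumes` named ml vector, `qpqs` = PA net
#'   over aortic net when both vessels are present, `labels` integer matrix
#'   (0 static, 1.. vessels in order, 99 lung), `static_mask`,
#'   `vessel_masks`, `lung_mask` logical matrices, `rr_series`).
#' @examples
#' ph <- make_phantom(phantom_params(snr_tissue = Inf,
#'                                   background_coeffs = c(0, 0, 0)))
#' fr <- flow_curve(ph$series, ph$truth$vessel_masks$aorta)
#' all.equal(fr$net_volume, ph$truth$stroke_volumes[["aorta"]])
#' @export
make_phantom <- function(params) {
  p <- validate_phantom_params(params)
  nr <- p$grid_rows; nc <- p$grid_cols
  npix <- nr * nc
  # pixel-center positions in mm
  row_mm <- (seq_len(nr) - 0.5) * p$pixel_spacing
  col_mm <- (seq_len(nc) - 0.5) * p$pixel_spacing
  rr_mm <- matrix(row_mm, nr, nc)
  cc_mm <- matrix(col_mm, nr, nc, byrow = TRUE)

  labels <- matrix(0L, nr, nc)
  lung <- matrix(FALSE, nr, nc)
  lr <- p$lung_rows * nr * p$pixel_spacing
  lc <- p$lung_cols * nc * p$pixel_spacing
  lung[rr_mm >= lr[1L] & rr_mm <= lr[2L] &
         (cc_mm <= lc[1L] | cc_mm >= lc[2L])] <- TRUE
  labels[lung] <- 99L

  vessel_masks <- list()
  profile <- matrix(0, nr, nc)     # parabolic spatial profile, unit peak
  for (k in seq_along(p$vessels)) {
    v <- p$vessels[[k]]
    ctr <- c(v$center[1L] * nr, v$center[2L] * nc) * p$pixel_spacing
    r2 <- (rr_mm - ctr[1L])^2 + (cc_mm - ctr[2L])^2
    inside <- r2 <= v$radius^2
    if (!any(inside))
      stop(sprintf("vessel '%s' contains no pixel centers", names(p$vessels)[k]))
    if (any(labels[inside] != 0L))
      stop(sprintf("vessel '%s' overlaps another vessel or the lung field",
                   names(p$vessels)[k]))
    labels[inside] <- k
    vessel_masks[[names(p$vessels)[k]]] <- inside
    profile[inside] <- 1 - r2[inside] / v$radius^2
  }

  s <- phantom_waveform(p)                       # per-frame waveform
  area <- prod(rep(p$pixel_spacing, 2L) / 10)    # cm^2
  dt <- p$rr_interval / p$n_frames / 1000        # s

  # scale each vessel's peak so the discrete stroke volume is exact
  v_clean <- array(0, dim = c(nr, nc, p$n_frames))
  peak <- numeric(length(p$vessels))
  for (k in seq_along(p$vessels)) {
    v <- p$vessels[[k]]
    w_sum <- sum(profile[vessel_masks[[k]]])
    scale_k <- v$stroke_volume / (sum(s) * w_sum * area * dt)
    peak[k] <- scale_k * max(s)
    prof_k <- ifelse(vessel_masks[[k]], profile, 0)
    v_clean <- v_clean + outer(prof_k, scale_k * s)
  }

  bg <- background_surface(p$background_coeffs, p$background_order, nr, nc)
  v_noisefree <- sweep(v_clean, c(1L, 2L), bg, "+")
  if (max(abs(v_noisefree)) > p$venc)
    stop(sprintf(
      "aliasing: peak noise-free velocity %.1f cm/s exceeds VENC %.0f cm/s",
      max(abs(v_noisefree)), p$venc))

  # magnitude: tissue 1, blood slightly brighter, lung dark
  m_lung <- if (is.finite(p$snr_tissue)) p$snr_lung / p$snr_tissue else 0.1
  mag0 <- matrix(1, nr, nc)
  mag0[labels %in% seq_along(p$vessels)] <- 1.2
  mag0[lung] <- m_lung

  out <- with_seed(p$seed, {
    noise_sd <- if (is.finite(p$snr_tissue))
      p$venc / (pi * p$snr_tissue * mag0) else matrix(0, nr, nc)
    vel <- v_noisefree +
      array(stats::rnorm(npix * p$n_frames, 0, rep(noise_sd, p$n_frames)),
            dim = dim(v_noisefree))
    mag_sd <- if (is.finite(p$snr_tissue)) 1 / p$snr_tissue else 0
    mag <- array(rep(mag0, p$n_frames) +
                   stats::rnorm(npix * p$n_frames, 0, mag_sd),
                 dim = dim(v_noisefree))
    list(vel = vel, mag = mag)
  })

  series <- pc_series(out$vel, out$mag, venc = p$venc,
                      pixel_spacing = p$pixel_spacing,
                      rr_interval = p$rr_interval,
                      rr_series = p$rr_series,
                      meta = list(phantom_seed = p$seed))

  sv <- vapply(p$vessels, function(v) v$stroke_volume, numeric(1))
  truth <- list(
    background_coeffs = p$background_coeffs,
    background_order = p$background_order,
    stroke_volumes = sv,
    qpqs = if (all(c("aorta", "pa") %in% names(sv)))
      unname(sv[["pa"]] / sv[["aorta"]]) else NA_real_,
    labels = labels,
    static_mask = labels == 0L,
    vessel_masks = vessel_masks,
    lung_mask = lung,
    peak_velocity = max(peak),
    rr_series = p$rr_series
  )
  structure(list(series = series, truth = truth, params = p),
            class = "pc_phantom")
}

#' @export
print.pc_phantom <- function(x, ...) {
  cat("Synthetic phase-contrast phantom\n")
  print(x$series)
  cat(sprintf("  vessels: %s (stroke volumes %s ml)\n",
              paste(names(x$truth$stroke_volumes), collapse = ", "),
              paste(round(x$truth$stroke_volumes, 1), collapse = ", ")))
  cat(sprintf("  background order %d, coefficients [%s] cm/s\n",
              x$truth$background_order,
              paste(signif(x$truth$background_coeffs, 3), collapse = ", ")))
  invisible(x)
}
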