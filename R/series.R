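#' Construct a phase-contrast cine series
#'
#' The unit every stage of the pipeline consumes and produces: a stack of
#' per-frame velocity images (cm/s) with the matching magnitude images and
#' the acquisition metadata needed for flow quantification.
#'
#' @param velocity numeric array `rows x cols x frames`, through-plane
#'   velocity in cm/s (positive = forward through the imaging plane).
#' @param magnitude numeric array with the same dimensions as `velocity`;
#'   signal magnitude in arbitrary scanner units.
#' @param venc velocity-encoding limit in cm/s; velocity mapped to phase
#'   `pi`. Must exceed every noise-free velocity in the series.
#' @param pixel_spacing in-plane pixel spacing in mm (scalar isotropic, or
#'   length-2 `c(row, col)`).
#' @param rr_interval mean R-R interval in ms; one cine cycle spans it.
#' @param rr_series optional numeric vector of the individual beat-to-beat
#'   R-R intervals (ms) observed during the acquisition, used by
#'   [rr_eligibility()].
#' @param meta optional named list of extra metadata (carried through
#'   untouched; the correction step records the applied model here).
#'
#' @return An object of class `pc_series`.
#' @seealso [make_phantom()], [fit_background()], [flow_curve()]
#' @export
pc_series <- function(velocity, magnitude, venc, pixel_spacing, rr_interval,
                      rr_series = NULL, meta = list()) {
  if (length(dim(velocity)) != 3L)
    stop("`velocity` must be a rows x cols x frames array")
  if (!identical(dim(velocity), dim(magnitude)))
    stop("`magnitude` dimensions must match `velocity`")
  if (!is.numeric(venc) || length(venc) != 1L || venc <= 0)
    stop("`venc` must be a single positive number (cm/s)")
  if (!all(pixel_spacing > 0) || !length(pixel_spacing) %in% c(1L, 2L))
    stop("`pixel_spacing` must be 1 or 2 positive values (mm)")
  if (!is.numeric(rr_interval) || length(rr_interval) != 1L || rr_interval <= 0)
    stop("`rr_interval` must be a single positive number (ms)")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  n_frames <- dim(velocity)[3L]
  structure(
    list(
      velocity = velocity,
      magnitude = magnitude,
      venc = venc,
      pixel_spacing = pixel_spacing,
      rr_interval = rr_interval,
      rr_series = rr_series,
      frame_times = rr_interval * (seq_len(n_frames) - 1L) / n_frames,
      meta = meta
    ),
    class = "pc_series"
  )
}

#' @export
print.pc_series <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf(
    "Phase-contrast cine series: %d x %d pixels, %d frames\n", d[1L], d[2L], d[3L]))
  cat(sprintf("  VENC %.0f cm/s, pixel spacing %.2f x %.2f mm, R-R %.0f ms\n",
              x$venc, x$pixel_spacing[1L], x$pixel_spacing[2L], x$rr_interval))
  if (!is.null(x$meta$background_model))
    cat(sprintf("  background-corrected (order %d)\n",
                x$meta$background_model$order))
  invisible(x)
}

n_frames <- function(series) dim(series$velocity)[3L]

#' Pixel area of a series in cm^2
#' @param series a [pc_series()].
#' @return scalar pixel area in cm^2.
#' @export
pixel_area_cm2 <- function(series) {
  prod(series$pixel_spacing / 10)
}

# Normalized image coordinates x, y in [-1, 1], centered on the image
# center: x varies along columns, y along rows. All polynomial background
# coefficients are expressed in these coordinates, so they are comparable
# across pixel spacings but not across grid aspect ratios.
normalized_coords <- function(n_rows, n_cols) {
  x <- if (n_cols > 1L) 2 * (seq_len(n_cols) - 1L) / (n_cols - 1L) - 1 else 0
  y <- if (n_rows > 1L) 2 * (seq_len(n_rows) - 1L) / (n_rows - 1L) - 1 else 0
  list(
    x = matrix(x, n_rows, n_cols, byrow = TRUE),
    y = matrix(y, n_rows, n_cols)
  )
}

#' Convert phase to velocity
#'
#' Standard PC-MRI scaling: a phase of `pi` radians corresponds to the
#' velocity-encoding limit, `v = phi * venc / pi`.
#'
#' @param phase numeric vector/matrix/array of phase values in radians,
#'   all within `[-pi, pi]`.
#' @param venc velocity-encoding limit in cm/s.
#' @return velocity in cm/s, same shape as `phase`.
#' @export
velocity_from_phase <- function(phase, venc) {
  if (!is.numeric(venc) || length(venc) != 1L || venc <= 0)
    stop("`venc` must be a single positive number (cm/s)")
  if (any(abs(phase) > pi + 1e-12, na.rm = TRUE))
    stop("phase outside [-pi, pi]: data are aliased; unwrapping is not supported")
  phase * venc / pi
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}
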