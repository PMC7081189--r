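#' Quantify the flow curve and volumes of a vessel ROI
#'
#' Integrates through-plane velocity over a vessel region of interest:
#' per frame, flow (ml/s) is the sum over ROI pixels of velocity (cm/s)
#' times pixel area (cm^2); volumes use rectangle-rule integration with a
#' uniform frame duration R-R / n_frames (retrospective gating). Forward
#' volume integrates only frames with positive net flow, backward volume
#' the absolute value of negative frames, so `net = forward - backward`
#' exactly. The ROI is fixed across frames.
#'
#' @param series a [pc_series()].
#' @param roi the vessel ROI: a logical matrix of the image size, an n x 2
#'   matrix of `(row, col)` pixel indices (1-based), or a polygon (n x 2
#'   vertex matrix, distinguished by non-integer coordinates or by
#'   `roi_is_polygon = TRUE`).
#' @param roi_is_polygon force interpretation of an n x 2 matrix as a
#'   polygon to be rasterized rather than a pixel list.
#' @param vessel label stored in the result.
#' @return An object of class `flow_result`: `flow` (ml/s per frame),
#'   `frame_times` (ms), `net_volume`, `forward_volume`, `backward_volume`
#'   (ml), `roi_area` (cm^2), `vessel`.
#' @examples
#' ph <- make_phantom(phantom_params(snr_tissue = Inf))
#' flow_curve(ph$series, ph$truth$vessel_masks$aorta, vessel = "aorta")
#' @export
flow_curve <- function(series, roi, roi_is_polygon = FALSE, vessel = "vessel") {
  stopifnot(inherits(series, "pc_series"))
  d <- dim(series$velocity)
  m <- resolve_roi(roi, d[1L], d[2L], roi_is_polygon)
  if (!any(m)) stop("ROI contains no pixels inside the image grid")

  area <- pixel_area_cm2(series)
  nf <- d[3L]
  vmat <- matrix(series$velocity, d[1L] * d[2L], nf)
  flow <- colSums(vmat[as.vector(m), , drop = FALSE]) * area  # cm^3/s = ml/s

  dt <- series$rr_interval / nf / 1000  # s
  vols <- flow * dt
  structure(
    list(flow = flow, frame_times = series$frame_times,
         net_volume = sum(vols),
         forward_volume = sum(vols[vols > 0]),
         backward_volume = -sum(vols[vols < 0]),
         roi_area = sum(m) * area, n_pixels = sum(m), vessel = vessel),
    class = "flow_result"
  )
}

resolve_roi <- function(roi, n_rows, n_cols, roi_is_polygon = FALSE) {
  if (is.logical(roi)) {
    if (!identical(dim(roi), c(n_rows, n_cols)))
      stop("logical ROI dimensions do not match the image")
    return(roi)
  }
  roi <- as.matrix(roi)
  if (ncol(roi) != 2L) stop("ROI matrix must have 2 columns (row, col)")
  if (roi_is_polygon || any(roi != round(roi)))
    return(polygon_mask(roi, n_rows, n_cols))
  if (any(roi < 1L) || any(roi[, 1L] > n_rows) || any(roi[, 2L] > n_cols))
    stop("ROI pixel indices fall outside the image grid")
  m <- matrix(FALSE, n_rows, n_cols)
  m[roi] <- TRUE
  m
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("Flow result [%s]: net %.1f ml, forward %.1f ml, backward %.1f ml over %d frames (ROI %.1f cm^2)\n",
              x$vessel, x$net_volume, x$forward_volume, x$backward_volume,
              length(x$flow), x$roi_area))
  invisible(x)
}

#' Pulmonary-to-systemic flow ratio and shunt classification
#'
#' Qp/Qs is the ratio of pulmonary (main pulmonary artery) to systemic
#' (ascending aorta) net flow volume. The normal range is 0.9 to 1.2,
#' bounds inclusive; a ratio above 1.2 indicates a left-to-right shunt,
#' below 0.9 a right-to-left shunt.
#'
#' @param pa pulmonary flow: a [flow_curve()] result or a net volume (ml).
#' @param ao systemic (aortic) flow, same forms; net volume must be
#'   positive.
#' @return An object of class `qpqs_result`: `qp`, `qs` (ml), `ratio`,
#'   `classification` (one of `"normal"`, `"left-to-right"`,
#'   `"right-to-left"`).
#' @export
qpqs <- function(pa, ao) {
  qp <- if (inherits(pa, "flow_result")) pa$net_volume else as.numeric(pa)
  qs <- if (inherits(ao, "flow_result")) ao$net_volume else as.numeric(ao)
  if (!is.finite(qs) || qs <= 0)
    stop("systemic (aortic) net volume must be positive to form Qp/Qs")
  ratio <- qp / qs
  structure(list(qp = qp, qs = qs, ratio = ratio,
                 classification = classify_qpqs(ratio)),
            class = "qpqs_result")
}

#' Classify a Qp/Qs ratio against the normal range
#'
#' @param ratio numeric vector of Qp/Qs ratios.
#' @param lower,upper normal-range bounds, inclusive.
#' @return character vector: `"normal"`, `"left-to-right"` (above range) or
#'   `"right-to-left"` (below range).
#' @export
classify_qpqs <- function(ratio, lower = 0.9, upper = 1.2) {
  ifelse(ratio > upper, "left-to-right",
         ifelse(ratio < lower, "right-to-left", "normal"))
}

#' @export
print.qpqs_result <- function(x, ...) {
  cat(sprintf("Qp/Qs = %.2f (Qp %.1f ml, Qs %.1f ml): %s\n",
              x$ratio, x$qp, x$qs, x$classification))
  invisible(x)
}

#' Arrhythmia eligibility from beat-to-beat R-R intervals
#'
#' A subject is eligible if, for every provided acquisition, the standard
#' deviation of the beat-to-beat R-R intervals does not exceed 10% of the
#' mean R-R interval ("exceeding" is strict: exactly 10% is still
#' eligible).
#'
#' @param rr_series numeric vector of R-R intervals (ms) for one
#'   acquisition, or a list of such vectors (one per acquisition).
#' @param max_cv maximum allowed coefficient of variation.
#' @return `TRUE` if eligible.
#' @export
rr_eligibility <- function(rr_series, max_cv = 0.10) {
  if (!is.list(rr_series)) rr_series <- list(rr_series)
  if (!length(rr_series) || any(!lengths(rr_series)))
    stop("empty R-R series")
  all(vapply(rr_series, function(rr) {
    if (length(rr) < 2L) stop("need at least 2 beats per acquisition")
    stats::sd(rr) / mean(rr) <= max_cv
  }, logical(1)))
}

#' Body surface area by the DuBois and DuBois formula
#'
#' `BSA = 0.007184 * weight^0.425 * height^0.725` with weight in kg and
#' height in cm, giving m^2. Used to index cardiac volumes and mass.
#'
#' @param weight body weight, kg.
#' @param height body height, cm.
#' @return body surface area, m^2 (vectorized).
#' @export
bsa_dubois <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  0.007184 * weight^0.425 * height^0.725
}
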