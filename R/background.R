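#' Time-averaged velocity map
#'
#' Per-pixel arithmetic mean of the velocity over all cine frames. The
#' background surface is fitted to this map: vessel pulsatility averages
#' toward the mean flow while static-tissue pixels average toward the
#' background offset itself.
#'
#' @param series a [pc_series()].
#' @return numeric matrix (rows x cols), cm/s.
#' @export
time_average_velocity <- function(series) {
  stopifnot(inherits(series, "pc_series"))
  d <- dim(series$velocity)
  matrix(rowMeans(matrix(series$velocity, d[1L] * d[2L], d[3L])), d[1L], d[2L])
}

# monomial design matrix in normalized coordinates for the masked pixels
background_design <- function(n_rows, n_cols, mask, order) {
  co <- normalized_coords(n_rows, n_cols)
  x <- co$x[mask]; y <- co$y[mask]
  X <- cbind(a00 = rep(1, length(x)), a10 = x, a01 = y)
  if (order == 2L)
    X <- cbind(X, a20 = x^2, a02 = y^2, a11 = x * y)
  X
}

#' Fit a polynomial background surface to stationary tissue
#'
#' The central computation of stationary-tissue background correction:
#' ordinary least squares of the time-averaged velocity of static pixels on
#' the monomial basis `{1, x, y}` (order 1, a tilted flat surface) or
#' `{1, x, y, x^2, y^2, xy}` (order 2) in normalized image coordinates
#' `x, y` in `[-1, 1]` centered on the image center. The fitted surface
#' estimates the eddy-current velocity offset and is what
#' [apply_correction()] subtracts from every frame.
#'
#' The fit is performed on velocity (cm/s) rather than raw phase; the two
#' differ only by the constant factor VENC/pi, so the results are
#' equivalent and one unit system is kept throughout. The fit is unweighted:
#' the mask's magnitude gate has already removed low-SNR pixels.
#' Coefficients are in normalized coordinates and are not comparable across
#' grid sizes.
#'
#' @param object a [pc_series()] (time-averaged internally) or a numeric
#'   matrix holding an already time-averaged velocity map, cm/s.
#' @param mask a [detect_static()] result, or a logical matrix of pixels to
#'   fit on.
#' @param order polynomial order, 1 (linear) or 2 (quadratic).
#'
#' @return An object of class `background_fit` with components
#'   `coefficients` (named, cm/s in normalized coordinates), `order`,
#'   `n_static`, `rms_residual` (cm/s), `fitted_mask` values, `mask`, and
#'   the grid dimensions. Supports `coef()`, `predict()` (the surface on
#'   the full grid or at new pixels), `residuals()`, `summary()`, `plot()`.
#' @examples
#' ph <- make_phantom(phantom_params(background_order = 1,
#'                                   background_coeffs = c(1, 0.5, -0.25)))
#' msk <- detect_static(ph$series,
#'                      exclusion_rois = list(ph$truth$lung_mask),
#'                      vessel_rois = ph$truth$vessel_masks)
#' fit <- fit_background(ph$series, msk, order = 1)
#' coef(fit)
#' @export
fit_background <- function(object, mask, order = 1L) {
  order <- as.integer(order)
  if (!order %in% 1:2) stop("`order` must be 1 or 2")
  vbar <- if (inherits(object, "pc_series")) time_average_velocity(object)
          else as.matrix(object)
  m <- if (inherits(mask, "static_mask")) mask$mask else mask
  if (!is.logical(m) || !identical(dim(m), dim(vbar)))
    stop("`mask` must be a static_mask or logical matrix matching the map")
  n_coef <- if (order == 1L) 3L else 6L
  if (sum(m) < n_coef)
    stop(sprintf("need at least %d static pixels for an order-%d fit, got %d",
                 n_coef, order, sum(m)))

  X <- background_design(nrow(vbar), ncol(vbar), m, order)
  fit <- stats::lm.fit(X, vbar[m])
  if (fit$rank < n_coef)
    stop("rank-deficient design: static pixels are degenerate for this basis")
  res <- fit$residuals
  structure(
    list(
      coefficients = fit$coefficients,
      order = order,
      n_static = sum(m),
      rms_residual = sqrt(mean(res^2)),
      residuals_mask = res,
      mask = m,
      dim = dim(vbar)
    ),
    class = "background_fit"
  )
}

#' Evaluate a fitted background surface
#'
#' @param object a [fit_background()] result.
#' @param newdata optional n x 2 matrix of `(row, col)` pixel coordinates;
#'   if omitted the surface is evaluated on the full image grid.
#' @param ... unused.
#' @return matrix (full grid) or numeric vector (at `newdata`), cm/s.
#' @export
predict.background_fit <- function(object, newdata = NULL, ...) {
  nr <- object$dim[1L]; nc <- object$dim[2L]
  if (is.null(newdata)) {
    cf <- object$coefficients
    full <- if (object$order == 1L) c(cf, a20 = 0, a02 = 0, a11 = 0) else cf
    return(background_surface(unname(full), 2L, nr, nc))
  }
  newdata <- as.matrix(newdata)
  x <- if (nc > 1L) 2 * (newdata[, 2L] - 1) / (nc - 1) - 1 else 0
  y <- if (nr > 1L) 2 * (newdata[, 1L] - 1) / (nr - 1) - 1 else 0
  cf <- object$coefficients
  out <- cf[["a00"]] + cf[["a10"]] * x + cf[["a01"]] * y
  if (object$order == 2L)
    out <- out + cf[["a20"]] * x^2 + cf[["a02"]] * y^2 + cf[["a11"]] * x * y
  out
}

#' @export
residuals.background_fit <- function(object, ...) object$residuals_mask

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf("Background surface fit (order %d, %d static pixels)\n",
              x$order, x$n_static))
  print(round(x$coefficients, 4))
  cat(sprintf("RMS residual: %.3f cm/s\n", x$rms_residual))
  invisible(x)
}

#' @export
summary.background_fit <- function(object, ...) {
  structure(
    list(fit = object,
         surface_range = range(predict(object)),
         resid_quartiles = stats::quantile(object$residuals_mask,
                                           c(0.25, 0.5, 0.75))),
    class = "summary.background_fit"
  )
}

#' @export
print.summary.background_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Surface range over image: [%.3f, %.3f] cm/s\n",
              x$surface_range[1L], x$surface_range[2L]))
  cat("Residual quartiles (cm/s):\n")
  print(round(x$resid_quartiles, 4))
  invisible(x)
}

#' Plot a fitted background surface
#'
#' Image of the fitted velocity-offset surface over the full grid, with the
#' static pixels used in the fit marked.
#'
#' @param x a [fit_background()] result.
#' @param show_mask overlay the static-pixel mask outline.
#' @param ... passed to [graphics::image()].
#' @export
plot.background_fit <- function(x, show_mask = TRUE, ...) {
  surf <- predict(x)
  graphics::image(t(surf)[, nrow(surf):1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  axes = FALSE, asp = nrow(surf) / ncol(surf),
                  main = sprintf("Background surface, order %d (cm/s)", x$order),
                  ...)
  if (show_mask) {
    pts <- which(x$mask, arr.ind = TRUE)
    graphics::points((pts[, 2L] - 1) / (ncol(surf) - 1),
                     1 - (pts[, 1L] - 1) / (nrow(surf) - 1),
                     pch = ".", col = grDevices::adjustcolor("black", 0.25))
  }
  invisible(x)
}

#' Subtract a fitted background surface from every frame
#'
#' Applies stationary-tissue background correction: each frame's velocity
#' at `(x, y)` is reduced by the fitted polynomial evaluated there.
#' Magnitude images are unchanged; the applied model is recorded in the
#' series metadata.
#'
#' @param series a [pc_series()].
#' @param model a [fit_background()] result fitted on the same grid.
#' @return the corrected [pc_series()].
#' @export
apply_correction <- function(series, model) {
  stopifnot(inherits(series, "pc_series"), inherits(model, "background_fit"))
  if (!identical(model$dim, dim(series$velocity)[1:2]))
    stop("background model grid does not match the series")
  surf <- predict(model)
  out <- series
  out$velocity <- sweep(series$velocity, c(1L, 2L), surf, "-")
  out$meta$background_model <- list(order = model$order,
                                    coefficients = model$coefficients,
                                    n_static = model$n_static,
                                    rms_residual = model$rms_residual)
  out
}
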