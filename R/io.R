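#' Write a phase-contrast series to a directory
#'
#' One directory per series: `velocity.csv` and `magnitude.csv` hold the
#' pixel-by-frame stacks (one row per pixel in column-major order, one
#' column per frame, plain CSV), and `meta.json` the acquisition metadata
#' (grid dimensions, VENC cm/s, pixel spacing mm, R-R ms, frame times,
#' R-R series, extra metadata). Everything is plain text and round-trips
#' losslessly at full double precision.
#'
#' @param series a [pc_series()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "pc_series"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series$velocity)
  write_stack <- function(a, file) {
    m <- matrix(a, d[1L] * d[2L], d[3L])
    colnames(m) <- paste0("frame_", seq_len(d[3L]))
    utils::write.csv(m, file.path(path, file), row.names = FALSE)
  }
  write_stack(series$velocity, "velocity.csv")
  write_stack(series$magnitude, "magnitude.csv")
  meta <- list(
    dim = d, venc = series$venc, pixel_spacing = series$pixel_spacing,
    rr_interval = series$rr_interval, frame_times = series$frame_times,
    rr_series = series$rr_series, meta = series$meta,
    units = list(velocity = "cm/s", pixel_spacing = "mm",
                 rr_interval = "ms", frame_times = "ms")
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a phase-contrast series from a directory
#'
#' Inverse of [write_series()]. Fails with an error naming the field when
#' required metadata (`venc`, `pixel_spacing`, `rr_interval`, `dim`) is
#' missing, and rejects stacks whose frame counts disagree.
#'
#' @param path directory written by [write_series()].
#' @return a [pc_series()].
#' @export
read_series <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json under ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (fld in c("dim", "venc", "pixel_spacing", "rr_interval")) {
    if (is.null(meta[[fld]]))
      stop(sprintf("metadata field '%s' missing from %s", fld, meta_path))
  }
  d <- as.integer(meta$dim)
  read_stack <- function(file) {
    m <- as.matrix(utils::read.csv(file.path(path, file)))
    if (ncol(m) != d[3L] || nrow(m) != d[1L] * d[2L])
      stop(sprintf("%s: expected %d pixels x %d frames, got %d x %d",
                   file, d[1L] * d[2L], d[3L], nrow(m), ncol(m)))
    array(m, dim = d)
  }
  pc_series(read_stack("velocity.csv"), read_stack("magnitude.csv"),
            venc = meta$venc, pixel_spacing = meta$pixel_spacing,
            rr_interval = meta$rr_interval,
            rr_series = meta$rr_series,
            meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Write a phantom (series, label maps and ground truth) to a directory
#'
#' Writes the series via [write_series()] plus `labels.csv` (the integer
#' label map: 0 static, 1.. vessels, 99 lung) and `truth.json` (background
#' coefficients and order, stroke volumes, Qp/Qs, R-R series).
#'
#' @param phantom a [make_phantom()] result.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "pc_phantom"))
  write_series(phantom$series, path)
  utils::write.table(phantom$truth$labels, file.path(path, "labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  truth <- phantom$truth
  truth$labels <- NULL
  truth$static_mask <- NULL
  truth$vessel_masks <- NULL
  truth$lung_mask <- NULL
  truth$stroke_volumes <- as.list(truth$stroke_volumes)  # keep vessel names
  jsonlite::write_json(truth, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom directory back
#'
#' @param path directory written by [write_phantom()].
#' @return list with `series`, `labels` (integer matrix), `vessel_masks`,
#'   `lung_mask`, `static_mask` and `truth` (the sidecar contents).
#' @export
read_phantom <- function(path) {
  series <- read_series(path)
  labels <- as.matrix(utils::read.table(file.path(path, "labels.csv"),
                                        sep = ","))
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  truth <- jsonlite::read_json(file.path(path, "truth.json"),
                               simplifyVector = TRUE)
  truth$stroke_volumes <- unlist(truth$stroke_volumes)
  vessel_ids <- sort(setdiff(unique(as.vector(labels)), c(0L, 99L)))
  vessel_masks <- lapply(vessel_ids, function(k) labels == k)
  names(vessel_masks) <- names(truth$stroke_volumes)[vessel_ids]
  list(series = series, labels = labels,
       static_mask = labels == 0L, vessel_masks = vessel_masks,
       lung_mask = labels == 99L, truth = truth)
}

#' Write / read a polygon ROI as a CSV vertex list
#'
#' Vertex files are plain CSV with columns `row,col`, 0-based pixel
#' coordinates (stated in the header comment); in-memory polygons are
#' 1-based `(row, col)` matrices, converted on the way in and out.
#'
#' @param polygon n x 2 matrix of 1-based `(row, col)` vertices.
#' @param file CSV path.
#' @return `write_roi`: `file` invisibly; `read_roi`: the 1-based matrix.
#' @export
write_roi <- function(polygon, file) {
  polygon <- as.matrix(polygon)
  con <- file(file, "w")
  writeLines("# pcflow ROI: vertices as row,col in 0-based pixel coordinates",
             con)
  writeLines("row,col", con)
  utils::write.table(polygon - 1, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(file)
}

#' @rdname write_roi
#' @export
read_roi <- function(file) {
  v <- utils::read.csv(file, comment.char = "#")
  as.matrix(v[, c("row", "col")]) + 1
}
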