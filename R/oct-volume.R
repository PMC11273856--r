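#' OCT volume container
#'
#' A 3D swept-source OCT intensity grid with its physical calibration. The
#' array is indexed `[depth, ascan, bscan]` with depth index 1 anteriormost
#' (top of the B-scan). Intensities are expected in `[0, 1]`.
#'
#' @param data numeric 3D array `[depth_px, n_ascans, n_bscans]`.
#' @param transverse_extent_mm nominal en-face extent covered by the scan, mm
#'   (applies to both the A-scan and B-scan axes).
#' @param axial_extent_mm imaged depth, mm.
#' @param axial_length_mm the eye's axial length, mm (used for Bennett
#'   magnification scaling); `NA` if unknown.
#' @param orientation `"left"` or `"right"`: with `"left"`, the A-scan index
#'   increases from temporal to nasal.
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(data, transverse_extent_mm = 12, axial_extent_mm = 4.5,
                       axial_length_mm = NA_real_, orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  stopifnot(is.array(data), length(dim(data)) == 3L,
            transverse_extent_mm > 0, axial_extent_mm > 0)
  structure(list(
    data = data,
    transverse_extent_mm = transverse_extent_mm,
    axial_extent_mm = axial_extent_mm,
    axial_length_mm = axial_length_mm,
    orientation = orientation
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume> %d depth x %d A-scans x %d B-scans (%.1f x %.1f mm, depth %.1f mm)\n",
              d[1], d[2], d[3], x$transverse_extent_mm, x$transverse_extent_mm,
              x$axial_extent_mm))
  cat(sprintf("  axial length: %s mm; orientation: %s eye\n",
              format(x$axial_length_mm), x$orientation))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

# Extract B-scan `b` as a [depth x n_ascans] matrix.
#' @rdname oct_volume
#' @param volume an `oct_volume`.
#' @param b B-scan index.
#' @export
get_bscan <- function(volume, b) {
  stopifnot(inherits(volume, "oct_volume"), b >= 1, b <= dim(volume$data)[3])
  volume$data[, , b]
}

# Voxel pitches (mm per pixel) before magnification scaling.
voxel_pitch_mm <- function(volume) {
  d <- dim(volume$data)
  c(axial = volume$axial_extent_mm / d[1],
    ascan = volume$transverse_extent_mm / d[2],
    bscan = volume$transverse_extent_mm / d[3])
}

#' Write / read an OCT volume as a multi-page TIFF
#'
#' Pages are B-scans (32-bit float, intensities clipped to `[0, 1]`); the
#' physical calibration travels in a JSON sidecar `<path>.json`.
#'
#' @param volume an [oct_volume()].
#' @param path output TIFF path.
#' @return `write_oct_volume()` returns `path` invisibly; `read_oct_volume()`
#'   returns an [oct_volume()].
#' @export
write_oct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  pages <- lapply(seq_len(dim(volume$data)[3]),
                  function(b) clamp(volume$data[, , b], 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(transverse_extent_mm = volume$transverse_extent_mm,
               axial_extent_mm = volume$axial_extent_mm,
               axial_length_mm = volume$axial_length_mm,
               orientation = volume$orientation)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- pages[[b]]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list()
  oct_volume(arr,
             transverse_extent_mm = meta$transverse_extent_mm %||% 12,
             axial_extent_mm = meta$axial_extent_mm %||% 4.5,
             axial_length_mm = meta$axial_length_mm %||% NA_real_,
             orientation = meta$orientation %||% "left")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
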