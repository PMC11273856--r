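#' Boundary surface set
#'
#' Per-(B-scan, A-scan) depth, in possibly fractional pixels (0-based, so a
#' value of 0 is the anteriormost sample), of the three boundaries the
#' analysis uses: the internal limiting membrane (ILM), the middle of the
#' retinal pigment epithelium (mid-RPE), and the choroid-scleral interface
#' (CSI). The retina is the band ILM..mid-RPE and the choroid the band
#' mid-RPE..CSI, so `ilm <= midrpe <= csi` must hold wherever the surfaces
#' are valid.
#'
#' @param ilm_px,midrpe_px,csi_px numeric matrices `[n_bscans x n_ascans]` of
#'   boundary depths in pixels.
#' @param valid logical matrix of the same shape; `FALSE` marks A-scans where
#'   segmentation failed.
#' @param depth_px axial grid size the depths refer to.
#' @return an object of class `surface_set`.
#' @export
surface_set <- function(ilm_px, midrpe_px, csi_px, valid = NULL, depth_px = NULL) {
  stopifnot(is.matrix(ilm_px),
            identical(dim(ilm_px), dim(midrpe_px)),
            identical(dim(ilm_px), dim(csi_px)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(ilm_px), ncol(ilm_px))
  stopifnot(identical(dim(valid), dim(ilm_px)))
  v <- which(valid)
  if (length(v)) {
    if (any(ilm_px[v] > midrpe_px[v] + 1e-9) || any(midrpe_px[v] > csi_px[v] + 1e-9))
      stop("surface ordering violated: need ilm <= midrpe <= csi at every valid A-scan")
    if (any(ilm_px[v] < 0))
      stop("surface depths must be non-negative")
    if (!is.null(depth_px) && any(csi_px[v] >= depth_px))
      stop("surface depths must lie within [0, depth_px)")
  }
  structure(list(ilm_px = ilm_px, midrpe_px = midrpe_px, csi_px = csi_px,
                 valid = valid, depth_px = depth_px),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %d B-scans x %d A-scans (%.1f%% valid)\n",
              nrow(x$ilm_px), ncol(x$ilm_px), 100 * mean(x$valid)))
  invisible(x)
}

#' Voxel masks for the retina and choroid layers
#'
#' Builds disjoint logical masks from a [surface_set()]: a voxel at integer
#' depth `k` (0-based) belongs to the retina iff `ilm <= k < midrpe` and to
#' the choroid iff `midrpe <= k < csi` at its A-scan. Invalid A-scans are
#' excluded from both masks.
#'
#' @param surfaces a [surface_set()].
#' @param depth_px axial size of the mask; defaults to the set's `depth_px`.
#' @return list with logical arrays `retina` and `choroid` of dimension
#'   `[depth_px, n_ascans, n_bscans]`.
#' @export
layer_masks <- function(surfaces, depth_px = surfaces$depth_px) {
  stopifnot(inherits(surfaces, "surface_set"), !is.null(depth_px))
  nb <- nrow(surfaces$ilm_px); na_ <- ncol(surfaces$ilm_px)
  k <- 0:(depth_px - 1L)
  retina <- array(FALSE, dim = c(depth_px, na_, nb))
  choroid <- array(FALSE, dim = c(depth_px, na_, nb))
  for (b in seq_len(nb)) {
    ilm <- rep(surfaces$ilm_px[b, ], each = depth_px)
    rpe <- rep(surfaces$midrpe_px[b, ], each = depth_px)
    csi <- rep(surfaces$csi_px[b, ], each = depth_px)
    ok <- rep(surfaces$valid[b, ], each = depth_px)
    kk <- rep(k, na_)
    retina[, , b] <- ok & kk >= ilm & kk < rpe
    choroid[, , b] <- ok & kk >= rpe & kk < csi
  }
  list(retina = retina, choroid = choroid)
}

#' Write / read a surface set as TSV
#'
#' Columns: `bscan`, `ascan` (1-based), `ilm_px`, `midrpe_px`, `csi_px`
#' (0-based fractional pixels), `valid` (0/1). This is also the drop-in
#' format for externally produced segmentations.
#'
#' @param surfaces a [surface_set()].
#' @param path TSV path.
#' @param depth_px axial grid size to record on reading.
#' @return `write_surface_tsv()` returns `path` invisibly; `read_surface_tsv()`
#'   a [surface_set()].
#' @export
write_surface_tsv <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  nb <- nrow(surfaces$ilm_px); na_ <- ncol(surfaces$ilm_px)
  df <- data.frame(
    bscan = rep(seq_len(nb), times = na_),
    ascan = rep(seq_len(na_), each = nb),
    ilm_px = as.vector(surfaces$ilm_px),
    midrpe_px = as.vector(surfaces$midrpe_px),
    csi_px = as.vector(surfaces$csi_px),
    valid = as.integer(as.vector(surfaces$valid))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_tsv
#' @export
read_surface_tsv <- function(path, depth_px = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  nb <- max(df$bscan); na_ <- max(df$ascan)
  idx <- cbind(df$bscan, df$ascan)
  mk <- function(v) { m <- matrix(NA_real_, nb, na_); m[idx] <- v; m }
  surface_set(mk(df$ilm_px), mk(df$midrpe_px), mk(df$csi_px),
              valid = { m <- matrix(FALSE, nb, na_); m[idx] <- df$valid > 0; m },
              depth_px = depth_px)
}
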