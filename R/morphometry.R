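#' Bennett magnification ratio
#'
#' Ocular magnification correction for the transverse image scale:
#' `ratio = 3.382 * 0.013062 * (axial_length_mm - 1.82)`, where 3.382 is the
#' device camera factor and the remainder the eye-specific factor. The
#' volume's transverse calibration (mm per pixel) is multiplied by this
#' ratio relative to the device-nominal eye.
#'
#' @param axial_length_mm axial length of the eye, mm (> 1.82).
#' @return the dimensionless magnification ratio.
#' @export
bennett_scale <- function(axial_length_mm) {
  if (any(axial_length_mm <= 1.82))
    stop("axial_length_mm must exceed 1.82 mm")
  3.382 * 0.013062 * (axial_length_mm - 1.82)
}

#' Physical calibration of an OCT grid
#'
#' Axial and (Bennett-scaled) transverse micrometres per pixel.
#'
#' @param depth_px,n_ascans,n_bscans grid size.
#' @param axial_extent_mm,transverse_extent_mm physical extents, mm.
#' @param axial_length_mm axial length used for Bennett scaling; `NA` keeps
#'   the nominal scale (ratio 1).
#' @return a `calibration` list with fields `axial_um_per_px`,
#'   `nominal_transverse_um_per_px` (length 2: ascan, bscan),
#'   `magnification_ratio` and `scaled_transverse_um_per_px`.
#' @export
calibration <- function(depth_px, n_ascans, n_bscans,
                        axial_extent_mm = 4.5, transverse_extent_mm = 12,
                        axial_length_mm = NA_real_) {
  stopifnot(depth_px >= 1, n_ascans >= 1, n_bscans >= 1,
            axial_extent_mm > 0, transverse_extent_mm > 0)
  nominal <- c(ascan = transverse_extent_mm * 1000 / n_ascans,
               bscan = transverse_extent_mm * 1000 / n_bscans)
  q <- if (is.na(axial_length_mm)) 1 else bennett_scale(axial_length_mm)
  structure(list(
    axial_um_per_px = axial_extent_mm * 1000 / depth_px,
    nominal_transverse_um_per_px = nominal,
    magnification_ratio = q,
    scaled_transverse_um_per_px = nominal * q
  ), class = "calibration")
}

#' Calibration of an OCT volume
#' @param volume an [oct_volume()].
#' @rdname calibration
#' @export
volume_calibration <- function(volume) {
  d <- dim(volume$data)
  calibration(d[1], d[2], d[3], volume$axial_extent_mm,
              volume$transverse_extent_mm, volume$axial_length_mm)
}

#' Locate the fovea on a segmented surface set
#'
#' The fovea is the lowest (deepest) point of the ILM: the valid `(b, a)`
#' maximising ILM depth within the central half of the grid (the outer part
#' of the scan is excluded so peripheral artefacts cannot win). Ties are
#' broken by proximity to the grid centre, then by lowest index.
#'
#' @param surfaces a [surface_set()].
#' @return list `(bscan, ascan, ilm_px)` of class `fovea_location`.
#' @export
locate_fovea <- function(surfaces) {
  stopifnot(inherits(surfaces, "surface_set"))
  nb <- nrow(surfaces$ilm_px); na_ <- ncol(surfaces$ilm_px)
  bwin <- seq.int(max(1L, floor(nb / 4) + 1L), min(nb, ceiling(3 * nb / 4)))
  awin <- seq.int(max(1L, floor(na_ / 4) + 1L), min(na_, ceiling(3 * na_ / 4)))
  sub <- surfaces$ilm_px[bwin, awin, drop = FALSE]
  sub[!surfaces$valid[bwin, awin, drop = FALSE]] <- NA
  if (all(is.na(sub))) stop("no valid A-scans in the central region")
  rng <- diff(range(sub, na.rm = TRUE))
  if (rng < 2) stop("no pit: ILM is flat in the central region")
  mx <- max(sub, na.rm = TRUE)
  cand <- which(sub >= mx - 1e-9, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    ctr <- c((length(bwin) + 1) / 2, (length(awin) + 1) / 2)
    d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2
    cand <- cand[order(d2, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  b <- bwin[cand[1, 1]]; a <- awin[cand[1, 2]]
  structure(list(bscan = b, ascan = a, ilm_px = surfaces$ilm_px[b, a]),
            class = "fovea_location")
}

# scaled en-face distance (mm) of every (b, a) from the fovea
enface_distance_mm <- function(surfaces, cal, fovea) {
  nb <- nrow(surfaces$ilm_px); na_ <- ncol(surfaces$ilm_px)
  db <- cal$scaled_transverse_um_per_px["bscan"] / 1000
  da <- cal$scaled_transverse_um_per_px["ascan"] / 1000
  xb <- (seq_len(nb) - fovea$bscan) * db
  xa <- (seq_len(na_) - fovea$ascan) * da
  sqrt(outer(xb^2, xa^2, `+`))
}

#' Mean layer thickness in a fovea-centred circular ROI
#'
#' Axial thickness (boundary depth difference times the axial calibration)
#' averaged over all A-scans whose Bennett-scaled en-face distance from the
#' fovea is strictly less than `diameter_mm / 2`. Invalid A-scans are
#' excluded.
#'
#' @param surfaces a [surface_set()].
#' @param cal a [calibration()].
#' @param fovea a `fovea_location` (or `(b, a)` pair).
#' @param diameter_mm ROI diameter, mm (1 or 3 in the standard protocol).
#' @param layer `"retina"` (ILM to mid-RPE) or `"choroid"` (mid-RPE to CSI).
#' @return list `mean_um` and `n` (number of A-scans in the ROI).
#' @export
roi_mean_thickness <- function(surfaces, cal, fovea, diameter_mm,
                               layer = c("retina", "choroid")) {
  layer <- match.arg(layer)
  stopifnot(inherits(surfaces, "surface_set"), inherits(cal, "calibration"))
  if (is.numeric(fovea)) fovea <- list(bscan = fovea[1], ascan = fovea[2])
  dmm <- enface_distance_mm(surfaces, cal, fovea)
  inside <- dmm < diameter_mm / 2 & surfaces$valid
  if (!any(inside)) stop("ROI contains no valid A-scans")
  thick <- if (layer == "retina") surfaces$midrpe_px - surfaces$ilm_px
           else surfaces$csi_px - surfaces$midrpe_px
  list(mean_um = mean(thick[inside]) * cal$axial_um_per_px, n = sum(inside))
}

#' Least-squares circle fit (Kasa + one geometric refinement)
#'
#' Algebraic Kasa least-squares circle through 2D points followed by one
#' Gauss-Newton pass on the geometric (orthogonal-distance) residuals.
#'
#' @param x,y point coordinates (>= 3 non-collinear points).
#' @return list `center` (length 2) and `radius`.
#' @export
fit_circle_2d <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  A <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  qr_A <- qr(A)
  if (qr_A$rank < 3) stop("collinear points: circle fit is degenerate")
  coef <- qr.coef(qr_A, rhs)
  cx <- -coef[1] / 2; cy <- -coef[2] / 2
  r <- sqrt(max(cx^2 + cy^2 - coef[3], 0))
  # one Gauss-Newton step on residuals d_i - r
  di <- sqrt((x - cx)^2 + (y - cy)^2)
  if (all(di > 1e-12) && r > 0) {
    J <- cbind(-(x - cx) / di, -(y - cy) / di, -1)
    res <- di - r
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) c(0, 0, 0))
    if (all(is.finite(step))) {
      cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    }
  }
  list(center = c(unname(cx), unname(cy)), radius = unname(r))
}

#' Directional best-fit-circle radius of the posterior eye
#'
#' Samples the mid-RPE surface (the upper boundary of the choroid) along the
#' en-face line through the fovea at the given angle (0 deg = the horizontal
#' B-scan direction, counterclockwise positive), keeps points by horizontal
#' (en-face, Bennett-scaled) distance from the fovea -- < 6 mm for 45 and
#' 135 deg, < 5 mm for 90 deg, and for 0 deg < 5 mm temporal / < 3 mm nasal
#' -- and fits a circle in the (arc-position, depth) plane in physical mm.
#'
#' @param surfaces a [surface_set()].
#' @param cal a [calibration()].
#' @param fovea a `fovea_location` (or `(b, a)` pair).
#' @param angle_deg one of 0, 45, 90, 135.
#' @param orientation `"left"` (A-scan index runs temporal to nasal) or
#'   `"right"`; resolves the asymmetric 0-degree window.
#' @return radius in mm (`Inf` with a warning if the sampled depths are
#'   collinear).
#' @export
directional_radius <- function(surfaces, cal, fovea, angle_deg,
                               orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  stopifnot(angle_deg %in% c(0, 45, 90, 135))
  if (is.numeric(fovea)) fovea <- list(bscan = fovea[1], ascan = fovea[2])
  nb <- nrow(surfaces$midrpe_px); na_ <- ncol(surfaces$midrpe_px)
  th <- angle_deg * pi / 180
  # unit step (1 nominal pixel) along the line in (a, b) index space
  da_idx <- cos(th); db_idx <- sin(th)
  da_mm <- cal$scaled_transverse_um_per_px["ascan"] / 1000
  db_mm <- cal$scaled_transverse_um_per_px["bscan"] / 1000
  step_mm <- sqrt((da_idx * da_mm)^2 + (db_idx * db_mm)^2)
  tmax <- ceiling(sqrt(nb^2 + na_^2))
  t <- seq(-tmax, tmax)
  ai <- fovea$ascan + t * da_idx
  bi <- fovea$bscan + t * db_idx
  keep <- ai >= 1 & ai <= na_ & bi >= 1 & bi <= nb
  t <- t[keep]; ai <- ai[keep]; bi <- bi[keep]
  s_mm <- t * step_mm
  if (angle_deg == 0) {
    # s > 0 points toward increasing A-scan index: nasal for a left eye
    win <- if (orientation == "left") s_mm > -5 & s_mm < 3 else s_mm > -3 & s_mm < 5
  } else if (angle_deg == 90) {
    win <- abs(s_mm) < 5
  } else {
    win <- abs(s_mm) < 6
  }
  t <- t[win]; ai <- ai[win]; bi <- bi[win]; s_mm <- s_mm[win]
  # require all four bilinear neighbours valid
  vnum <- matrix(as.numeric(surfaces$valid), nb, na_)
  vok <- bilinear_interp(vnum, bi, ai) > 0.999
  z_mm <- bilinear_interp(surfaces$midrpe_px, bi, ai) * cal$axial_um_per_px / 1000
  s_mm <- s_mm[vok]; z_mm <- z_mm[vok]
  if (length(s_mm) < 3) stop("directional window contains too few valid samples")
  if (diff(range(z_mm)) < 1e-9) {
    warning("collinear samples: radius reported as infinite")
    return(Inf)
  }
  fit <- fit_circle_2d(s_mm, z_mm)
  fit$radius
}

#' Full morphometry of one segmented volume
#'
#' Computes the eight posterior-segment endpoints for one volume: mean
#' retinal and choroidal thickness in fovea-centred 1 mm and 3 mm ROIs
#' (`rt_1mm_um` .. `ct_3mm_um`) and the four directional best-fit-circle
#' radii of the mid-RPE (`r0_mm`, `r45_mm`, `r90_mm`, `r135_mm`).
#'
#' @param surfaces a [surface_set()].
#' @param cal a [calibration()].
#' @param fovea optional precomputed `fovea_location` (reuse the baseline
#'   fovea for a registered follow-up volume); located automatically when
#'   `NULL`.
#' @param orientation eye orientation flag (see [directional_radius()]).
#' @return a one-row `data.frame` of class `morphometry_result`, with ROI
#'   A-scan counts `n_1mm` and `n_3mm`.
#' @export
measure_volume <- function(surfaces, cal, fovea = NULL,
                           orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  if (is.null(fovea)) fovea <- locate_fovea(surfaces)
  rt1 <- roi_mean_thickness(surfaces, cal, fovea, 1, "retina")
  rt3 <- roi_mean_thickness(surfaces, cal, fovea, 3, "retina")
  ct1 <- roi_mean_thickness(surfaces, cal, fovea, 1, "choroid")
  ct3 <- roi_mean_thickness(surfaces, cal, fovea, 3, "choroid")
  rad <- vapply(c(0, 45, 90, 135), function(ang)
    directional_radius(surfaces, cal, fovea, ang, orientation), numeric(1))
  out <- data.frame(rt_1mm_um = rt1$mean_um, rt_3mm_um = rt3$mean_um,
                    ct_1mm_um = ct1$mean_um, ct_3mm_um = ct3$mean_um,
                    r0_mm = rad[1], r45_mm = rad[2], r90_mm = rad[3],
                    r135_mm = rad[4],
                    n_1mm = rt1$n, n_3mm = rt3$n,
                    fovea_bscan = fovea$bscan, fovea_ascan = fovea$ascan)
  class(out) <- c("morphometry_result", class(out))
  out
}
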