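#' Segmentation parameters for the boundary search
#'
#' The segmenter first finds a coarse mid-RPE path per slice (a bright-band
#' center-surround score with a generous vertical step limit), flattens the
#' slice along it, and then finds all three boundaries as minimum-cost paths
#' in the flattened geometry, where the anatomy is near-horizontal and the
#' smoothness penalty acts at full strength. A final half-maximum crossing
#' refines the ILM edge.
#'
#' @param step_penalty cost per pixel of vertical step between neighbouring
#'   A-scans in the flattened geometry (costs are normalised to unit peak).
#' @param max_step_px maximum vertical step per A-scan in the flattened
#'   geometry, pixels.
#' @param coarse_penalty,coarse_max_step_px the same controls for the coarse
#'   (unflattened) mid-RPE pass, where the posterior curvature can reach
#'   several pixels per A-scan.
#' @param surround_um half-distance of the bright-band center-surround
#'   comparison, um.
#' @param min_retina_um,max_retina_um allowed ILM to mid-RPE separation, um.
#' @param min_choroid_um,max_choroid_um allowed mid-RPE to CSI separation, um.
#' @param rpe_band_um refinement half-band around the coarse mid-RPE, um.
#' @param bottom_guard_um depth band above the image bottom excluded from
#'   all searches: adaptive compensation drives the deepest samples towards
#'   0.5 regardless of signal, so boundaries may not be sought there.
#' @param energy_threshold minimum peak dark-to-bright axial gradient for an
#'   A-scan to count as segmentable; below it the A-scan is flagged invalid.
#' @export
segmentation_params <- function(step_penalty = 0.5, max_step_px = 2L,
                                coarse_penalty = 0.02, coarse_max_step_px = 5L,
                                surround_um = 70,
                                min_retina_um = 160, max_retina_um = 700,
                                min_choroid_um = 150, max_choroid_um = 800,
                                rpe_band_um = 120, bottom_guard_um = 300,
                                energy_threshold = 0.005) {
  stopifnot(step_penalty >= 0, max_step_px >= 1,
            coarse_penalty >= 0, coarse_max_step_px >= 1,
            surround_um > 0,
            min_retina_um > 0, max_retina_um > min_retina_um,
            min_choroid_um > 0, max_choroid_um > min_choroid_um,
            rpe_band_um > 0, bottom_guard_um >= 0, energy_threshold >= 0)
  structure(as.list(environment()), class = "segmentation_params")
}

# R wrapper around the compiled DP kernel (1-based band limits and output).
dp_min_path <- function(cost, lo, hi, max_step = 2L, step_penalty = 0.5) {
  dp_min_path_cpp(cost, as.integer(lo), as.integer(hi),
                  as.integer(max_step), step_penalty)
}

# Quadratic sub-pixel refinement of a path on a per-column profile
# (minimum of `prof`); returns fractional depths (1-based).
subpixel_refine <- function(prof, z) {
  nz <- nrow(prof)
  zf <- as.numeric(z)
  ok <- z > 1 & z < nz
  if (any(ok)) {
    a_ <- which(ok)
    cm <- prof[cbind(z[a_] - 1L, a_)]
    c0 <- prof[cbind(z[a_], a_)]
    cp <- prof[cbind(z[a_] + 1L, a_)]
    den <- cm - 2 * c0 + cp
    off <- ifelse(den > 1e-12, 0.5 * (cm - cp) / den, 0)
    zf[a_] <- z[a_] + clamp(off, -0.5, 0.5)
  }
  zf
}

# central vertical gradient (rows = depth)
depth_gradient <- function(img) {
  nz <- nrow(img)
  g <- img
  g[2:(nz - 1), ] <- (img[3:nz, ] - img[1:(nz - 2), ]) / 2
  g[1, ] <- img[2, ] - img[1, ]
  g[nz, ] <- img[nz, ] - img[nz - 1, ]
  g
}

# half-maximum crossing refinement of an edge path on profile matrix sm;
# dir = "rise" for dark-above/bright-below edges
half_cross <- function(sm, path, dir = c("rise", "fall"), rad = 6L) {
  dir <- match.arg(dir)
  nz <- nrow(sm); na_ <- ncol(sm)
  rad <- rep_len(as.integer(rad), na_)
  out <- path
  for (a in seq_len(na_)) {
    z <- round(path[a])
    r <- rad[a]
    lo <- max(1L, z - r); hi <- min(nz, z + r)
    pre <- stats::median(sm[max(1L, z - r - 3L):max(1L, z - r), a])
    post <- stats::median(sm[min(nz, z + r):min(nz, z + r + 3L), a])
    mid <- (pre + post) / 2
    seg <- sm[lo:hi, a]
    idx <- if (dir == "rise") which(seg >= mid) else which(seg <= mid)
    if (!length(idx) || idx[1] == 1L) next
    i <- idx[1]
    y0 <- seg[i - 1]; y1 <- seg[i]
    frac <- if (abs(y1 - y0) > 1e-12) (mid - y0) / (y1 - y0) else 0.5
    out[a] <- lo + (i - 2) + frac
  }
  out
}

#' Segment one enhanced B-scan
#'
#' Boundary search on an enhanced (diffused + compensated) slice: a coarse
#' bright-band path locates the RPE complex; the slice is flattened along
#' it; the mid-RPE (band-peak score), ILM (dark-to-bright gradient,
#' half-maximum refined) and CSI (bright-to-dark drop of the
#' texture-suppressed squared intensity) are then extracted as
#' smoothness-penalised minimum-cost paths with quadratic sub-pixel
#' refinement, and mapped back to image coordinates. A-scans whose peak
#' dark-to-bright gradient falls below `energy_threshold` are flagged
#' invalid.
#'
#' @param img numeric matrix `[depth x n_ascans]`, enhanced intensities.
#' @param params a [segmentation_params()].
#' @param axial_um_per_px axial calibration, um per pixel.
#' @return list with numeric vectors `ilm_px`, `midrpe_px`, `csi_px`
#'   (0-based fractional depths) and logical `valid`.
#' @export
segment_bscan <- function(img, params = segmentation_params(),
                          axial_um_per_px = 17.578125) {
  stopifnot(is.matrix(img), inherits(params, "segmentation_params"))
  nz <- nrow(img); na_ <- ncol(img)
  px <- function(um) max(1L, round(um / axial_um_per_px))
  guard <- max(nz - px(params$bottom_guard_um), 4L)
  sm <- smooth_matrix(img, 3L)
  g_raw <- depth_gradient(sm)
  peak_g <- apply(g_raw[seq_len(guard), , drop = FALSE], 2, max)
  valid <- peak_g >= params$energy_threshold
  if (!any(valid)) {
    na_v <- rep(NA_real_, na_)
    return(list(ilm_px = na_v, midrpe_px = na_v, csi_px = na_v,
                valid = rep(FALSE, na_)))
  }
  norm_band <- function(m) m / max(abs(m[seq_len(guard), , drop = FALSE]), 1e-12)
  w <- px(params$surround_um)
  band_peak <- function(m, wpx) {
    n <- nrow(m)
    up <- rbind(m[rep(1L, wpx), , drop = FALSE], m[1:(n - wpx), , drop = FALSE])
    dn <- rbind(m[(wpx + 1):n, , drop = FALSE], m[rep(n, wpx), , drop = FALSE])
    m - (up + dn) / 2
  }
  # coarse mid-RPE on the raw geometry
  cs0 <- norm_band(band_peak(sm, w))
  rpe0 <- dp_min_path(-cs0, rep(3L, na_), rep(guard, na_),
                      params$coarse_max_step_px, params$coarse_penalty)
  rpe0 <- round(stats::runmed(rpe0, min(5L, na_ - (1 - na_ %% 2)),
                              endrule = "median"))
  # flatten a band around the coarse RPE (edge-replicated rows)
  rh <- px(max(params$max_retina_um, params$max_choroid_um) + 100)
  rows <- -rh:rh
  flat <- matrix(0, length(rows), na_)
  for (a in seq_len(na_)) flat[, a] <- img[clamp(rpe0[a] + rows, 1L, nz), a]
  nzf <- nrow(flat); z0 <- rh + 1L
  # mirror-pad columns: in the flattened geometry the anatomy is nearly
  # horizontal, so the reflected continuation is smooth and gives the path
  # search full context at the scan edges
  hp <- min(8L, na_ - 1L)
  flat <- cbind(flat[, hp:1, drop = FALSE], flat,
                flat[, na_:(na_ - hp + 1L), drop = FALSE])
  na_pad <- ncol(flat)
  smf <- smooth_matrix(flat, 3L)
  csf <- hsmooth(band_peak(smf, w), 5L)
  csf <- csf / max(abs(csf))
  band <- function(lo_um, hi_um) {
    list(lo = rep(clamp(z0 + round(lo_um / axial_um_per_px), 2L, nzf - 1L), na_pad),
         hi = rep(clamp(z0 + round(hi_um / axial_um_per_px), 2L, nzf - 1L), na_pad))
  }
  crop <- function(x) x[(hp + 1L):(hp + na_)]
  ms <- params$max_step_px; pen <- params$step_penalty
  b_rpe <- band(-params$rpe_band_um, params$rpe_band_um)
  rpe <- dp_min_path(-csf, b_rpe$lo, b_rpe$hi, ms, pen)
  rpe_f <- subpixel_refine(-csf, rpe)
  # ILM: dark-to-bright gradient above the RPE complex
  gf <- hsmooth(depth_gradient(smf), 3L)
  gf <- gf / max(abs(gf))
  b_ilm <- band(-params$max_retina_um, -params$min_retina_um)
  # the foveal pit is the steepest anatomy; soften the ILM smoothness prior
  ilm <- dp_min_path(-gf, b_ilm$lo, b_ilm$hi, ms, 0.5 * pen)
  ilm_f <- subpixel_refine(-gf, ilm)
  # CSI: sustained bright-to-dark drop on the squared, texture-suppressed image
  smf2 <- smooth_matrix(flat, 5L)^2
  g2 <- hsmooth(smooth_matrix(depth_gradient(smf2), 3L), 9L)
  g2 <- g2 / max(abs(g2))
  b_csi <- band(params$min_choroid_um, params$max_choroid_um)
  csi <- dp_min_path(g2, b_csi$lo, b_csi$hi, ms, pen)
  csi_f <- subpixel_refine(g2, csi)
  ilm_f <- crop(ilm_f); rpe_f <- crop(rpe_f); csi_f <- crop(csi_f)
  # back to image coordinates
  shift <- rpe0 - z0
  ilm_f <- ilm_f + shift; rpe_f <- rpe_f + shift; csi_f <- csi_f + shift
  if (na_ >= 5) {
    ilm_f <- stats::runmed(ilm_f, 5, endrule = "median")
    rpe_f <- stats::runmed(rpe_f, 5, endrule = "median")
    csi_f <- stats::runmed(csi_f, 5, endrule = "median")
  }
  # keep the deep reference window of the crossing clear of the RPE complex
  rad_ilm <- clamp(floor((rpe_f - ilm_f) / 2) - 1, 3L, 6L)
  ilm_f <- half_cross(sm, ilm_f, "rise", rad = rad_ilm)
  rpe_f <- pmax(rpe_f, ilm_f); csi_f <- pmax(csi_f, rpe_f)
  ilm_f <- clamp(ilm_f, 1, nz); rpe_f <- clamp(rpe_f, 1, nz)
  csi_f <- clamp(csi_f, 1, nz)
  list(ilm_px = ilm_f - 1, midrpe_px = rpe_f - 1, csi_px = csi_f - 1,
       valid = valid)
}

# run segment_bscan over all slices of one direction; along = "b" uses the
# native B-scans, "a" the orthogonal slices. Returns [b, a] matrices.
segment_pass <- function(arr, params, aupp, along = c("b", "a")) {
  along <- match.arg(along)
  d <- dim(arr)
  nsl <- if (along == "b") d[3] else d[2]
  nco <- if (along == "b") d[2] else d[3]
  ilm <- rpe <- csi <- matrix(NA_real_, nsl, nco)
  valid <- matrix(FALSE, nsl, nco)
  for (s in seq_len(nsl)) {
    img <- if (along == "b") arr[, , s] else arr[, s, ]
    r <- segment_bscan(img, params, aupp)
    ilm[s, ] <- r$ilm_px; rpe[s, ] <- r$midrpe_px; csi[s, ] <- r$csi_px
    valid[s, ] <- r$valid
  }
  if (along == "a") {
    ilm <- t(ilm); rpe <- t(rpe); csi <- t(csi); valid <- t(valid)
  }
  list(ilm = ilm, rpe = rpe, csi = csi, valid = valid)
}

#' Segment a whole (enhanced) OCT volume
#'
#' Runs the boundary search over the native B-scans and over the orthogonal
#' slices, combines the two passes with weights favouring each pass's
#' in-slice interior (path estimates weaken near slice borders), replaces
#' B-scans that are mostly invalid by interpolation from their neighbours
#' (recorded in the `replaced_bscans` attribute), median-filters and lightly
#' mean-smooths every surface across the en-face plane, and enforces the
#' ILM <= mid-RPE <= CSI ordering. If more than 20% of A-scans are invalid
#' the result carries the quality flag `"poor"`.
#'
#' @param volume an enhanced [oct_volume()].
#' @param params a [segmentation_params()].
#' @param two_pass combine the orthogonal pass (default) or use only the
#'   native B-scan pass (faster).
#' @return a [surface_set()] with attributes `quality` (`"ok"`/`"poor"`),
#'   `invalid_fraction` and `replaced_bscans`.
#' @export
segment_volume <- function(volume, params = segmentation_params(),
                           two_pass = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$data)
  nz <- d[1]; na_ <- d[2]; nb <- d[3]
  aupp <- volume$axial_extent_mm * 1000 / nz
  p1 <- segment_pass(volume$data, params, aupp, "b")
  if (two_pass && nb >= 8) {
    p2 <- segment_pass(volume$data, params, aupp, "a")
    # weight by distance from the in-slice border of each pass
    wa <- pmin(matrix(seq_len(na_), nb, na_, byrow = TRUE) - 1,
               na_ - matrix(seq_len(na_), nb, na_, byrow = TRUE))
    wb <- pmin(matrix(seq_len(nb), nb, na_) - 1,
               nb - matrix(seq_len(nb), nb, na_))
    w1 <- pmin(wa, 8) + 0.5; w2 <- pmin(wb, 8) + 0.5
    comb <- function(f) {
      v1 <- p1[[f]]; v2 <- p2[[f]]
      u1 <- ifelse(is.na(v1), 0, w1); u2 <- ifelse(is.na(v2), 0, w2)
      out <- (u1 * ifelse(is.na(v1), 0, v1) + u2 * ifelse(is.na(v2), 0, v2)) /
        pmax(u1 + u2, 1e-12)
      out[u1 + u2 == 0] <- NA_real_
      out
    }
    ilm <- comb("ilm"); rpe <- comb("rpe"); csi <- comb("csi")
    valid <- (p1$valid | p2$valid) & !is.na(ilm) & !is.na(rpe) & !is.na(csi)
  } else {
    ilm <- p1$ilm; rpe <- p1$rpe; csi <- p1$csi; valid <- p1$valid
  }
  # fill invalid gaps by interpolation so surface regularisation stays NA-free
  fill_na_matrix <- function(m) {
    if (!anyNA(m)) return(m)
    for (a in seq_len(ncol(m))) {
      col <- m[, a]; okc <- !is.na(col)
      if (any(okc) && !all(okc))
        m[!okc, a] <- stats::approx(which(okc), col[okc], xout = which(!okc),
                                    rule = 2)$y
    }
    if (anyNA(m)) {
      for (b in seq_len(nrow(m))) {
        row <- m[b, ]; okr <- !is.na(row)
        if (any(okr) && !all(okr))
          m[b, !okr] <- stats::approx(which(okr), row[okr], xout = which(!okr),
                                      rule = 2)$y
      }
    }
    m
  }
  ilm <- fill_na_matrix(ilm); rpe <- fill_na_matrix(rpe)
  csi <- fill_na_matrix(csi)
  # replace B-scans that are mostly invalid by neighbour interpolation
  bad_b <- which(rowMeans(valid) < 0.5)
  good_b <- setdiff(seq_len(nb), bad_b)
  if (length(bad_b) && length(good_b) >= 2) {
    fill <- function(m) {
      for (a in seq_len(na_))
        m[bad_b, a] <- stats::approx(good_b, m[good_b, a], xout = bad_b,
                                     rule = 2)$y
      m
    }
    ilm <- fill(ilm); rpe <- fill(rpe); csi <- fill(csi)
    valid[bad_b, ] <- TRUE
  }
  # en-face surface regularisation: median across B-scans, then a light
  # separable mean (the anatomy is smooth at this scale)
  if (nb >= 3) {
    med3 <- function(m) apply(m, 2, function(x) stats::runmed(x, 3, endrule = "keep"))
    reg <- function(m) smooth_matrix(med3(m), 3L)
    ilm <- reg(ilm); rpe <- reg(rpe); csi <- reg(csi)
  }
  rpe <- pmax(rpe, ilm); csi <- pmax(csi, rpe)
  ilm <- clamp(ilm, 0, nz - 1); rpe <- clamp(rpe, 0, nz - 1)
  csi <- clamp(csi, 0, nz - 1)
  ilm[!valid] <- NA_real_; rpe[!valid] <- NA_real_; csi[!valid] <- NA_real_
  out <- surface_set(ilm, rpe, csi, valid = valid, depth_px = nz)
  attr(out, "invalid_fraction") <- 1 - mean(valid)
  attr(out, "quality") <- if (mean(valid) < 0.8) "poor" else "ok"
  attr(out, "replaced_bscans") <- bad_b
  out
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two logical masks of identical
#' shape; two empty masks score 1 by convention.
#'
#' @param a,b logical arrays of the same dimension.
#' @return overlap fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
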