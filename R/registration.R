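#' Rigid 3D transform
#'
#' A rotation (Euler angles, degrees, applied about the depth, A-scan and
#' B-scan axes in that order) about a centre point plus a translation, all
#' in physical millimetre coordinates, so that Bennett calibration and
#' registration compose unambiguously. Maps fixed-space points into
#' moving-space points (the resampling convention):
#' `p' = R (p - c) + c + t`.
#'
#' @param rotation_deg numeric length 3: angles about the depth, A-scan and
#'   B-scan axes, degrees.
#' @param translation_mm numeric length 3 `(dz, da, db)`, mm.
#' @param center_mm rotation centre `(z, a, b)`, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3, length(translation_mm) == 3,
            length(center_mm) == 3)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s; trans (mm): %s; centre (mm): %s\n",
              paste(signif(x$rotation_deg, 4), collapse = ", "),
              paste(signif(x$translation_mm, 4), collapse = ", "),
              paste(signif(x$center_mm, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  c1 <- cos(r[1]); s1 <- sin(r[1])
  c2 <- cos(r[2]); s2 <- sin(r[2])
  c3 <- cos(r[3]); s3 <- sin(r[3])
  R1 <- matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
  R2 <- matrix(c(c2, 0, -s2, 0, 1, 0, s2, 0, c2), 3, 3)
  R3 <- matrix(c(c3, s3, 0, -s3, c3, 0, 0, 0, 1), 3, 3)
  R1 %*% R2 %*% R3
}

rotation_angles <- function(R) {
  beta <- asin(clamp(R[1, 3], -1, 1))
  gamma <- atan2(-R[1, 2], R[1, 1])
  alpha <- atan2(-R[2, 3], R[3, 3])
  c(alpha, beta, gamma) * 180 / pi
}

#' Apply a rigid transform to physical points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric `N x 3` matrix of `(z, a, b)` mm coordinates.
#' @return transformed `N x 3` matrix.
#' @export
transform_points <- function(transform, points) {
  R <- rotation_matrix(transform$rotation_deg)
  ctr <- transform$center_mm
  sweep(sweep(points, 2, ctr) %*% t(R), 2, ctr + transform$translation_mm, `+`)
}

#' Invert / compose rigid transforms
#'
#' `invert_transform(t)` returns the transform undoing `t`;
#' `compose_transforms(t2, t1)` returns the transform equivalent to applying
#' `t1` first, then `t2` (both must share a centre).
#'
#' @param transform,t1,t2 [rigid_transform()] objects.
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform$rotation_deg)
  rigid_transform(rotation_angles(t(R)),
                  -as.numeric(t(R) %*% transform$translation_mm),
                  transform$center_mm)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(t2, t1) {
  stopifnot(max(abs(t1$center_mm - t2$center_mm)) < 1e-9)
  R1 <- rotation_matrix(t1$rotation_deg)
  R2 <- rotation_matrix(t2$rotation_deg)
  rigid_transform(rotation_angles(R2 %*% R1),
                  as.numeric(R2 %*% t1$translation_mm) + t2$translation_mm,
                  t1$center_mm)
}

#' Serialize a rigid transform as JSON
#'
#' @param transform a [rigid_transform()].
#' @param path JSON file path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation_deg, x$translation_mm, x$center_mm)
}

# small separable 3D box blur (width 3 along each axis, edge-replicated);
# applied symmetrically to both volumes before the fine metric so the
# smoothing of the resampled moving volume does not bias the optimum
blur3d <- function(arr) {
  d <- dim(arr)
  a1 <- array(box_smooth_cpp(matrix(arr, d[1], d[2] * d[3]), 3L, 1L), d)
  a2 <- aperm(array(box_smooth_cpp(matrix(aperm(a1, c(2, 1, 3)), d[2], d[1] * d[3]),
                                   3L, 1L), c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(box_smooth_cpp(matrix(aperm(a2, c(3, 1, 2)), d[3], d[1] * d[2]),
                             3L, 1L), c(d[3], d[1], d[2])), c(2, 3, 1))
}

# mean-pool a 3D array by a factor of 2 along every axis (trimming odd ends)
downsample2 <- function(arr) {
  d <- dim(arr) %/% 2L * 2L
  arr <- arr[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  arr <- (arr[seq(1, d[1], 2), , , drop = FALSE] + arr[seq(2, d[1], 2), , , drop = FALSE]) / 2
  arr <- (arr[, seq(1, d[2], 2), , drop = FALSE] + arr[, seq(2, d[2], 2), , drop = FALSE]) / 2
  (arr[, , seq(1, d[3], 2), drop = FALSE] + arr[, , seq(2, d[3], 2), drop = FALSE]) / 2
}

# physical (z, a, b) mm coordinates of a volume's voxel grid, optionally
# strided and restricted to an interior margin (in voxels) so that small
# transforms keep every query inside the moving volume and the metric stays
# smooth; returns list(points, values)
grid_points <- function(arr, pitch, stride = 1L, margin = c(0L, 0L, 0L)) {
  d <- dim(arr)
  zi <- seq(1L + margin[1], d[1] - margin[1], stride)
  ai <- seq(1L + margin[2], d[2] - margin[2], stride)
  bi <- seq(1L + margin[3], d[3] - margin[3], stride)
  pts <- cbind(rep((zi - 1) * pitch[1], times = length(ai) * length(bi)),
               rep(rep((ai - 1) * pitch[2], each = length(zi)), times = length(bi)),
               rep((bi - 1) * pitch[3], each = length(zi) * length(ai)))
  vals <- as.vector(arr[zi, ai, bi])
  list(points = pts, values = vals)
}

#' Estimate the rigid transform aligning a moving volume to a fixed volume
#'
#' Minimises the mean-squared intensity difference between the fixed volume
#' and the transformed, trilinearly interpolated moving volume over a
#' 2-level multi-resolution pyramid, starting from identity (same-session
#' OCT volumes are near-aligned). The 6 rigid parameters are optimised by a
#' derivative-free simplex search at each level: the trilinear MSE is only
#' piecewise smooth, which defeats finite-difference gradient methods.
#' If the optimum does not improve on the identity metric the identity
#' transform is returned with a warning and status `"not_improved"`.
#'
#' @param moving,fixed [oct_volume()] objects with identical physical
#'   extents and preprocessing state.
#' @param opts list: `stride_coarse`, `stride_fine` (grid subsampling at the
#'   two levels), `maxit_coarse`, `maxit_fine`, `maxit_refine`, and
#'   `refine_interp` (run the symmetric half-transform refinement; disable
#'   for speed when sub-half-degree depth-axis rotation accuracy is not
#'   needed).
#' @return a [rigid_transform()] with attributes `metric_identity`,
#'   `metric_final` and `status`.
#' @export
estimate_rigid <- function(moving, fixed, opts = list()) {
  stopifnot(inherits(moving, "oct_volume"), inherits(fixed, "oct_volume"))
  if (abs(moving$transverse_extent_mm - fixed$transverse_extent_mm) > 1e-9 ||
      abs(moving$axial_extent_mm - fixed$axial_extent_mm) > 1e-9)
    stop("volumes must share physical extents")
  o <- utils::modifyList(list(stride_coarse = 2L, stride_fine = 2L,
                              maxit_coarse = 500L, maxit_fine = 250L,
                              maxit_refine = 250L, refine_interp = TRUE), opts)
  pitch <- unname(voxel_pitch_mm(fixed))
  d <- dim(fixed$data)
  ctr <- (d - 1) / 2 * pitch
  make_metric <- function(mov_arr, mov_pitch, fix_pts, fix_vals) {
    force(mov_arr); force(mov_pitch)
    dims <- dim(mov_arr)
    function(par) {
      tr <- rigid_transform(par[1:3], par[4:6], ctr)
      p <- transform_points(tr, fix_pts)
      m <- mse_interp_cpp(mov_arr, dims,
                          p[, 1] / mov_pitch[1] + 1,
                          p[, 2] / mov_pitch[2] + 1,
                          p[, 3] / mov_pitch[3] + 1, fix_vals)
      if (m[2] < 0.25) return(1e6)
      m[1]
    }
  }
  par <- rep(0, 6)
  # interior margins (voxels) keeping every query inside for small transforms
  marg <- function(d) pmax(2L, pmin(c(16L, 5L, 5L), d %/% 6L))
  # level 2: half-resolution volumes
  fix2 <- downsample2(fixed$data); mov2 <- downsample2(moving$data)
  gp2 <- grid_points(fix2, pitch * 2, stride = o$stride_coarse,
                     margin = marg(dim(fix2)))
  m2 <- make_metric(mov2, pitch * 2, gp2$points, gp2$values)
  fit2 <- stats::optim(par, m2, method = "Nelder-Mead",
                       control = list(maxit = o$maxit_coarse, reltol = 1e-9,
                                      parscale = c(0.5, 0.5, 0.5, pitch)))
  # level 1: full resolution, strided grid, symmetric 3-box blur
  fixb <- blur3d(fixed$data); movb <- blur3d(moving$data)
  gp1 <- grid_points(fixb, pitch, stride = o$stride_fine, margin = marg(d))
  m1 <- make_metric(movb, pitch, gp1$points, gp1$values)
  fit1 <- stats::optim(fit2$par, m1, method = "Nelder-Mead",
                       control = list(maxit = o$maxit_fine, reltol = 1e-9,
                                      parscale = c(0.2, 0.2, 0.2, pitch / 2)))
  # simplex restart guards against premature contraction
  fit1 <- stats::optim(fit1$par, m1, method = "Nelder-Mead",
                       control = list(maxit = o$maxit_fine, reltol = 1e-9,
                                      parscale = c(0.1, 0.1, 0.1, pitch / 4)))
  if (isTRUE(o$refine_interp)) {
    # symmetric (half-transform) refinement: sample both volumes midway, so
    # each is trilinearly interpolated at half the offset and the
    # interpolation smoothing cancels between the two arms. This removes a
    # depth-axis rotation bias (worst near half-voxel translations) that an
    # asymmetric fixed-vs-interpolated-moving metric cannot avoid.
    dims_f <- dim(fixb); dims_m <- dim(movb)
    sym_metric <- function(par) {
      half <- rigid_transform(par[1:3] / 2, par[4:6] / 2, ctr)
      pf <- transform_points(invert_transform(half), gp1$points)
      pm <- transform_points(half, gp1$points)
      vf <- interp3_cpp(fixb, dims_f, pf[, 1] / pitch[1] + 1,
                        pf[, 2] / pitch[2] + 1, pf[, 3] / pitch[3] + 1)
      vm <- interp3_cpp(movb, dims_m, pm[, 1] / pitch[1] + 1,
                        pm[, 2] / pitch[2] + 1, pm[, 3] / pitch[3] + 1)
      okv <- !is.na(vf) & !is.na(vm)
      if (mean(okv) < 0.25) return(1e6)
      mean((vf[okv] - vm[okv])^2)
    }
    fit_s <- stats::optim(fit1$par, sym_metric, method = "Nelder-Mead",
                          control = list(maxit = o$maxit_refine, reltol = 1e-10,
                                         parscale = c(0.1, 0.1, 0.1, pitch / 4)))
    fit1 <- list(par = fit_s$par, value = m1(fit_s$par))
  }
  metric_id <- m1(rep(0, 6))
  status <- "converged"
  par_final <- fit1$par
  metric_final <- fit1$value
  if (metric_final >= metric_id) {
    warning("registration metric not improved from identity; returning identity")
    par_final <- rep(0, 6)
    metric_final <- metric_id
    status <- "not_improved"
  }
  out <- rigid_transform(par_final[1:3], par_final[4:6], ctr)
  attr(out, "metric_identity") <- metric_id
  attr(out, "metric_final") <- metric_final
  attr(out, "status") <- status
  out
}

#' Resample a moving volume onto a fixed volume's grid
#'
#' Trilinear interpolation of the moving volume at the transformed fixed
#' grid points; voxels that map outside the moving field are set to 0 and
#' recorded in the `field_mask` attribute. The output carries the fixed
#' volume's calibration.
#'
#' @param moving an [oct_volume()].
#' @param transform a [rigid_transform()] mapping fixed-space points to
#'   moving-space points.
#' @param fixed the [oct_volume()] defining the target grid.
#' @return an [oct_volume()] on the fixed grid with a logical `field_mask`
#'   attribute (TRUE where the moving volume covered the voxel).
#' @export
resample_to_grid <- function(moving, transform, fixed) {
  stopifnot(inherits(moving, "oct_volume"), inherits(fixed, "oct_volume"),
            inherits(transform, "rigid_transform"))
  pitch <- unname(voxel_pitch_mm(fixed))
  mp <- unname(voxel_pitch_mm(moving))
  gp <- grid_points(fixed$data, pitch, stride = 1L)
  p <- transform_points(transform, gp$points)
  v <- trilinear_interp(moving$data, p[, 1] / mp[1] + 1, p[, 2] / mp[2] + 1,
                        p[, 3] / mp[3] + 1)
  mask <- !is.na(v)
  v[!mask] <- 0
  out <- fixed
  out$data <- array(v, dim = dim(fixed$data))
  out$axial_length_mm <- moving$axial_length_mm
  attr(out, "field_mask") <- array(mask, dim = dim(fixed$data))
  out
}
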