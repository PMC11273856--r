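#' Eye geometry configuration for the synthetic OCT generator
#'
#' Describes the layered posterior-eye phantom: a spherical mid-RPE cap of
#' radius `posterior_radius_mm` (apex, i.e. deepest point, at the fovea), a
#' retina of configurable mean thickness with a Gaussian foveal pit carved
#' into the ILM, and a choroid of configurable mean thickness and nasal-
#' temporal slope below the RPE. Defaults are the reduced test geometry
#' (64 x 64 x 256 voxels) covering the full-protocol physical extents of
#' 12 mm x 12 mm x 4.5 mm; the full 512 x 512 x 1920 grid is configuration
#' only. Thickness defaults reproduce a healthy-adult macula: foveal pit
#' depth and radius are chosen so that the 1 mm / 3 mm fovea-centred mean
#' retinal thicknesses are about 246 and 315 um, and the choroid mean is
#' 283 um.
#'
#' @param n_bscans,n_ascans,depth_px grid size (each >= 8).
#' @param transverse_extent_mm,axial_extent_mm physical extents, mm.
#' @param axial_length_mm the eye's axial length, mm (> 1.82; drives Bennett
#'   magnification scaling of the transverse pitch).
#' @param fovea_position integer `(bscan, ascan)` pair; default grid centre.
#' @param pit_depth_um,pit_radius_mm foveal pit depth and Gaussian radius.
#' @param retina_thickness_um,choroid_thickness_um numeric `(mean, slope)`
#'   field parameters: thickness in um at the fovea plus a linear slope in
#'   um per mm along the A-scan axis.
#' @param posterior_radius_mm radius of the spherical mid-RPE cap, mm.
#' @param rpe_apex_mm depth of the mid-RPE at the fovea, mm from the top of
#'   the scan.
#' @param surface_undulation_um amplitude of a smooth random axial
#'   undulation applied to the whole geometry (set 0 for exactly analytic
#'   surfaces).
#' @param orientation `"left"` (A-scan index runs temporal to nasal) or
#'   `"right"` (reversed).
#' @return an `eye_geometry_config` list.
#' @export
eye_geometry_config <- function(n_bscans = 64L, n_ascans = 64L, depth_px = 256L,
                                transverse_extent_mm = 12, axial_extent_mm = 4.5,
                                axial_length_mm = 25.563,
                                fovea_position = NULL,
                                pit_depth_um = 123, pit_radius_mm = 0.75,
                                retina_thickness_um = c(mean = 345, slope = 0),
                                choroid_thickness_um = c(mean = 283, slope = -5),
                                posterior_radius_mm = 20,
                                rpe_apex_mm = 3.2,
                                surface_undulation_um = 4,
                                orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  stopifnot(n_bscans >= 8, n_ascans >= 8, depth_px >= 8,
            transverse_extent_mm > 0, axial_extent_mm > 0,
            axial_length_mm > 1.82,
            pit_depth_um >= 0, pit_radius_mm > 0,
            length(retina_thickness_um) == 2, retina_thickness_um[1] > 0,
            length(choroid_thickness_um) == 2, choroid_thickness_um[1] > 0,
            posterior_radius_mm > 0, rpe_apex_mm > 0,
            surface_undulation_um >= 0)
  if (is.null(fovea_position))
    fovea_position <- c(floor(n_bscans / 2) + 1L, floor(n_ascans / 2) + 1L)
  stopifnot(length(fovea_position) == 2,
            fovea_position[1] >= 1, fovea_position[1] <= n_bscans,
            fovea_position[2] >= 1, fovea_position[2] <= n_ascans)
  if (pit_radius_mm > transverse_extent_mm / 2)
    stop("pit_radius_mm exceeds half the transverse extent")
  structure(list(
    n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
    depth_px = as.integer(depth_px),
    transverse_extent_mm = transverse_extent_mm,
    axial_extent_mm = axial_extent_mm,
    axial_length_mm = axial_length_mm,
    fovea_position = as.integer(fovea_position),
    pit_depth_um = pit_depth_um, pit_radius_mm = pit_radius_mm,
    retina_thickness_um = unname(retina_thickness_um),
    choroid_thickness_um = unname(choroid_thickness_um),
    posterior_radius_mm = posterior_radius_mm,
    rpe_apex_mm = rpe_apex_mm,
    surface_undulation_um = surface_undulation_um,
    orientation = orientation
  ), class = "eye_geometry_config")
}

#' Noise configuration for OCT rendering
#'
#' Multiplicative unit-mean gamma speckle (shape `speckle_shape`; variance
#' `1/speckle_shape`, so `Inf` disables speckle), exponential depth
#' attenuation `exp(-attenuation_coeff * z_mm)`, and an additive background
#' floor.
#'
#' @param speckle_shape gamma shape (> 0, or `Inf` for no speckle).
#' @param attenuation_coeff signal decay per mm of depth (>= 0).
#' @param background_level additive intensity floor.
#' @param seed RNG seed; a fixed seed makes the render bit-identical.
#' @export
noise_config <- function(speckle_shape = 4, attenuation_coeff = 0.5,
                         background_level = 0.02, seed = 1L) {
  stopifnot(speckle_shape > 0, attenuation_coeff >= 0, background_level >= 0)
  structure(list(speckle_shape = speckle_shape,
                 attenuation_coeff = attenuation_coeff,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Stress-session effect configuration
#'
#' The between-session effect applied to a ground-truth eye: a signed
#' choroidal thickening (the CSI is displaced posteriorly; the retina is
#' untouched) followed by a small rigid motion of the whole geometry
#' (translation in voxels and a rotation about the depth axis).
#'
#' @param delta_ct_um choroidal thickening, um (signed).
#' @param rigid_shift_px numeric `(dz, db, da)` translation, voxels.
#' @param rigid_rot_deg rotation about the depth axis, degrees (|rot| < 5).
#' @param seed RNG seed (reserved; the effect itself is deterministic).
#' @export
stress_effect_config <- function(delta_ct_um = 3.326,
                                 rigid_shift_px = c(0, 0, 0),
                                 rigid_rot_deg = 0, seed = 1L) {
  stopifnot(length(rigid_shift_px) == 3, abs(rigid_rot_deg) < 5)
  structure(list(delta_ct_um = delta_ct_um,
                 rigid_shift_px = as.numeric(rigid_shift_px),
                 rigid_rot_deg = rigid_rot_deg,
                 seed = as.integer(seed)),
            class = "stress_effect_config")
}

axial_um_per_px <- function(config) config$axial_extent_mm * 1000 / config$depth_px

# Bennett-scaled transverse pitches (mm per pixel) for a geometry config.
scaled_pitch_mm <- function(config) {
  q <- bennett_scale(config$axial_length_mm)
  c(bscan = config$transverse_extent_mm * q / config$n_bscans,
    ascan = config$transverse_extent_mm * q / config$n_ascans)
}

#' Generate a ground-truthed synthetic eye
#'
#' Builds the three boundary surfaces (ILM, mid-RPE, CSI) of the phantom
#' described by `config`. The mid-RPE lies on a sphere cap whose apex (the
#' deepest point) sits at the fovea; the ILM carries a Gaussian foveal pit,
#' so its unique deepest point is the fovea. All physical coordinates use
#' the Bennett-scaled transverse pitch of the configured axial length.
#'
#' @param config an [eye_geometry_config()].
#' @param seed RNG seed for the smooth random surface undulation.
#' @return a `ground_truth` list: `surfaces` ([surface_set()]), `ct_map_um`,
#'   `fovea`, `config`, `applied_transform`, `applied_delta_ct_um`.
#' @export
generate_eye <- function(config, seed = 1L) {
  stopifnot(inherits(config, "eye_geometry_config"))
  nb <- config$n_bscans; na_ <- config$n_ascans; nz <- config$depth_px
  pit <- scaled_pitch_mm(config)
  fb <- config$fovea_position[1]; fa <- config$fovea_position[2]
  xb <- (seq_len(nb) - fb) * pit["bscan"]
  xa <- (seq_len(na_) - fa) * pit["ascan"]
  XA <- matrix(xa, nb, na_, byrow = TRUE)
  XB <- matrix(xb, nb, na_)
  rho2 <- XA^2 + XB^2
  R <- config$posterior_radius_mm
  if (max(rho2) >= R^2)
    stop("posterior_radius_mm too small for the scanned extent")
  rpe_mm <- config$rpe_apex_mm - (R - sqrt(R^2 - rho2))
  if (config$surface_undulation_um > 0) {
    und <- with_seed(seed, {
      ph <- stats::runif(6, 0, 2 * pi)
      fr <- stats::runif(4, 0.5, 1.5)
      w <- cos(2 * pi * fr[1] * XA / config$transverse_extent_mm + ph[1]) *
        cos(2 * pi * fr[2] * XB / config$transverse_extent_mm + ph[2]) +
        0.6 * cos(2 * pi * fr[3] * (XA + XB) / config$transverse_extent_mm + ph[3]) *
        cos(2 * pi * fr[4] * (XA - XB) / config$transverse_extent_mm + ph[4])
      w / max(abs(w))
    })
    rpe_mm <- rpe_mm + config$surface_undulation_um / 1000 * und
  }
  rt_um <- config$retina_thickness_um[1] + config$retina_thickness_um[2] * XA -
    config$pit_depth_um * exp(-rho2 / config$pit_radius_mm^2)
  ct_um <- config$choroid_thickness_um[1] + config$choroid_thickness_um[2] * XA
  if (any(rt_um <= 0) || any(ct_um <= 0))
    stop("thickness field became non-positive; check slope parameters")
  ilm_mm <- rpe_mm - rt_um / 1000
  csi_mm <- rpe_mm + ct_um / 1000
  dz_mm <- config$axial_extent_mm / nz
  to_px <- function(mm) mm / dz_mm
  ilm <- to_px(ilm_mm); rpe <- to_px(rpe_mm); csi <- to_px(csi_mm)
  if (min(ilm) < 1 || max(csi) > nz - 2)
    stop("generated surfaces fall outside the axial depth range")
  surfaces <- surface_set(ilm, rpe, csi, depth_px = nz)
  structure(list(
    surfaces = surfaces,
    ct_map_um = (csi - rpe) * axial_um_per_px(config),
    fovea = c(fb, fa),
    config = config,
    applied_transform = NULL,
    applied_delta_ct_um = 0
  ), class = "ground_truth")
}

# Band reflectivities of the rendered phantom. The RPE is the brightest
# band; the vitreous is darkest; the choroid carries multiplicative texture.
render_reflectivities <- function() {
  c(vitreous = 0.04, retina = 0.38, rpe = 0.95, choroid = 0.30, sclera = 0.14)
}

#' Render a ground-truth eye into an OCT volume
#'
#' Layer-wise reflectivity bands (vitreous < retina < RPE, textured choroid,
#' dim sclera) scaled by `exp(-attenuation_coeff * z_mm)`, multiplied by
#' unit-mean gamma speckle, plus the background floor; intensities are
#' clipped to `[0, 1]`. A bright RPE band of about 40 um total thickness is
#' drawn around the mid-RPE surface.
#'
#' @param truth a `ground_truth` from [generate_eye()].
#' @param noise a [noise_config()].
#' @param choroid_texture_sd amplitude (SD of the multiplicative modulation,
#'   clipped at 2.7 SD) of the smooth 3D vascular texture of the choroid;
#'   0 renders a texture-free choroid (the noise-free limit).
#' @return an [oct_volume()].
#' @export
render_volume <- function(truth, noise = noise_config(), choroid_texture_sd = 0.15) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_config"))
  cfg <- truth$config
  nz <- cfg$depth_px; na_ <- cfg$n_ascans; nb <- cfg$n_bscans
  s <- truth$surfaces
  if (min(s$ilm_px) < 0 || max(s$csi_px) > nz - 1)
    stop("truth surfaces outside the depth range")
  refl <- render_reflectivities()
  dz_mm <- cfg$axial_extent_mm / nz
  rpe_half_px <- 20 / (axial_um_per_px(cfg))   # 20 um half-thickness
  k <- 0:(nz - 1L)
  atten <- exp(-noise$attenuation_coeff * k * dz_mm)
  arr <- array(0, dim = c(nz, na_, nb))
  with_seed(noise$seed, {
    # smooth 3D choroidal texture field (vascular structure is 3D, so the
    # field is correlated across B-scans as well as within them)
    tex3 <- array(stats::rnorm(nz * na_ * nb), dim = c(nz, na_, nb))
    tex3 <- array(box_smooth_cpp(matrix(tex3, nz, na_ * nb), 3L, 1L),
                  dim = c(nz, na_, nb))
    tex3 <- aperm(array(box_smooth_cpp(matrix(aperm(tex3, c(2, 1, 3)), na_, nz * nb),
                                       3L, 1L), dim = c(na_, nz, nb)), c(2, 1, 3))
    tex3 <- aperm(array(box_smooth_cpp(matrix(aperm(tex3, c(3, 1, 2)), nb, nz * na_),
                                       3L, 1L), dim = c(nb, nz, na_)), c(2, 3, 1))
    tex3 <- tex3 / max(stats::sd(tex3), 1e-12) * choroid_texture_sd
    for (b in seq_len(nb)) {
      ilm <- matrix(s$ilm_px[b, ], nz, na_, byrow = TRUE)
      rpe <- matrix(s$midrpe_px[b, ], nz, na_, byrow = TRUE)
      csi <- matrix(s$csi_px[b, ], nz, na_, byrow = TRUE)
      K <- matrix(k, nz, na_)
      # partial-volume rendering: each voxel (spanning K +/- 0.5) averages
      # the piecewise-constant band profile it covers, so band edges are
      # antialiased rather than snapped to the voxel grid
      cov <- function(bound) clamp(bound - (K - 0.5), 0, 1)
      c1 <- cov(ilm)                      # fraction above the ILM
      c2 <- cov(rpe - rpe_half_px)        # above the RPE band
      c3 <- cov(rpe + rpe_half_px)        # above the RPE band's bottom
      c4 <- cov(csi)                      # above the CSI
      cho_refl <- refl["choroid"] *
        (1 + clamp(tex3[, , b], -2.7 * choroid_texture_sd,
                   2.7 * choroid_texture_sd))
      band <- refl["vitreous"] * c1 + refl["retina"] * (c2 - c1) +
        refl["rpe"] * (c3 - c2) + cho_refl * (c4 - c3) +
        refl["sclera"] * (1 - c4)
      img <- band * atten
      if (is.finite(noise$speckle_shape)) {
        spk <- matrix(stats::rgamma(nz * na_, shape = noise$speckle_shape,
                                    rate = noise$speckle_shape), nz, na_)
        img <- img * spk
      }
      arr[, , b] <- clamp(noise$background_level + img, 0, 1)
    }
  })
  oct_volume(arr, transverse_extent_mm = cfg$transverse_extent_mm,
             axial_extent_mm = cfg$axial_extent_mm,
             axial_length_mm = cfg$axial_length_mm,
             orientation = cfg$orientation)
}

#' Apply a between-session stress effect to a ground truth
#'
#' Displaces the CSI posteriorly by `delta_ct_um` (choroidal thickening; the
#' retinal surfaces are untouched), then moves the whole geometry rigidly by
#' the configured translation and depth-axis rotation. Surfaces are
#' resampled bilinearly on the en-face grid (nearest-edge extrapolation at
#' the borders); the applied effect is recorded on the returned truth.
#'
#' @param truth a `ground_truth`.
#' @param effect a [stress_effect_config()].
#' @return a new `ground_truth` with updated surfaces, `ct_map_um`, `fovea`,
#'   `applied_transform` and `applied_delta_ct_um`.
#' @export
apply_stress_effect <- function(truth, effect) {
  stopifnot(inherits(truth, "ground_truth"), inherits(effect, "stress_effect_config"))
  cfg <- truth$config
  nz <- cfg$depth_px
  dz_px <- effect$delta_ct_um / axial_um_per_px(cfg)
  ilm <- truth$surfaces$ilm_px
  rpe <- truth$surfaces$midrpe_px
  csi <- truth$surfaces$csi_px + dz_px
  if (any(csi < rpe))
    stop("negative thickening exceeds choroidal thickness")
  # rigid motion: rotation about the depth axis around the grid centre,
  # then translation (dz, db, da) in voxels
  sh <- effect$rigid_shift_px
  th <- effect$rigid_rot_deg * pi / 180
  nb <- nrow(ilm); na_ <- ncol(ilm)
  cb <- (nb + 1) / 2; ca <- (na_ + 1) / 2
  B <- matrix(seq_len(nb), nb, na_)
  A <- matrix(seq_len(na_), nb, na_, byrow = TRUE)
  # inverse map: where did the surface value at (b, a) come from
  b0 <- B - cb - sh[2]; a0 <- A - ca - sh[3]
  bs <- cos(th) * b0 + sin(th) * a0 + cb
  as_ <- -sin(th) * b0 + cos(th) * a0 + ca
  warp <- function(m) matrix(bilinear_interp(m, as.vector(bs), as.vector(as_)), nb, na_)
  ilm2 <- warp(ilm) + sh[1]
  rpe2 <- warp(rpe) + sh[1]
  csi2 <- warp(csi) + sh[1]
  if (min(ilm2) < 0 || max(csi2) > nz - 1)
    stop("stress effect pushes surfaces outside the depth range")
  # forward-map the fovea
  fb0 <- truth$fovea[1] - cb; fa0 <- truth$fovea[2] - ca
  fov <- c(cos(th) * fb0 - sin(th) * fa0 + cb + sh[2],
           sin(th) * fb0 + cos(th) * fa0 + ca + sh[3])
  structure(list(
    surfaces = surface_set(ilm2, rpe2, csi2, depth_px = nz),
    ct_map_um = (csi2 - rpe2) * axial_um_per_px(cfg),
    fovea = as.integer(round(clamp(fov, 1, c(nb, na_)))),
    config = cfg,
    applied_transform = list(rigid_shift_px = sh, rigid_rot_deg = effect$rigid_rot_deg),
    applied_delta_ct_um = effect$delta_ct_um
  ), class = "ground_truth")
}

#' RR-interval series
#'
#' Ordered RR intervals (ms) with cumulative beat end-times and labelled
#' acquisition-end event markers.
#'
#' @param rr_ms positive numeric vector of RR intervals, ms.
#' @param events named numeric vector of event times (ms) within the
#'   recording span.
#' @export
rr_series <- function(rr_ms, events = numeric()) {
  stopifnot(is.numeric(rr_ms), all(rr_ms > 0))
  t_end <- cumsum(rr_ms)
  if (length(events)) {
    stopifnot(is.numeric(events))
    if (any(events < 0) || any(events > t_end[length(t_end)]))
      stop("events beyond the total recording duration")
  }
  structure(list(rr_ms = as.numeric(rr_ms), t_end_ms = t_end, events = events),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.1f s, %d events\n",
              length(x$rr_ms), x$t_end_ms[length(x$t_end_ms)] / 1000,
              length(x$events)))
  invisible(x)
}

#' Generate an autocorrelated RR-interval series
#'
#' First-order autoregressive Gaussian RR sequence with marginal mean
#' `mean_rr_ms` and marginal SD `sd_rr_ms` (AR coefficient `ar_coef`,
#' default 0.4, which keeps RMSSD below the overall SD as in real
#' recordings).
#'
#' @param mean_rr_ms,sd_rr_ms marginal mean and SD of the intervals, ms;
#'   `mean_rr_ms > 3 * sd_rr_ms` is required so intervals stay positive.
#' @param n_beats number of beats.
#' @param events named numeric event times (ms).
#' @param seed RNG seed.
#' @param ar_coef lag-1 autocorrelation in `[0, 0.95]`.
#' @return an [rr_series()].
#' @export
generate_rr_series <- function(mean_rr_ms, sd_rr_ms, n_beats,
                               events = numeric(), seed = 1L, ar_coef = 0.4) {
  stopifnot(mean_rr_ms > 0, sd_rr_ms >= 0, n_beats >= 1,
            ar_coef >= 0, ar_coef <= 0.95)
  if (mean_rr_ms <= 3 * sd_rr_ms)
    stop("mean_rr_ms must exceed 3 * sd_rr_ms to keep intervals positive")
  x <- if (sd_rr_ms == 0) rep(0, n_beats) else with_seed(seed, {
    e <- stats::rnorm(n_beats, 0, sd_rr_ms * sqrt(1 - ar_coef^2))
    e[1] <- stats::rnorm(1, 0, sd_rr_ms)   # start at the marginal distribution
    as.numeric(stats::filter(e, ar_coef, method = "recursive"))
  })
  rr <- mean_rr_ms + x
  if (any(rr <= 0)) rr <- pmax(rr, mean_rr_ms / 10)
  rr_series(rr, events = events)
}

#' Write / read an RR series as plain text
#'
#' One RR interval (ms) per line, with a JSON sidecar of labelled event
#' times, mirroring common chest-strap app exports.
#'
#' @param series an [rr_series()].
#' @param path text file path; events go to `<path>.events.json`.
#' @export
write_rr_series <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  writeLines(sprintf("%.4f", series$rr_ms), path)
  jsonlite::write_json(as.list(series$events), paste0(path, ".events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rr_series
#' @export
read_rr_series <- function(path) {
  rr <- as.numeric(readLines(path))
  ev_path <- paste0(path, ".events.json")
  events <- if (file.exists(ev_path))
    unlist(jsonlite::read_json(ev_path, simplifyVector = TRUE)) else numeric()
  rr_series(rr, events = events)
}
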