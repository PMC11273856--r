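test_that("generators are pure functions of config and seed", {
  cfg <- mid_geometry()
  t1 <- generate_eye(cfg, seed = 5)
  t2 <- generate_eye(cfg, seed = 5)
  expect_identical(t1, t2)
  t3 <- generate_eye(cfg, seed = 6)
  expect_false(identical(t1$surfaces$midrpe_px, t3$surfaces$midrpe_px))
  v1 <- render_volume(t1, noise_config(seed = 3))
  v2 <- render_volume(t1, noise_config(seed = 3))
  expect_identical(v1$data, v2$data)
})

test_that("thickness map is consistent with the surfaces everywhere", {
  truth <- generate_eye(mid_geometry(), seed = 9)
  aupp <- 4.5 * 1000 / 160
  ct_from_surf <- (truth$surfaces$csi_px - truth$surfaces$midrpe_px) * aupp
  expect_lt(max(abs(ct_from_surf - truth$ct_map_um)), 0.5 * aupp)
  expect_true(all(truth$surfaces$ilm_px <= truth$surfaces$midrpe_px))
  expect_true(all(truth$surfaces$midrpe_px <= truth$surfaces$csi_px))
})

test_that("mid-RPE of a noise-free eye lies on the configured sphere cap", {
  cfg <- analytic_geometry(posterior_radius_mm = 12, transverse_extent_mm = 10,
                           rpe_apex_mm = 3.6)
  truth <- generate_eye(cfg, seed = 1)
  cal <- calibration(cfg$depth_px, cfg$n_ascans, cfg$n_bscans,
                     transverse_extent_mm = cfg$transverse_extent_mm,
                     axial_length_mm = cfg$axial_length_mm)
  # central B-scan cross-section in physical mm
  b <- truth$fovea[1]
  x <- (seq_len(cfg$n_ascans) - truth$fovea[2]) *
    cal$scaled_transverse_um_per_px["ascan"] / 1000
  z <- truth$surfaces$midrpe_px[b, ] * cal$axial_um_per_px / 1000
  fit <- fit_circle_2d(x, z)
  expect_equal(fit$radius, 12, tolerance = 1e-3)
})

test_that("uniform choroid config yields a uniform thickness map", {
  cfg <- analytic_geometry(choroid_thickness_um = c(280, 0))
  truth <- generate_eye(cfg, seed = 2)
  aupp <- 4.5 * 1000 / 160
  expect_true(all(abs(truth$ct_map_um - 280) < 0.5 * aupp))
})

test_that("pit radius beyond half the extent is rejected", {
  expect_error(mid_geometry(pit_radius_mm = 7), "pit_radius")
})

test_that("rendered bands follow the reflectivity order and attenuation dims depth", {
  cfg <- analytic_geometry()
  truth <- generate_eye(cfg, seed = 3)
  # noise-free limit: piecewise-constant columns at the band reflectivities
  v0 <- render_volume(truth, noise_config(speckle_shape = Inf,
                                          attenuation_coeff = 0,
                                          background_level = 0, seed = 1))
  b <- truth$fovea[1]; a <- truth$fovea[2]
  col <- v0$data[, a, b]
  refl <- choromet:::render_reflectivities()
  ilm <- truth$surfaces$ilm_px[b, a]; rpe <- truth$surfaces$midrpe_px[b, a]
  csi <- truth$surfaces$csi_px[b, a]
  expect_equal(unname(col[floor(ilm) - 4]), unname(refl["vitreous"]))
  expect_equal(unname(col[round((ilm + rpe) / 2)]), unname(refl["retina"]))
  # at this axial pitch the RPE band is ~1.4 voxels, so the central voxel
  # may be partially blended with its neighbours (partial-volume rendering)
  expect_gt(unname(col[round(rpe) + 1]), 0.9 * unname(refl["rpe"]))
  expect_equal(unname(col[round(csi) + 6]), unname(refl["sclera"]))
  # attenuation: the same band is dimmer when rendered deeper
  va <- render_volume(truth, noise_config(speckle_shape = Inf,
                                          attenuation_coeff = 1,
                                          background_level = 0, seed = 1))
  shallow <- va$data[round(ilm) + 3, a, b]
  deep <- va$data[round(rpe) - 3, a, b]   # same retina band, deeper sample
  expect_lt(deep, shallow)
})

test_that("stress effect displaces only the CSI and records itself", {
  truth <- generate_eye(analytic_geometry(), seed = 4)
  # identity effect
  same <- apply_stress_effect(truth, stress_effect_config(0, c(0, 0, 0), 0))
  expect_equal(same$surfaces$csi_px, truth$surfaces$csi_px, tolerance = 1e-9)
  expect_equal(same$surfaces$ilm_px, truth$surfaces$ilm_px, tolerance = 1e-9)
  # pure thickening
  aupp <- 4.5 * 1000 / 160
  eff <- apply_stress_effect(truth, stress_effect_config(3.3, c(0, 0, 0), 0))
  expect_equal(mean(eff$ct_map_um - truth$ct_map_um), 3.3,
               tolerance = 0.5 * aupp)
  expect_equal(eff$surfaces$midrpe_px, truth$surfaces$midrpe_px,
               tolerance = 1e-9)
  expect_equal(eff$applied_delta_ct_um, 3.3)
  # pure translation by 2 B-scans: surfaces equal after shifting indices
  mv <- apply_stress_effect(truth, stress_effect_config(0, c(0, 2, 0), 0))
  expect_equal(mv$surfaces$ilm_px[3:32, ], truth$surfaces$ilm_px[1:30, ],
               tolerance = 1e-6)
  # pushing the CSI out of the grid is rejected
  expect_error(apply_stress_effect(truth, stress_effect_config(1e5, c(0, 0, 0), 0)),
               "depth range")
})

test_that("RR generator honours its contracts", {
  # degenerate: zero variability
  s0 <- generate_rr_series(800, 0, 50, seed = 1)
  expect_true(all(s0$rr_ms == 800))
  expect_equal(rmssd(s0$rr_ms), 0)
  # determinism
  s1 <- generate_rr_series(800, 40, 200, seed = 7)
  s2 <- generate_rr_series(800, 40, 200, seed = 7)
  expect_identical(s1$rr_ms, s2$rr_ms)
  # non-positive interval guard
  expect_error(generate_rr_series(100, 40, 10), "3 \\* sd")
  # events beyond duration are rejected
  expect_error(generate_rr_series(800, 10, 10, events = c(end = 1e6)),
               "duration")
})

test_that("baseline vs stress RR means reproduce the expected HR rise", {
  # 60000/779 = 77.0 bpm vs 60000/692 = 86.7 bpm: difference 9.7 bpm
  sb <- generate_rr_series(779, 34, 160, seed = 21)
  ss <- generate_rr_series(692, 23, 180, seed = 22)
  hr_b <- mean_hr(sb$rr_ms)
  hr_s <- mean_hr(ss$rr_ms)
  expect_equal(hr_s - hr_b, 60000 / 692 - 60000 / 779, tolerance = 1.5)
})

test_that("volume and RR series survive a file round-trip", {
  truth <- generate_eye(mid_geometry(), seed = 11)
  vol <- render_volume(truth, noise_config(seed = 12))
  tmp <- tempfile(fileext = ".tif")
  write_oct_volume(vol, tmp)
  back <- read_oct_volume(tmp)
  expect_equal(dim(back$data), dim(vol$data))
  expect_lt(max(abs(back$data - vol$data)), 1e-6)
  expect_equal(back$axial_length_mm, vol$axial_length_mm)
  rr <- generate_rr_series(800, 30, 50, events = c(scan_end = 20000), seed = 3)
  tmp2 <- tempfile(fileext = ".txt")
  write_rr_series(rr, tmp2)
  rr2 <- read_rr_series(tmp2)
  expect_equal(rr2$rr_ms, rr$rr_ms, tolerance = 1e-6)
  expect_equal(unname(rr2$events), unname(rr$events))
  # surfaces TSV
  tmp3 <- tempfile(fileext = ".tsv")
  write_surface_tsv(truth$surfaces, tmp3)
  s2 <- read_surface_tsv(tmp3, depth_px = 160)
  expect_equal(s2$ilm_px, truth$surfaces$ilm_px, tolerance = 1e-6)
})
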