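test_that("dice handles identity, disjoint, partial overlap and degenerate masks", {
  a <- array(FALSE, c(4, 4, 1)); a[1:2, 1:2, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(4, 4, 1)); b[3:4, 3:4, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  shifted <- array(FALSE, c(4, 4, 1)); shifted[1:2, 2:3, 1] <- TRUE
  expect_equal(dice(a, shifted), 0.5)   # overlap 2 of 4+4
  expect_equal(dice(array(FALSE, c(2, 2, 1)), array(FALSE, c(2, 2, 1))), 1)
  expect_error(dice(a, array(FALSE, c(3, 3, 1))), "shapes")
})

test_that("layer masks are disjoint and consistent with the surfaces", {
  truth <- generate_eye(mid_geometry(), seed = 3)
  m <- layer_masks(truth$surfaces, 160)
  expect_false(any(m$retina & m$choroid))
  k <- 0:159
  b <- 10; a <- 20
  inret <- k >= truth$surfaces$ilm_px[b, a] & k < truth$surfaces$midrpe_px[b, a]
  expect_equal(m$retina[, a, b], inret)
})

test_that("a noise-free rendered B-scan segments to sub-pixel mean accuracy", {
  cfg <- eye_geometry_config(surface_undulation_um = 0)
  truth <- generate_eye(cfg, seed = 5)
  vol <- render_volume(truth, noise_config(speckle_shape = Inf, seed = 1),
                       choroid_texture_sd = 0)
  env <- enhance_volume(vol)
  b <- truth$fovea[1]
  s <- segment_bscan(env$data[, , b], axial_um_per_px = 4.5 * 1000 / 256)
  inner <- 6:59   # clear of the slice borders
  ei <- abs(s$ilm_px - truth$surfaces$ilm_px[b, ])[inner]
  er <- abs(s$midrpe_px - truth$surfaces$midrpe_px[b, ])[inner]
  ec <- abs(s$csi_px - truth$surfaces$csi_px[b, ])[inner]
  expect_lt(mean(ei), 1)
  expect_lt(mean(er), 1)
  expect_lt(mean(ec), 1.5)
  expect_lt(max(ei), 4)
  expect_lt(max(er), 4)
  expect_true(all(s$valid))
})

test_that("segmentation is deterministic and enforces boundary ordering", {
  fx <- default_enhanced()
  s1 <- segment_volume(fx$enh)
  s2 <- segment_volume(fx$enh)
  expect_identical(s1$ilm_px, s2$ilm_px)
  expect_identical(s1$csi_px, s2$csi_px)
  ok <- s1$valid
  expect_true(all(s1$ilm_px[ok] <= s1$midrpe_px[ok]))
  expect_true(all(s1$midrpe_px[ok] <= s1$csi_px[ok]))
})

test_that("a default-noise volume meets the Dice quality floor", {
  fx <- default_enhanced()
  s <- segment_volume(fx$enh)
  mt <- layer_masks(fx$truth$surfaces, 256)
  ms <- layer_masks(s, 256)
  expect_gte(dice(mt$retina, ms$retina), 0.95)
  expect_gte(dice(mt$choroid, ms$choroid), 0.94)
})

test_that("an all-zero image flags every A-scan invalid", {
  s <- segment_bscan(matrix(0, 256, 64), axial_um_per_px = 17.58)
  expect_true(all(!s$valid))
  expect_true(all(is.na(s$ilm_px)))
})

test_that("a corrupted B-scan is interpolated from its neighbours and flagged", {
  fx <- default_enhanced()
  env <- fx$enh
  env$data[, , 20] <- 0
  s <- segment_volume(env, two_pass = FALSE)
  expect_true(20 %in% attr(s, "replaced_bscans"))
  expect_true(all(s$valid[20, ]))
  # interpolated surfaces stay close to the truth of that B-scan
  expect_lt(mean(abs(s$csi_px[20, 6:59] - fx$truth$surfaces$csi_px[20, 6:59])), 4)
})

test_that("surface sets validate their ordering invariant", {
  expect_error(surface_set(matrix(5, 2, 2), matrix(3, 2, 2), matrix(8, 2, 2)),
               "ordering")
  expect_error(surface_set(matrix(-1, 2, 2), matrix(3, 2, 2), matrix(8, 2, 2)),
               "non-negative")
  expect_silent(surface_set(matrix(1, 2, 2), matrix(3, 2, 2), matrix(8, 2, 2),
                            depth_px = 10))
})
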