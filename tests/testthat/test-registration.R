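test_that("transform algebra: inverse and composition", {
  ctr <- c(2.25, 6, 6)
  t1 <- rigid_transform(c(1.5, -0.8, 0.5), c(0.1, -0.2, 0.3), ctr)
  comp <- compose_transforms(invert_transform(t1), t1)
  expect_lt(max(abs(comp$rotation_deg)), 1e-6)
  expect_lt(max(abs(comp$translation_mm)), 1e-6)
  # applying then inverting maps points back
  set.seed(2)
  pts <- matrix(runif(30, 0, 10), 10, 3)
  back <- transform_points(invert_transform(t1), transform_points(t1, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("transforms survive JSON serialization", {
  t1 <- rigid_transform(c(0.2, 0.1, -0.3), c(0.01, 0.02, -0.03), c(1, 2, 3))
  f <- tempfile(fileext = ".json")
  write_transform(t1, f)
  t2 <- read_transform(f)
  expect_equal(t2$rotation_deg, t1$rotation_deg, tolerance = 1e-12)
  expect_equal(t2$translation_mm, t1$translation_mm, tolerance = 1e-12)
})

test_that("self-registration returns identity", {
  fx <- default_enhanced()
  suppressWarnings(tr <- estimate_rigid(fx$enh, fx$enh))
  pitch <- c(4.5 / 256, 12 / 64, 12 / 64)
  expect_lt(max(abs(tr$translation_mm / pitch)), 0.1)
  expect_lt(max(abs(tr$rotation_deg)), 0.05)
})

test_that("resampling: identity copies, integer shifts hit lattice points, range preserved", {
  fx <- default_enhanced()
  ev <- fx$enh
  tid <- rigid_transform(center_mm = (dim(ev$data) - 1) / 2 * c(4.5 / 256, 12 / 64, 12 / 64))
  out <- resample_to_grid(ev, tid, ev)
  expect_equal(out$data, ev$data, tolerance = 1e-12)
  # pure integer-voxel translation: interior voxels equal shifted originals
  tsh <- rigid_transform(translation_mm = c(0, 2 * 12 / 64, 0),
                         center_mm = tid$center_mm)
  out2 <- resample_to_grid(ev, tsh, ev)
  expect_equal(out2$data[, 1:62, ], ev$data[, 3:64, ], tolerance = 1e-9)
  # interpolation cannot create out-of-range intensities
  trot <- rigid_transform(c(0.7, 0.3, -0.4), c(0.01, 0.05, -0.04), tid$center_mm)
  out3 <- resample_to_grid(ev, trot, ev)
  expect_gte(min(out3$data), min(ev$data, 0))
  expect_lte(max(out3$data), max(ev$data))
})

test_that("a known 3-A-scan shift is recovered within a quarter pixel", {
  fx <- default_enhanced()
  ev <- fx$enh
  mv <- ev
  mv$data <- ev$data * 0
  mv$data[, 4:64, ] <- ev$data[, 1:61, ]
  tr <- estimate_rigid(mv, ev)
  pitch <- c(4.5 / 256, 12 / 64, 12 / 64)
  expect_equal(tr$translation_mm[2] / pitch[2], 3, tolerance = 0.25)
  expect_lt(max(abs(tr$rotation_deg)), 0.1)
})

test_that("random small transforms are recovered within the stated budget", {
  fx <- default_enhanced()
  ev <- fx$enh
  pitch <- c(4.5 / 256, 12 / 64, 12 / 64)
  ctr <- (dim(ev$data) - 1) / 2 * pitch
  set.seed(11)
  for (k in 1:4) {
    rot <- pmin(pmax(rnorm(3, 0, 0.3), -0.8), 0.8)
    tr <- rnorm(3, 0, 0.5) * pitch
    tk <- rigid_transform(rot, tr, ctr)
    mv <- resample_to_grid(ev, tk, ev)
    te <- estimate_rigid(mv, ev)
    ti <- invert_transform(tk)
    expect_lt(max(abs(te$rotation_deg - ti$rotation_deg)), 0.2)
    expect_lt(max(abs((te$translation_mm - ti$translation_mm) / pitch)), 0.25)
  }
})

test_that("structureless volumes flag non-improvement and fall back to identity", {
  flat <- oct_volume(array(0.5, c(32, 16, 16)))
  expect_warning(tr <- estimate_rigid(flat, flat), "not improved")
  expect_equal(attr(tr, "status"), "not_improved")
  expect_equal(tr$translation_mm, c(0, 0, 0))
})
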