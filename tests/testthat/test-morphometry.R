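test_that("Bennett magnification ratio matches hand-evaluated values", {
  expect_error(bennett_scale(1.82), "1.82")
  expect_equal(round(bennett_scale(25.563), 4), 1.0489)
  expect_equal(round(bennett_scale(24.0), 4), 0.9798)
  # doubling (AL - 1.82) doubles the ratio exactly
  expect_equal(bennett_scale(1.82 + 2 * 10), 2 * bennett_scale(1.82 + 10))
})

test_that("circle fit recovers exact and noisy circles", {
  f <- fit_circle_2d(c(0, 2, 4), c(0, 2, 0))
  expect_equal(f$center, c(2, 0), tolerance = 1e-9)
  expect_equal(f$radius, 2, tolerance = 1e-9)
  th <- seq(0, 2 * pi, length.out = 100)
  f2 <- fit_circle_2d(3 + 10 * cos(th), -1 + 10 * sin(th))
  expect_equal(f2$radius, 10, tolerance = 1e-9)
  set.seed(8)
  f3 <- fit_circle_2d(10 * cos(th) + rnorm(100, 0, 0.01),
                      10 * sin(th) + rnorm(100, 0, 0.01))
  expect_equal(f3$radius, 10, tolerance = 0.1)
  expect_error(fit_circle_2d(1:5, 2 * (1:5) + 1), "collinear")
})

test_that("fovea location finds the deepest ILM point and rejects flat surfaces", {
  cfg <- analytic_geometry(fovea_position = c(17, 15))
  truth <- generate_eye(cfg, seed = 2)
  fov <- locate_fovea(truth$surfaces)
  expect_equal(c(fov$bscan, fov$ascan), c(17, 15))
  flat <- surface_set(matrix(50, 32, 32), matrix(70, 32, 32),
                      matrix(90, 32, 32), depth_px = 160)
  expect_error(locate_fovea(flat), "no pit")
})

test_that("ROI mean thickness matches constant, symmetric and brute-force cases", {
  nb <- 41; na_ <- 41
  cal <- calibration(200, na_, nb, axial_extent_mm = 4,
                     transverse_extent_mm = 8, axial_length_mm = 24.455)
  aupp <- cal$axial_um_per_px
  fov <- c(21, 21)
  mk <- function(ct_px) surface_set(matrix(20, nb, na_), matrix(60, nb, na_),
                                    matrix(60, nb, na_) + ct_px, depth_px = 200)
  # constant 280 um choroid
  s1 <- mk(matrix(280 / aupp, nb, na_))
  for (d in c(1, 3)) {
    r <- roi_mean_thickness(s1, cal, fov, d, "choroid")
    expect_equal(r$mean_um, 280, tolerance = 1e-9)
    expect_gt(r$n, 0)
  }
  # linear ramp: odd terms cancel, ROI mean equals the foveal value
  ramp <- matrix(rep(seq_len(na_) - 21, each = nb), nb, na_) * 0.4 + 250 / aupp
  s2 <- mk(ramp)
  r2 <- roi_mean_thickness(s2, cal, fov, 3, "choroid")
  expect_equal(r2$mean_um, ramp[21, 21] * aupp, tolerance = 1e-9)
  # quadratic bowl vs an independent brute-force average
  xb <- (seq_len(nb) - 21) * cal$scaled_transverse_um_per_px["bscan"] / 1000
  xa <- (seq_len(na_) - 21) * cal$scaled_transverse_um_per_px["ascan"] / 1000
  bowl <- (200 + 15 * outer(xb^2, rep(1, na_)) + 10 * outer(rep(1, nb), xa^2)) / aupp
  s3 <- mk(bowl)
  r3 <- roi_mean_thickness(s3, cal, fov, 3, "choroid")
  acc <- n <- 0
  for (b in seq_len(nb)) for (a in seq_len(na_)) {
    if (sqrt(xb[b]^2 + xa[a]^2) < 1.5) { acc <- acc + bowl[b, a]; n <- n + 1 }
  }
  expect_equal(r3$mean_um, acc / n * aupp, tolerance = 1e-9)
  expect_equal(r3$n, n)
  s_bad <- s3
  s_bad$valid[] <- FALSE
  expect_error(roi_mean_thickness(s_bad, cal, fov, 3, "choroid"), "no valid")
})

test_that("a fixed-mm ROI holds more A-scans when the magnification ratio falls", {
  s <- surface_set(matrix(20, 41, 41), matrix(60, 41, 41),
                   matrix(80, 41, 41), depth_px = 200)
  n_short <- roi_mean_thickness(s, calibration(200, 41, 41, axial_length_mm = 23),
                                c(21, 21), 3, "choroid")$n
  n_long <- roi_mean_thickness(s, calibration(200, 41, 41, axial_length_mm = 27),
                               c(21, 21), 3, "choroid")$n
  expect_lt(bennett_scale(23), 1)
  expect_gt(n_short, n_long)
})

test_that("directional radii recover a 12 mm sphere cap in all four directions", {
  cfg <- analytic_geometry(posterior_radius_mm = 12, transverse_extent_mm = 10,
                           rpe_apex_mm = 3.6)
  truth <- generate_eye(cfg, seed = 1)
  cal <- calibration(cfg$depth_px, cfg$n_ascans, cfg$n_bscans,
                     transverse_extent_mm = 10,
                     axial_length_mm = cfg$axial_length_mm)
  fov <- list(bscan = truth$fovea[1], ascan = truth$fovea[2])
  for (ang in c(0, 45, 90, 135)) {
    r <- directional_radius(truth$surfaces, cal, fov, ang)
    expect_equal(r, 12, tolerance = 0.12)
  }
})

test_that("the inclusion window shields the fit from points beyond it", {
  cfg <- analytic_geometry(posterior_radius_mm = 12, transverse_extent_mm = 10,
                           rpe_apex_mm = 3.6)
  truth <- generate_eye(cfg, seed = 1)
  cal <- calibration(cfg$depth_px, cfg$n_ascans, cfg$n_bscans,
                     transverse_extent_mm = 10,
                     axial_length_mm = cfg$axial_length_mm)
  fov <- list(bscan = truth$fovea[1], ascan = truth$fovea[2])
  r_clean <- directional_radius(truth$surfaces, cal, fov, 90)
  # corrupt the surface beyond the 5 mm window of the 90-degree direction
  s2 <- truth$surfaces
  far <- abs((seq_len(cfg$n_bscans) - truth$fovea[1]) *
               cal$scaled_transverse_um_per_px["bscan"] / 1000) >= 5.3
  s2$midrpe_px[far, truth$fovea[2]] <- s2$midrpe_px[far, truth$fovea[2]] - 30
  s2$ilm_px[far, ] <- pmin(s2$ilm_px[far, ], s2$midrpe_px[far, ])
  r_out <- directional_radius(s2, cal, fov, 90)
  expect_equal(r_out, r_clean, tolerance = 1e-9)
})

test_that("oblique radii match an independent least-squares oracle on an ellipsoidal cap", {
  # ellipsoidal cap: different curvature radii along the two axes
  nb <- 64; na_ <- 64
  cal <- calibration(256, na_, nb, axial_length_mm = 24.455)
  db <- cal$scaled_transverse_um_per_px["bscan"] / 1000
  da <- cal$scaled_transverse_um_per_px["ascan"] / 1000
  fov <- list(bscan = 33, ascan = 33)
  xb <- (seq_len(nb) - 33) * db
  xa <- (seq_len(na_) - 33) * da
  Ra <- 14; Rb <- 20
  z_mm <- 3 - (outer(rep(1, nb), xa^2) / (2 * Ra) + outer(xb^2, rep(1, na_)) / (2 * Rb))
  rpe <- z_mm / (cal$axial_um_per_px / 1000)
  s <- surface_set(rpe - 20, rpe, rpe + 16, depth_px = 256)
  geom_fit <- function(x, y) {
    # brute-force geometric least squares, converged
    k <- fit_circle_2d(x, y)
    par <- c(k$center, k$radius)
    obj <- function(p) sum((sqrt((x - p[1])^2 + (y - p[2])^2) - p[3])^2)
    optim(par, obj, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14))$par[3]
  }
  for (ang in c(0, 45, 90, 135)) {
    r <- directional_radius(s, cal, fov, ang)
    # independent sampling of the same line with the same windows
    th <- ang * pi / 180
    tseq <- seq(-96, 96)
    ai <- 33 + tseq * cos(th); bi <- 33 + tseq * sin(th)
    keep <- ai >= 1 & ai <= na_ & bi >= 1 & bi <= nb
    step <- sqrt((cos(th) * da)^2 + (sin(th) * db)^2)
    smm <- tseq[keep] * step
    win <- if (ang == 0) smm > -5 & smm < 3
           else if (ang == 90) abs(smm) < 5 else abs(smm) < 6
    zi <- choromet:::bilinear_interp(rpe, bi[keep][win], ai[keep][win]) *
      cal$axial_um_per_px / 1000
    expect_equal(r, geom_fit(smm[win], zi), tolerance = 1e-4)
  }
})

test_that("collinear mid-RPE samples report an infinite radius", {
  s <- surface_set(matrix(20, 32, 32), matrix(60, 32, 32),
                   matrix(80, 32, 32), depth_px = 160)
  s$ilm_px[16, 16] <- 18   # give locate a pit-free surface; pass fovea directly
  cal <- calibration(160, 32, 32, axial_length_mm = 24.455)
  expect_warning(r <- directional_radius(s, cal, c(16, 16), 90), "collinear")
  expect_true(is.infinite(r))
})

test_that("measure_volume assembles all eight endpoints with positive values", {
  truth <- generate_eye(mid_geometry(), seed = 15)
  cal <- calibration(160, 32, 32, axial_length_mm = 25.563)
  m <- measure_volume(truth$surfaces, cal)
  expect_s3_class(m, "morphometry_result")
  expect_true(all(unlist(m[c("rt_1mm_um", "rt_3mm_um", "ct_1mm_um",
                             "ct_3mm_um")]) > 0))
  expect_true(all(unlist(m[c("r0_mm", "r45_mm", "r90_mm", "r135_mm")]) > 0))
  expect_true(m$n_1mm > 0 && m$n_3mm > m$n_1mm)
})
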