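test_that("diffusion identities: constant image and zero iterations", {
  img <- matrix(0.5, 40, 30)
  expect_equal(anisotropic_diffusion(img, n_iter = 10), img)
  rnd <- matrix(runif(1200), 40, 30)
  expect_equal(anisotropic_diffusion(rnd, n_iter = 0), rnd)
})

test_that("one explicit step on an isolated bright line halves its peak", {
  # kappa large makes the conduction ~1; lambda 0.25, one iteration:
  # centre update = 0.25 * (dW + dE) = 0.25 * (-1 - 1) = -0.5
  img <- matrix(0, 11, 11)
  img[, 6] <- 1
  out <- anisotropic_diffusion(img, n_iter = 1, kappa = 1e6, lambda = 0.25)
  expect_equal(out[6, 6], 0.5, tolerance = 1e-9)
})

test_that("diffusion obeys the maximum principle and conserves the mean", {
  set.seed(31)
  for (k in 1:5) {
    img <- matrix(runif(60 * 40), 60, 40)
    out <- anisotropic_diffusion(img, n_iter = 15, kappa = 0.1, lambda = 0.25)
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
    expect_equal(mean(out), mean(img), tolerance = 1e-6)
  }
  expect_error(anisotropic_diffusion(img, lambda = 0.3), "lambda")
})

test_that("compensation matches its closed forms", {
  # brute-force oracle for a single column
  comp1 <- function(col, n) {
    En <- col^n
    sapply(seq_along(col), function(z) {
      s <- sum(En[z:length(col)])
      if (s == 0) 0 else En[z] / (2 * s)
    })
  }
  expect_equal(as.vector(adaptive_compensation(cbind(c(1, 1)), 1, FALSE)),
               c(0.25, 0.5))
  expect_equal(as.vector(adaptive_compensation(cbind(c(0.5, 0.25, 0.25)), 1, FALSE)),
               c(0.25, 0.25, 0.5))
  set.seed(5)
  col <- runif(30)
  for (n in c(1, 2, 3)) {
    expect_equal(as.vector(adaptive_compensation(cbind(col), n, FALSE)),
                 comp1(col, n), tolerance = 1e-12)
  }
  # deepest non-zero sample always maps to 0.5 (before the root)
  m <- matrix(runif(200), 50, 4)
  out <- adaptive_compensation(m, 2, FALSE)
  expect_equal(unname(out[50, ]), rep(0.5, 4), tolerance = 1e-12)
  # all-zero columns map to zero
  m[, 2] <- 0
  out2 <- adaptive_compensation(m, 2, FALSE)
  expect_true(all(out2[, 2] == 0))
  expect_error(adaptive_compensation(m - 2, 2), "non-negative")
})

test_that("compensation brightens the deep choroid of an attenuated scan", {
  fx <- default_enhanced()
  b <- fx$truth$fovea[1]
  img <- anisotropic_diffusion(fx$vol$data[, , b])
  out <- adaptive_compensation(img)
  csi <- fx$truth$surfaces$csi_px[b, ]
  rpe <- fx$truth$surfaces$midrpe_px[b, ]
  sel <- cbind(round((csi + rpe) / 2), seq_along(csi))  # mid-choroid band
  expect_gt(mean(out[sel]), mean(img[sel]))
})
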