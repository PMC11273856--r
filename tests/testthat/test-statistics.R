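test_that("identical paired vectors give the degenerate result", {
  x <- rnorm(20)
  pc <- paired_compare(x, x)
  expect_true(pc$degenerate)
  expect_equal(pc$p_value, 1)
  expect_equal(pc$test_used, "none")
})

test_that("the Shapiro gate selects t for normal and wilcoxon for heavy-tailed differences", {
  set.seed(42)
  x <- rnorm(33)
  pc_norm <- paired_compare(x, x + rnorm(33, 0.5, 1))
  # strongly non-normal differences: a few huge outliers
  d <- c(rnorm(30, 0, 0.1), 40, -35, 50)
  pc_heavy <- paired_compare(x, x + d)
  expect_equal(pc_norm$test_used, "t")
  expect_equal(pc_heavy$test_used, "wilcoxon")
  expect_true(pc_norm$shapiro_p >= 0.05)
  expect_true(pc_heavy$shapiro_p < 0.05)
  expect_error(paired_compare(1:2, 2:3), "3 complete pairs")
})

test_that("paired comparison is invariant to subject ordering", {
  set.seed(9)
  b <- rnorm(25); s <- b + rnorm(25, 0.4)
  o <- sample(25)
  p1 <- paired_compare(b, s)
  p2 <- paired_compare(b[o], s[o])
  expect_equal(p1$p_value, p2$p_value, tolerance = 1e-12)
  expect_equal(p1$statistic, p2$statistic, tolerance = 1e-12)
  expect_equal(p1$test_used, p2$test_used)
})

test_that("correlation gate picks pearson for linear gaussian data and spearman for monotone heavy-tailed data", {
  set.seed(4)
  x <- rnorm(30)
  c1 <- correlate(x, 2 * x + 1)
  expect_equal(c1$method, "pearson")
  expect_equal(unname(c1$r), 1, tolerance = 1e-12)
  xt <- c(rnorm(27), 8, 12, 20)           # heavy tail fails normality
  c2 <- correlate(xt, exp(xt))
  expect_equal(c2$method, "spearman")
  expect_equal(unname(c2$r), 1, tolerance = 1e-12)
  expect_error(correlate(rep(1, 10), rnorm(10)), "variance")
})

test_that("Bland-Altman limits follow the 1.96 SD identity", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba <- bland_altman(c(0, 0, 0), c(1, 2, 3))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(round(c(ba$loa_low, ba$loa_high), 2), c(0.04, 3.96))
  # reconstruction identity holds for arbitrary inputs
  set.seed(13)
  for (k in 1:5) {
    b2 <- bland_altman(rnorm(20), rnorm(20))
    expect_equal(b2$loa_low, b2$mean_diff - 1.96 * b2$sd_diff)
    expect_equal(b2$loa_high, b2$mean_diff + 1.96 * b2$sd_diff)
  }
  expect_error(bland_altman(1, 2), "2 pairs")
})

test_that("summary-input mode reproduces the published repeatability limits", {
  ref <- reference_repeatability_table()
  rt3 <- ref[ref$parameter == "rt_3mm_um", ]
  ba <- bland_altman_from_summary(rt3$mean_diff, rt3$sd_diff)
  expect_equal(round(ba$loa_low, 3), rt3$loa_low_published)   # -2.851
  expect_equal(round(ba$loa_high, 3), rt3$loa_high_published) #  2.061
})

test_that("a paired t from summary statistics matches the published choroidal significance", {
  res <- paired_t_from_summary(2.742, 7.098, 33)
  expect_equal(res$df, 32)
  expect_equal(round(res$p_value, 3), 0.034)
})
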