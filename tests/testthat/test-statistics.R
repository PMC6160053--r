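test_that("one full-size iteration reduces to the standard rank-sum test", {
  set.seed(2)
  x <- rnorm(80); y <- rnorm(80, 0.3)
  r <- subsampled_wilcoxon(x, y, n = 80, iterations = 1, seed = 1)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(r$mean_p, ref, tolerance = 1e-12)
})

test_that("subsampling is reproducible and permutation-invariant", {
  set.seed(4)
  x <- rnorm(500); y <- rnorm(500)
  a <- subsampled_wilcoxon(x, y, n = 100, iterations = 25, seed = 7)
  b <- subsampled_wilcoxon(sample(x), sample(y), n = 100, iterations = 25,
                           seed = 7)
  expect_identical(a$p_values, b$p_values)
  expect_equal(a$mean_p, mean(a$p_values))
  expect_length(a$p_values, 25)
  expect_true(all(a$p_values >= 0 & a$p_values <= 1))
})

test_that("small groups lower n with a warning; empty groups error", {
  expect_warning(
    r <- subsampled_wilcoxon(rnorm(50), rnorm(200), n = 300,
                             iterations = 5, seed = 1),
    "lowered"
  )
  expect_equal(r$n, 50)
  expect_error(subsampled_wilcoxon(numeric(0), rnorm(10)), "empty")
})

test_that("tidy and glance summarize a comparison", {
  r <- subsampled_wilcoxon(rnorm(100), rnorm(100), n = 50, iterations = 20,
                           seed = 3)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("mean_p", "median_p", "frac_below_05") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$iterations, 20)
  expect_equal(gl$mean_p, r$mean_p)
})

test_that("Shapiro-Wilk wrapper matches stats::shapiro.test", {
  x <- withr::with_seed(10, rnorm(500))
  out <- shapiro_wilk(x)
  ref <- shapiro.test(x)
  expect_equal(out$statistic, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
  expect_gt(out$p_value, 0.05)
  u <- withr::with_seed(11, runif(500))
  expect_lt(shapiro_wilk(u)$p_value, 0.001)
  big <- withr::with_seed(12, rnorm(6000))
  outb <- shapiro_wilk(big, seed = 2)
  expect_true(outb$subsampled)
  expect_equal(outb$n, 5000L)
  expect_error(shapiro_wilk(rep(1, 10)), "degenerate")
})

test_that("moment skewness and kurtosis use the plain moment formulas", {
  expect_equal(moment_skewness(c(-1, 0, 1)), 0)
  x <- withr::with_seed(13, rnorm(1e5))
  expect_gt(moment_kurtosis(x), 2.9)
  expect_lt(moment_kurtosis(x), 3.1)
  e <- withr::with_seed(14, rexp(1e5))
  expect_gt(moment_skewness(e), 1.9)
  expect_lt(moment_skewness(e), 2.1)
  # independent cross-check against e1071 type-1 moment estimators
  skip_if_not_installed("e1071")
  y <- withr::with_seed(15, rgamma(2000, 2))
  expect_equal(moment_skewness(y), e1071::skewness(y, type = 1),
               tolerance = 1e-12)
  expect_equal(moment_kurtosis(y), e1071::kurtosis(y, type = 1) + 3,
               tolerance = 1e-12)
})

test_that("chi-squared uniformity handles extremes and uniform draws", {
  equal <- rep(seq(5, 355, by = 10), each = 3)   # 3 per 10-degree sector
  out <- chi_square_uniformity(equal, 36)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$df, 35)
  concentrated <- rep(1, 360)                    # all in the first sector
  out2 <- chi_square_uniformity(concentrated, 36)
  expect_equal(out2$statistic, 360 * 35)         # closed-form value
  unif <- withr::with_seed(16, runif(1500, 0, 360))
  expect_gt(chi_square_uniformity(unif, 36)$p_value, 0.05)
  expect_error(chi_square_uniformity(runif(10, 0, 360), 36), "fewer bins")
  expect_error(chi_square_uniformity(c(10, 400), 4), "\\[0, 360\\)")
})

test_that("chi-squared statistic is invariant under bin-width rotations", {
  ang <- withr::with_seed(17, runif(800, 0, 360))
  s0 <- chi_square_uniformity(ang, 36)$statistic
  s1 <- chi_square_uniformity((ang + 20) %% 360, 36)$statistic
  expect_equal(s1, s0, tolerance = 1e-9)
})

test_that("rose bins are half-open and sum to N", {
  out <- rose_bins(c(0, 90, 180, 270), 4)
  expect_equal(out$count, rep(1L, 4))
  expect_equal(sum(rose_bins(numeric(0), 8)$count), 0)
  out2 <- rose_bins(360 - 1e-9, 36)
  expect_equal(out2$count[36], 1L)
  expect_equal(sum(out2$count), 1L)
  out3 <- rose_bins(c(10 - 1e-12, 10), 36)       # boundary goes right
  expect_equal(out3$count[1:2], c(1L, 1L))
})
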