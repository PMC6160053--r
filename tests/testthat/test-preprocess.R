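test_that("contrast enhancement leaves constant volumes unchanged", {
  v <- voxel_volume(array(77, c(6, 6, 6)))
  out <- denoise_contrast(v)
  expect_equal(out$data, v$data)
})

test_that("salt noise is suppressed to the neighborhood value", {
  dat <- array(0, c(7, 7, 7))
  dat[4, 4, 4] <- 255                      # isolated bright voxel
  v <- voxel_volume(dat)
  out <- denoise_contrast(v, size_px = 3, neighborhood = 26)
  # oracle: local median over the 3^3 neighborhood (center excluded) is 0
  nb <- dat[3:5, 3:5, 3:5]
  expect_equal(median(nb[-14]), 0)
  expect_equal(out$data[4, 4, 4], 0)
  # two-phase volume with material phase intact
  dat2 <- array(0, c(7, 7, 7))
  dat2[3:5, 3:5, ] <- 255                  # a thick beam survives
  dat2[1, 1, 1] <- 255                     # salt in the background
  out2 <- denoise_contrast(voxel_volume(dat2))
  expect_equal(out2$data[1, 1, 1], 0)
  expect_true(all(out2$data[3:5, 3:5, ] == 255))
})

test_that("enhancement is idempotent on two-valued volumes", {
  set.seed(3)
  dat <- array(sample(c(0, 255), 8^3, TRUE, prob = c(0.7, 0.3)), c(8, 8, 8))
  v1 <- denoise_contrast(voxel_volume(dat))
  v2 <- denoise_contrast(v1)
  expect_equal(v2$data, v1$data)
})

test_that("invalid de-noise parameters error", {
  v <- voxel_volume(array(1, c(3, 3, 3)))
  expect_error(denoise_contrast(v, size_px = 0), "positive")
  expect_error(denoise_contrast(v, neighborhood = 10), "6, 18, 26")
  expect_equal(denoise_contrast(v, bypass = TRUE)$data, v$data)
})

test_that("threshold band is inclusive at both ends", {
  v <- voxel_volume(array(100, c(3, 3, 3)))
  expect_true(all(threshold_band(v, 76, 172)$mask))
  v2 <- voxel_volume(array(200, c(3, 3, 3)))
  expect_false(any(threshold_band(v2, 76, 172)$mask))
  dat <- array(c(50, 76, 172, 200), c(4, 1, 1))
  m <- threshold_band(voxel_volume(dat), 76, 172)$mask
  expect_equal(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(threshold_band(v, 172, 76), "exceed")
})

test_that("small-component removal follows size and connectivity rules", {
  mask <- array(FALSE, c(30, 15, 15))
  mask[1:12, 1:10, 1:10] <- TRUE           # 1200-voxel blob
  mask[20:27, 1:10, 1:10] <- TRUE          # 800-voxel blob
  bin <- binary_volume(mask, 3)
  out <- remove_small_components(bin, min_size_vox = 1000)
  expect_equal(sum(out$mask), 1200)
  expect_true(all(which(out$mask) %in% which(mask)))
  # boundary inclusive: a component of exactly min_size survives
  out2 <- remove_small_components(bin, min_size_vox = 800)
  expect_equal(sum(out2$mask), 2000)
})

test_that("diagonal chains split under 6- but not 26-connectivity", {
  mask <- array(FALSE, c(5, 5, 5))
  mask[cbind(2:4, 2:4, 2:4)] <- TRUE       # 3-voxel diagonal chain
  bin <- binary_volume(mask, 3)
  # flood-fill oracle agrees with the compiled labeling
  expect_equal(max(oracle_label(mask, 26)), 1)
  expect_equal(max(oracle_label(mask, 6)), 3)
  expect_equal(sum(remove_small_components(bin, 2, 26)$mask), 3)
  expect_equal(sum(remove_small_components(bin, 2, 6)$mask), 0)
})

test_that("removal is idempotent and never increases foreground", {
  set.seed(11)
  mask <- array(runif(10^3) < 0.2, c(10, 10, 10))
  bin <- binary_volume(mask, 3)
  once <- remove_small_components(bin, 5)
  twice <- remove_small_components(once, 5)
  expect_equal(twice$mask, once$mask)
  expect_lte(sum(once$mask), sum(mask))
})

test_that("threshold + removal commutes with interior cropping", {
  set.seed(12)
  dat <- array(0, c(20, 20, 20))
  dat[5:9, 5:9, 5:9] <- 100                # blob well inside the crop
  dat[14:15, 14:15, 14:15] <- 100          # small blob, also interior
  v <- voxel_volume(dat, voxel_size = 1)
  chain <- function(vol) {
    remove_small_components(threshold_band(vol, 76, 172), 20)
  }
  whole <- chain(v)
  cropped <- chain(extract_subvolume(v, c(2, 2, 2), 16))
  inner <- whole$mask[3:18, 3:18, 3:18]
  expect_equal(cropped$mask, inner)
})

test_that("full preprocessing chain errors on degenerate output", {
  v <- voxel_volume(array(0, c(6, 6, 6)))
  expect_error(preprocess_volume(v, min_size_vox = 1), "degenerate")
})
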