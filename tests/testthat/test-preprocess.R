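# HU windowing, resizing, masking, VOI extraction, mean-fill and CLAHE.

test_that("windowing clamps and rescales HU to [0, 1]", {
  expect_equal(window_and_normalize(-400), 0)
  expect_equal(window_and_normalize(250), 1)
  expect_equal(window_and_normalize(0), 0.5)
  # monotone non-decreasing in HU
  hu <- sort(runif(200, -1200, 1200))
  out <- window_and_normalize(hu)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("resize preserves constancy and the mask alphabet", {
  const <- matrix(0.42, 512, 512)
  expect_equal(resize_image(const, 256), matrix(0.42, 256, 256),
               tolerance = 1e-12)
  set.seed(41)
  m <- disc_mask(64, c(30, 34), 12)
  rm_ <- resize_image(m, 32, mode = "mask")
  expect_true(all(rm_ %in% c(0, 1)))
  expect_error(resize_image(matrix(0, 4, 6), 8), "square")
  # smooth ramp survives an up/down round trip within a small bound
  ramp <- outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 64),
                function(a, b) (a + b) / 2)
  rt <- resize_image(resize_image(ramp, 128), 64)
  expect_lt(max(abs(rt - ramp)), 0.01)
})

test_that("liver masking zeroes exactly the background", {
  set.seed(42)
  img <- matrix(runif(100, 0.1, 1), 10, 10)
  expect_equal(apply_liver_mask(img, matrix(1, 10, 10)), img)
  expect_equal(apply_liver_mask(img, matrix(0, 10, 10)), matrix(0, 10, 10))
  chk <- matrix(rep(c(0, 1), 50), 10, 10)
  out <- apply_liver_mask(img, chk)
  expect_equal(out != 0, chk == 1)
  expect_error(apply_liver_mask(img, matrix(1, 9, 10)), "extent")
})

test_that("VOI scan returns half-open 0-based bounds", {
  v <- array(0, c(10, 30, 25))
  v[4:8, 11:21, 6:16] <- 1
  voi <- find_voi(v)
  expect_equal(voi$lo, c(3L, 10L, 5L))
  expect_equal(voi$hi, c(8L, 21L, 16L))
  full <- find_voi(array(1, c(4, 5, 6)))
  expect_equal(full$lo, c(0L, 0L, 0L))
  expect_equal(full$hi, c(4L, 5L, 6L))
  expect_error(find_voi(array(0, c(3, 3, 3))), "nonzero")
})

test_that("zero padding does not change VOI content coordinates", {
  set.seed(43)
  v <- array(0, c(6, 12, 12))
  v[2:4, 3:9, 4:8] <- 1
  voi <- find_voi(v)
  pad <- array(0, c(10, 20, 20))
  pad[3 + (1:6) - 1, 5 + (1:12) - 1, 2 + (1:12) - 1] <- v
  voi_p <- find_voi(pad)
  expect_equal(voi_p$lo - c(2L, 4L, 1L), voi$lo)
  expect_equal(voi_p$hi - c(2L, 4L, 1L), voi$hi)
})

test_that("VOI crop drops out-of-range slices and resizes in-plane", {
  v <- array(0.5, c(64, 32, 32))
  full <- find_voi(array(1, dim(v)))
  id <- crop_voi_and_resize(v, full, 32)
  expect_length(id, 64)
  expect_equal(id[[10]], v[10, , ])
  sub <- list(lo = c(10L, 0L, 0L), hi = c(15L, 32L, 32L))
  expect_length(crop_voi_and_resize(v, sub, 16), 5)
  expect_equal(crop_voi_and_resize(v, sub, 16)[[1]],
               matrix(0.5, 16, 16), tolerance = 1e-12)
  bad <- list(lo = c(0L, 0L, 0L), hi = c(65L, 32L, 32L))
  expect_error(crop_voi_and_resize(v, bad, 16), "VOI")
})

test_that("background mean-fill replaces zeros with the nonzero mean", {
  img <- matrix(0, 4, 4)
  img[1, 1] <- 0.4; img[2, 2] <- 0.6
  out <- fill_background_with_mean(img)
  expect_equal(out[1, 1], 0.4)
  expect_equal(out[3, 3], 0.5)
  all_nz <- matrix(runif(16, 0.1, 1), 4, 4)
  expect_equal(fill_background_with_mean(all_nz), all_nz)
  zero <- matrix(0, 4, 4)
  expect_equal(fill_background_with_mean(zero), zero)
})

test_that("CLAHE is range-closed, fixes constants, and keeps level separation", {
  set.seed(44)
  const <- matrix(0.5, 64, 64)
  expect_equal(clahe_enhance(const), const)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- clahe_enhance(x)
  expect_true(all(out >= 0 & out <= 1))
  # strongly imbalanced two-level image: the level gap does not decrease
  two <- matrix(0.45, 64, 64)
  two[20:28, 20:28] <- 0.55
  en <- clahe_enhance(two)
  gap_before <- mean(two[20:28, 20:28]) - mean(two[1:10, 1:10])
  gap_after <- mean(en[20:28, 20:28]) - mean(en[1:10, 1:10])
  expect_gte(gap_after, gap_before)
  expect_error(clahe_enhance(matrix(0.5, 4, 4)), "grid")
  expect_error(clahe_enhance(matrix(2, 64, 64)), "\\[0, 1\\]")
})
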