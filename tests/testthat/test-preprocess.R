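# Intensity normalization, percentile saturation, resampling, half-image
# cropping and paired augmentation.

test_that("min-max normalization maps the range onto [0, 1] and is idempotent", {
  img <- matrix(c(0, 5, 10, 5), 2, 2, byrow = TRUE)
  expect_equal(normalize_minmax(img), matrix(c(0, 0.5, 1, 0.5), 2, 2, byrow = TRUE))
  u <- matrix(runif(64), 8, 8)
  expect_equal(normalize_minmax(normalize_minmax(u)), normalize_minmax(u))
  already <- (u - min(u)) / (max(u) - min(u))
  expect_equal(normalize_minmax(already), already)
  expect_warning(z <- normalize_minmax(matrix(7, 3, 3)), "constant")
  expect_true(all(z == 0))
})

test_that("percentile saturation clips to the empirical bounds, monotonically", {
  set.seed(1)
  x <- matrix(c(rep(10, 98), 0, 1000), 10, 10)
  q <- quantile(x, c(0.01, 0.99), names = FALSE, type = 1)
  y <- saturate_percentiles(x)
  expect_true(all(y >= q[1] - 1e-12 & y <= q[2] + 1e-12))
  expect_equal(max(y), q[2])
  expect_equal(min(y), q[1])
  # values strictly inside the bounds are untouched
  inside <- x > q[1] & x < q[2]
  expect_equal(y[inside], x[inside])
  # idempotent and monotone non-decreasing pixel-wise
  expect_equal(saturate_percentiles(y), y)
  a <- matrix(runif(100, 0, 50), 10, 10)
  b <- a + matrix(runif(100, 0, 5), 10, 10)
  expect_true(all(saturate_percentiles(b) >= saturate_percentiles(a) - 1e-9))
  expect_error(saturate_percentiles(a, 50, 40), "low_pct")
})

test_that("saturation before normalization increases CT ring contrast", {
  p <- phantom_params("ct", outlier_fraction = 0.01, noise_sd = 0, seed = 6)
  v <- generate_volume(p)
  img <- v$intensities[[5]]
  m <- v$region_masks[[5]] > 0
  ring <- orbitseg:::dilate3(v$region_masks[[5]], 2) > 0 & !m
  contrast <- function(x) mean(x[ring]) - mean(x[!ring & !m])
  plain <- normalize_minmax(img)
  sat <- normalize_minmax(saturate_percentiles(img))
  expect_gt(contrast(sat), contrast(plain))
})

test_that("isotropic resampling rescales shapes and keeps masks binary", {
  p <- tiny_ct_params(seed = 2, noise_sd = 0.01)
  v <- generate_volume(p)
  same <- resample_isotropic(v, 0.5)
  expect_identical(same$intensities, v$intensities)
  coarse <- v
  coarse$spacing_mm <- c(1, 1, 0.5)
  fine <- resample_isotropic(coarse, 0.5)
  expect_equal(dim(fine$intensities[[1]]), c(128L, 128L), tolerance = 0)
  expect_equal(fine$spacing_mm[1:2], c(0.5, 0.5))
  mvol <- list(slices = v$region_masks, spacing_mm = c(1, 1, 0.5))
  mfine <- resample_isotropic(mvol, 0.5, interp = "nearest")
  expect_true(all(unlist(mfine$slices) %in% c(0L, 1L)))
  bad <- v; bad$spacing_mm <- NULL
  expect_error(resample_isotropic(bad), "spacing")
})

test_that("half-image cropping follows the floor contract and inverts", {
  img <- matrix(seq_len(352 * 16), 16, 352)
  left <- crop_half(img, "left")
  expect_equal(ncol(left), 176)
  expect_equal(attr(left, "crop_offset"), 0L)
  right <- crop_half(img, "right")
  expect_equal(ncol(right), 176)
  expect_equal(attr(right, "crop_offset"), 176L)
  # offset bookkeeping recovers original coordinates
  expect_equal(right[3, 10], img[3, 10 + attr(right, "crop_offset")])
  odd <- matrix(1, 4, 7)
  expect_equal(ncol(crop_half(odd, "left")), 3)
})

test_that("augmentation applies one identical transform to image and mask", {
  cfg0 <- augment_config(flip_probability = 0, rotation_range_deg = 0)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- make_disk(c(64, 64), c(32.5, 32.5), 12)
  out <- augment_pair(img, msk, cfg0)
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)
  # rotation of a centered disk leaves the disk unchanged up to the rim
  cfg_rot <- augment_config(flip_probability = 0, rotation_range_deg = 10,
                            seed = 3)
  out <- augment_pair(img, msk, cfg_rot)
  expect_lt(sum(out$mask != msk) / sum(msk), 0.05)
  # mask pixel count preserved within 2% for centered convex masks
  cfgs <- augment_config(seed = 7)
  for (i in 1:20) {
    o <- augment_pair(img, msk, cfgs)
    expect_lt(abs(sum(o$mask) - sum(msk)) / sum(msk), 0.02)
  }
})

test_that("seeded draws give the advertised flip rate and angle range", {
  cfg <- augment_config(flip_probability = 0.5, rotation_range_deg = 10,
                        seed = 123)
  img <- matrix(1:16 + 0, 4, 4)
  msk <- matrix(0L, 4, 4); msk[2:3, 2:3] <- 1L
  n <- 10000
  flips <- logical(n); angles <- numeric(n)
  for (i in seq_len(n)) {
    o <- augment_pair(img, msk, cfg)
    flips[i] <- o$flipped; angles[i] <- o$angle_deg
  }
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(flips) - 0.5), 3 * se)
  expect_true(all(angles >= -10 & angles <= 10))
  # a private stream leaves the session RNG untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(augment_pair(img, msk, augment_config(seed = 5)))
  expect_equal(runif(1), before)
})
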