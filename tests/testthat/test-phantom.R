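# Synthetic phantom generator: determinism, geometry priors, ground-truth
# consistency, modality contrast.

test_that("generation is deterministic and the taper prior holds", {
  p <- phantom_params("ct", n_slices = 9, medial_radius = 20, taper = 0.9,
                      seed = 42)
  v1 <- generate_volume(p)
  v2 <- generate_volume(p)
  expect_identical(v1$intensities, v2$intensities)
  expect_identical(v1$region_masks, v2$region_masks)

  # pixel counts strictly decrease away from the medial slice (index 5)
  areas <- vapply(v1$region_masks, sum, 0)
  expect_true(all(diff(areas[1:5]) > 0))
  expect_true(all(diff(areas[5:9]) < 0))
})

test_that("taper = 1 with no triangularity or jitter yields identical disks", {
  p <- phantom_params("ct", n_slices = 5, taper = 1, triangularity_gain = 0,
                      noise_sd = 0, center_jitter = 0, seed = 1)
  v <- generate_volume(p)
  areas <- vapply(v$region_masks, sum, 0)
  expect_true(all(areas == areas[1]))
  for (s in 2:5) expect_identical(v$region_masks[[s]], v$region_masks[[1]])
})

test_that("ground truth is self-consistent on every slice", {
  p <- phantom_params("mri", n_slices = 7, triangularity_gain = 0.8, seed = 9)
  v <- generate_volume(p)
  for (s in seq_along(v$region_masks)) {
    m <- v$region_masks[[s]]
    # every slice contains the orbit as a closed contour
    expect_gt(sum(m), 0)
    # center equals the mask centroid within 0.5 px
    expect_lt(max(abs(v$centers[s, ] - mask_centroid(m))), 0.5)
    # rasterizing the contour and filling reproduces the mask exactly
    cm <- matrix(0L, nrow(m), ncol(m))
    cm[v$contours[[s]]] <- 1L
    expect_identical(fill_holes(cm), m)
    # dice of the truth against itself is exactly 1
    expect_identical(as.numeric(dice(m, m)), 1)
  }
})

test_that("CT style has at least twice the MRI ring/background contrast", {
  michelson <- function(v) {
    s <- (length(v$intensities) + 1) %/% 2
    img <- v$intensities[[s]]
    m <- v$region_masks[[s]]
    ring <- orbitseg:::dilate3(m, 2) & !orbitseg:::dilate3(m, 0)
    ring_i <- mean(img[ring > 0])
    bg <- img[!orbitseg:::dilate3(m, 6)]
    bg_i <- mean(bg)
    abs(ring_i - bg_i) / (ring_i + bg_i)
  }
  pct <- phantom_params("ct", noise_sd = 0, outlier_fraction = 0, seed = 2)
  pmr <- phantom_params("mri", noise_sd = 0, seed = 2)
  ct <- generate_volume(pct); mr <- generate_volume(pmr)
  expect_gte(michelson(ct), 2 * michelson(mr))
})

test_that("outlier pixels occur only on the CT path and truth is noise free", {
  p <- phantom_params("ct", outlier_fraction = 0.005, noise_sd = 0, seed = 3)
  v <- generate_volume(p)
  img <- v$intensities[[3]]
  expect_gt(sum(img > 1 | img < 0), 0)             # extremes present
  expect_true(all(v$region_masks[[3]] %in% c(0L, 1L)))
  expect_error(phantom_params("mri", outlier_fraction = 0.01), "CT")
  # noise-free CT: thresholding at the bone/background midpoint recovers a
  # bright ring hugging the contour
  p0 <- phantom_params("ct", noise_sd = 0, outlier_fraction = 0, seed = 4)
  v0 <- generate_volume(p0)
  thr <- (p0$bone_intensity + p0$background_intensity) / 2
  ring <- v0$intensities[[5]] > thr
  expect_gt(sum(ring), 0)
  near_ring <- orbitseg:::dilate3(matrix(as.integer(ring), 128, 128), 1)
  expect_true(all(near_ring[v0$contours[[5]]] > 0))
})

test_that("parameter validation rejects misconfiguration", {
  expect_error(phantom_params("ct", n_slices = 2), "n_slices")
  expect_error(phantom_params("ct", medial_radius = -3), "radius")
  expect_error(phantom_params("ct", taper = 0), "taper")
  expect_error(phantom_params("ct", slice_shape = c(32L, 32L),
                              medial_radius = 20), "too small")
})

test_that("cohorts are seeded, mutually distinct and reproducible", {
  p <- phantom_params("ct", seed = 1)
  d1 <- generate_dataset(6, p, seed = 5)
  d2 <- generate_dataset(6, p, seed = 5)
  expect_equal(length(d1), 6)
  for (i in 1:6) expect_identical(d1[[i]]$intensities, d2[[i]]$intensities)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_false(identical(d1[[i]]$intensities, d1[[j]]$intensities))
  }
  # a single subject reproduces generate_volume under its derived parameters
  one <- generate_dataset(1, p, seed = 5)
  again <- generate_volume(one[[1]]$params)
  expect_identical(one[[1]]$intensities, again$intensities)
})

test_that("phantom volumes survive a disk round trip in plain formats", {
  p <- tiny_ct_params(seed = 8, noise_sd = 0.01)
  v <- generate_volume(p)
  dir <- withr::local_tempdir()
  write_phantom(v, dir)
  expect_true(file.exists(file.path(dir, "params.yaml")))
  back <- read_phantom(dir)
  expect_identical(back$region_masks, v$region_masks)
  expect_equal(back$contours, lapply(v$contours, function(k) {
    colnames(k) <- c("row", "col"); k
  }), ignore_attr = TRUE)
  # intensities quantized to 16 bits
  expect_lt(max(abs(back$intensities[[1]] - pmin(pmax(v$intensities[[1]], 0), 1))),
            1 / 65535 + 1e-9)
})
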