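# Dice (per slice and pooled), centroid error, boundary MAE, Hausdorff.

test_that("dice handles identity, disjunction, toy counts and empties", {
  a <- matrix(c(1, 1, 0, 0, 0, 0), 2, 3)
  expect_equal(as.numeric(dice(a, a)), 1)
  b <- matrix(c(0, 0, 1, 1, 0, 0), 2, 3)
  expect_equal(as.numeric(dice(a, b)), 0)
  # TP = 2, FP = 1, FN = 1 on a 6-pixel grid
  pred <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  truth <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3)
  expect_equal(as.numeric(dice(pred, truth)), 4 / 6)
  # symmetric, translation invariant
  expect_equal(dice(pred, truth), dice(truth, pred))
  shift <- function(m) cbind(0L, m[, -3])
  expect_equal(dice(shift(pred), shift(truth)), dice(pred, truth))
  # both empty: defined as 1 with a flag
  e <- dice(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(as.numeric(e), 1)
  expect_true(attr(e, "empty"))
  expect_equal(as.numeric(dice(matrix(0, 2, 2), matrix(1, 2, 2))), 0)
})

test_that("volumetric dice pools counts and differs from the slice mean", {
  # slice A: TP 10, FP 0, FN 0; slice B: TP 2, FP 2, FN 2
  mk <- function(tp, fp, fn, dims = c(4, 5)) {
    pred <- matrix(0L, dims[1], dims[2]); truth <- pred
    pred[seq_len(tp + fp)] <- 1L
    truth[c(seq_len(tp), tp + fp + seq_len(fn))] <- 1L
    list(pred = pred, truth = truth)
  }
  A <- mk(10, 0, 0); B <- mk(2, 2, 2)
  pooled <- volumetric_dice(list(A$pred, B$pred), list(A$truth, B$truth))
  expect_equal(as.numeric(pooled), 24 / 28)
  slice_mean <- mean(c(as.numeric(dice(A$pred, A$truth)),
                       as.numeric(dice(B$pred, B$truth))))
  expect_equal(slice_mean, 0.75)
  expect_false(isTRUE(all.equal(as.numeric(pooled), slice_mean)))
  # perfect volume and single-slice reduction
  expect_equal(as.numeric(volumetric_dice(list(A$truth), list(A$truth))), 1)
  expect_equal(as.numeric(volumetric_dice(list(B$pred), list(B$truth))),
               as.numeric(dice(B$pred, B$truth)))
})

test_that("centroid error is the Euclidean distance", {
  expect_equal(centroid_error(c(3, 4), c(3, 4)), 0)
  expect_equal(centroid_error(c(0, 0), c(3, 4)), 5)
})

test_that("boundary MAE matches analytic offsets", {
  c1 <- circle_points(c(50, 50), 20)
  expect_equal(boundary_mae(c1, c1), 0)
  c2 <- circle_points(c(50, 50), 22)
  expect_equal(boundary_mae(c1, c2), 2, tolerance = 0.01)
  shifted <- sweep(c1, 2, c(1, 0), "+")
  expect_lte(boundary_mae(shifted, c1), 1 + 1e-9)
  expect_error(boundary_mae(c1[1:2, ], c1), "3 points")
})

test_that("hausdorff equals the brute-force double loop", {
  expect_equal(hausdorff_distance(cbind(0, 0), cbind(3, 4)), 5)
  A <- circle_points(c(10, 10), 5, n = 30)
  expect_equal(hausdorff_distance(A, A), 0)
  set.seed(12)
  for (rep in 1:5) {
    A <- cbind(runif(20, 0, 50), runif(20, 0, 50))
    B <- cbind(runif(20, 0, 50), runif(20, 0, 50))
    brute <- function(A, B) {
      h <- -Inf
      for (i in seq_len(nrow(A))) {
        best <- Inf
        for (j in seq_len(nrow(B))) {
          best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
        }
        h <- max(h, best)
      }
      h
    }
    expect_equal(hausdorff_distance(A, B), max(brute(A, B), brute(B, A)),
                 tolerance = 1e-12)
    # directed mean error never exceeds the Hausdorff bound
    expect_lte(boundary_mae(B, A), hausdorff_distance(A, B) + 1e-12)
  }
})

test_that("volume evaluation aggregates, converts units, matches brute force", {
  set.seed(30)
  n <- 5
  truth_masks <- list(); pred_masks <- list()
  truth_ct <- list(); pred_ct <- list()
  truth_cn <- list(); pred_cn <- list()
  for (i in 1:n) {
    r <- 8 + i
    truth_masks[[i]] <- make_disk(c(64, 64), c(32, 32), r)
    pred_masks[[i]] <- make_disk(c(64, 64), c(32 + 1, 32), r)
    truth_ct[[i]] <- circle_points(c(32, 32), r, 90)
    pred_ct[[i]] <- circle_points(c(33, 32), r, 90)
    truth_cn[[i]] <- c(32, 32); pred_cn[[i]] <- c(33, 32)
  }
  ev <- evaluate_volume(list(masks = pred_masks, contours = pred_ct,
                             centers = pred_cn),
                        list(masks = truth_masks, contours = truth_ct,
                             centers = truth_cn),
                        spacing_mm = 0.5)
  expect_equal(ev$centroid_error_px[["mean"]], 1)
  expect_equal(ev$boundary_mae_mm[["mean"]], 0.5 * ev$boundary_mae_px[["mean"]])
  expect_equal(ev$hausdorff_mm[["mean"]], 0.5 * ev$hausdorff_px[["mean"]])
  # sd fields match an independent recomputation
  manual <- sapply(1:n, function(i) as.numeric(dice(pred_masks[[i]], truth_masks[[i]])))
  expect_equal(ev$dice_orbit_per_slice[["mean"]], mean(manual))
  expect_equal(ev$dice_orbit_per_slice[["sd"]], sd(manual))
  # perfect prediction: all dice 1, all distances 0
  pe <- evaluate_volume(list(masks = truth_masks, contours = truth_ct,
                             centers = truth_cn),
                        list(masks = truth_masks, contours = truth_ct,
                             centers = truth_cn))
  expect_equal(pe$dice_orbit_volumetric, 1)
  expect_equal(pe$dice_background_volumetric, 1)
  expect_equal(pe$hausdorff_px[["mean"]], 0)
  expect_equal(pe$centroid_error_px[["mean"]], 0)
})
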