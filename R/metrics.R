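# Evaluation metrics: two-class Dice (per slice and pooled per volume),
# centroid Euclidean error, boundary mean absolute error, and Hausdorff
# distance. Distances are reported in pixels; millimetre values are pixels
# times the in-plane spacing (0.5 mm at the working resolution).

dice_counts <- function(pred, truth) {
  p <- pred > 0; t <- truth > 0
  c(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

dice_from_counts <- function(cnt) {
  denom <- 2 * cnt[["tp"]] + cnt[["fp"]] + cnt[["fn"]]
  if (denom == 0) return(structure(1, empty = TRUE))  # both masks empty
  2 * cnt[["tp"]] / denom
}

#' Dice coefficient between two binary masks
#'
#' `2 TP / (2 TP + FP + FN)` counted per pixel. The background-class Dice is
#' obtained by passing inverted masks (or via [evaluate_volume()], which
#' reports both classes). When both masks are empty the Dice is defined as 1
#' and the result carries attribute `empty = TRUE`; an empty mask against a
#' non-empty one scores 0.
#'
#' @param pred,truth congruent binary matrices.
#' @param roi optional ROI spec (from [extract_roi()]); when given, both
#'   masks are cropped to that window before counting, matching evaluation
#'   over the 128x128 region extracted around the orbit.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(pred, truth, roi = NULL) {
  stopifnot(all(dim(pred) == dim(truth)))
  if (!is.null(roi)) {
    rows <- (roi$offset[1] + 1):(roi$offset[1] + roi$size)
    cols <- (roi$offset[2] + 1):(roi$offset[2] + roi$size)
    pred <- pred[rows, cols, drop = FALSE]
    truth <- truth[rows, cols, drop = FALSE]
  }
  dice_from_counts(dice_counts(pred, truth))
}

#' Volumetric Dice over a stack of slices
#'
#' Pools the per-pixel confusion counts across all evaluated slices before
#' applying the Dice formula. This is not the mean of per-slice Dice values:
#' slices with small cross-sections contribute proportionally to their pixel
#' counts rather than equally.
#'
#' @param pred_masks,truth_masks lists of congruent binary matrices (end
#'   slices already omitted by the caller).
#' @param rois optional list of ROI specs, one per slice.
#' @return pooled Dice coefficient.
#' @export
volumetric_dice <- function(pred_masks, truth_masks, rois = NULL) {
  stopifnot(length(pred_masks) == length(truth_masks))
  total <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(pred_masks)) {
    p <- pred_masks[[i]]; t <- truth_masks[[i]]
    if (!is.null(rois)) {
      roi <- rois[[i]]
      rows <- (roi$offset[1] + 1):(roi$offset[1] + roi$size)
      cols <- (roi$offset[2] + 1):(roi$offset[2] + roi$size)
      p <- p[rows, cols, drop = FALSE]; t <- t[rows, cols, drop = FALSE]
    }
    total <- total + dice_counts(p, t)
  }
  dice_from_counts(total)
}

#' Euclidean distance between true and proposed centroids
#'
#' @param pred_center,true_center numeric `(row, col)` in pixels.
#' @return distance in pixels.
#' @export
centroid_error <- function(pred_center, true_center) {
  sqrt(sum((as.numeric(pred_center) - as.numeric(true_center))^2))
}

# pairwise Euclidean distances between two (row, col) point sets
cross_dist <- function(A, B) {
  sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
}

#' Mean absolute boundary error between two contours
#'
#' Mean over the truth contour points of the distance to the nearest
#' predicted point. The default is directed (truth to prediction), which is
#' stable when the two contours are sampled at different densities;
#' `symmetric = TRUE` averages both directions.
#'
#' @param pred,truth n x 2 matrices of (row, col) contour points (>= 3
#'   points each).
#' @param symmetric average the two directed errors.
#' @return mean absolute error in pixels.
#' @export
boundary_mae <- function(pred, truth, symmetric = FALSE) {
  if (nrow(pred) < 3 || nrow(truth) < 3) {
    stop("contours must have at least 3 points")
  }
  D <- cross_dist(truth, pred)
  e_t2p <- mean(apply(D, 1, min))
  if (!symmetric) return(e_t2p)
  (e_t2p + mean(apply(D, 2, min))) / 2
}

#' Hausdorff distance between two point sets
#'
#' Symmetric Hausdorff distance: the greatest of all distances from a point
#' in one set to the closest point in the other set, taken in both
#' directions.
#'
#' @param A,B non-empty n x 2 matrices of (row, col) points.
#' @return distance in pixels.
#' @export
hausdorff_distance <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) stop("point sets must be non-empty")
  D <- cross_dist(A, B)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

#' Evaluate a segmented volume against ground truth
#'
#' Aggregates all metrics over the evaluated slices of one volume: orbit and
#' background Dice per slice (mean +/- sd) and pooled volumetrically,
#' centroid error, boundary MAE and Hausdorff distance (each mean +/- sd, in
#' pixels and millimetres).
#'
#' @param pred list with `masks`, `contours`, `centers` (per evaluated
#'   slice).
#' @param truth list of the same shape, aligned slice by slice.
#' @param spacing_mm in-plane pixel spacing (0.5 mm at the working
#'   resolution).
#' @param rois optional list of ROI specs; Dice is then computed within the
#'   128x128 evaluation window.
#' @return object of class `orbit_eval` (a list of summary statistics plus
#'   a per-slice data frame).
#' @export
evaluate_volume <- function(pred, truth, spacing_mm = 0.5, rois = NULL) {
  n <- length(pred$masks)
  stopifnot(n == length(truth$masks), n >= 1)
  per <- data.frame(slice = seq_len(n), dice_orbit = NA_real_,
                    dice_background = NA_real_, centroid_error_px = NA_real_,
                    boundary_mae_px = NA_real_, hausdorff_px = NA_real_,
                    failed = FALSE)
  for (i in seq_len(n)) {
    roi <- if (is.null(rois)) NULL else rois[[i]]
    per$dice_orbit[i] <- dice(pred$masks[[i]], truth$masks[[i]], roi = roi)
    per$dice_background[i] <- dice(1 - (pred$masks[[i]] > 0),
                                   1 - (truth$masks[[i]] > 0), roi = roi)
    # a slice whose predicted segmentation is empty has no contour or
    # center; its overlap scores count, its distances are undefined
    if (nrow(pred$contours[[i]]) < 3 || anyNA(pred$centers[[i]])) {
      per$failed[i] <- TRUE
      next
    }
    per$centroid_error_px[i] <- centroid_error(pred$centers[[i]],
                                               truth$centers[[i]])
    per$boundary_mae_px[i] <- boundary_mae(pred$contours[[i]],
                                           truth$contours[[i]])
    per$hausdorff_px[i] <- hausdorff_distance(pred$contours[[i]],
                                              truth$contours[[i]])
  }
  vol_orbit <- volumetric_dice(pred$masks, truth$masks, rois = rois)
  inv <- function(ms) lapply(ms, function(m) 1 - (m > 0))
  vol_bg <- volumetric_dice(inv(pred$masks), inv(truth$masks), rois = rois)
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else 0)
  }
  out <- list(
    n_slices = n,
    n_failed_slices = sum(per$failed),
    dice_orbit_volumetric = as.numeric(vol_orbit),
    dice_background_volumetric = as.numeric(vol_bg),
    dice_orbit_per_slice = msd(per$dice_orbit),
    dice_background_per_slice = msd(per$dice_background),
    centroid_error_px = msd(per$centroid_error_px),
    boundary_mae_px = msd(per$boundary_mae_px),
    boundary_mae_mm = msd(per$boundary_mae_px * spacing_mm),
    hausdorff_px = msd(per$hausdorff_px),
    hausdorff_mm = msd(per$hausdorff_px * spacing_mm),
    spacing_mm = spacing_mm,
    per_slice = per
  )
  class(out) <- "orbit_eval"
  out
}

#' @export
print.orbit_eval <- function(x, ...) {
  f <- function(v) sprintf("%.3f ± %.3f", v["mean"], v["sd"])
  cat(sprintf("<orbit_eval> %d evaluated slices (%.2g mm/px)\n",
              x$n_slices, x$spacing_mm))
  cat(sprintf("  volumetric Dice: orbit %.3f, background %.3f\n",
              x$dice_orbit_volumetric, x$dice_background_volumetric))
  cat(sprintf("  per-slice Dice:  orbit %s, background %s\n",
              f(x$dice_orbit_per_slice), f(x$dice_background_per_slice)))
  cat(sprintf("  centroid error:  %s px\n", f(x$centroid_error_px)))
  cat(sprintf("  boundary MAE:    %s px (%s mm)\n",
              f(x$boundary_mae_px), f(x$boundary_mae_mm)))
  cat(sprintf("  Hausdorff:       %s px (%s mm)\n",
              f(x$hausdorff_px), f(x$hausdorff_mm)))
  invisible(x)
}
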