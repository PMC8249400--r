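# Volume-level post-processing: adjacent-slice 2-of-3 voting with end-slice
# omission, and k-fold ensemble majority voting. Both operations are
# monotone: adding positive pixels to any input never removes positives
# from the output.

#' Average each slice mask with its neighbours
#'
#' Replaces every interior slice by the pixel-wise 2-of-3 majority of the
#' slice and its two neighbours (threshold-at-0.5 of their mean). Because
#' the orbit cross-section shrinks monotonically away from the medial slice,
#' this removes isolated over- or under-segmentations without distorting
#' consistent slices. The first and last slices, which lack a neighbour, are
#' omitted from subsequent analysis, so the output has `length(masks) - 2`
#' elements; attribute `slice_indices` records which input slices remain.
#'
#' @param masks list of >= 3 congruent binary matrices, in slice order.
#' @return list of `length(masks) - 2` voted masks.
#' @export
average_adjacent_slices <- function(masks) {
  n <- length(masks)
  if (n < 3) stop("adjacent-slice averaging needs at least 3 slices")
  out <- vector("list", n - 2L)
  for (i in seq.int(2L, n - 1L)) {
    mean3 <- ((masks[[i - 1]] > 0) + (masks[[i]] > 0) + (masks[[i + 1]] > 0)) / 3
    m <- matrix(as.integer(mean3 >= 0.5), nrow(masks[[i]]), ncol(masks[[i]]))
    out[[i - 1L]] <- m
  }
  attr(out, "slice_indices") <- seq.int(2L, n - 1L)
  out
}

#' Ensemble voting configuration
#'
#' @param k number of cross-validation fold models in the ensemble.
#' @param vote_rule minimum number of positive votes for a pixel to be
#'   positive; the default `ceiling((k + 1) / 2)` is a strict majority
#'   (4 of 6 for the standard k = 6).
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(k = 6L, vote_rule = ceiling((k + 1) / 2)) {
  if (vote_rule < 1 || vote_rule > k) stop("need 1 <= vote_rule <= k")
  structure(list(k = as.integer(k), vote_rule = as.integer(vote_rule)),
            class = "ensemble_config")
}

#' Majority vote across fold prediction maps
#'
#' Binarizes each of the k fold models' prediction maps at 0.5 and sets a
#' pixel positive where at least `vote_rule` maps agree. The voted map is
#' what the graph search segments in ensemble mode.
#'
#' @param maps list of k congruent probability or binary maps.
#' @param cfg an [ensemble_config()]; defaults to `k = length(maps)` with a
#'   strict majority rule.
#' @return binary matrix of votes.
#' @export
majority_vote <- function(maps, cfg = ensemble_config(k = length(maps))) {
  stopifnot(length(maps) >= 1)
  if (length(maps) != cfg$k) stop("number of maps must equal cfg$k")
  d <- dim(maps[[1]])
  for (m in maps) if (!all(dim(m) == d)) stop("prediction maps differ in shape")
  votes <- Reduce(`+`, lapply(maps, function(m) m >= 0.5))
  matrix(as.integer(votes >= cfg$vote_rule), d[1], d[2])
}
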