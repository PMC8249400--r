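# Stage 1 post-processing: turn the global network's region probability map
# into an orbit center and a fixed 128x128 region of interest. Connectivity
# convention throughout: 8-connected foreground, 4-connected background.

#' Fill holes in a binary mask
#'
#' Every background region not 4-connected to the image border is set to
#' foreground. Foreground never shrinks; the operation is idempotent.
#'
#' @param mask binary matrix.
#' @return integer matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- mask > 0
  bg <- matrix(as.integer(!m), nrow(m), ncol(m))
  lab <- EBImage::bwlabel(bg)           # 4-connected background labels
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- lab > 0 & !(lab %in% border)
  out <- matrix(as.integer(m | hole), nrow(m), ncol(m))
  out
}

# label 8-connected foreground components; returns an integer label matrix
label_components8 <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  fg <- which(m)
  if (length(fg) == 0) return(lab)
  id <- match(seq_len(nr * nc), fg)     # pixel index -> vertex id
  edges <- integer(0)
  add_edges <- function(di, dj) {
    r <- ((fg - 1L) %% nr) + 1L; c <- ((fg - 1L) %/% nr) + 1L
    r2 <- r + di; c2 <- c + dj
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- fg[ok]
    both <- !is.na(id[nb])
    rbind(id[src[both]], id[nb[both]])
  }
  el <- cbind(add_edges(1L, 0L), add_edges(0L, 1L),
              add_edges(1L, 1L), add_edges(-1L, 1L))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (ncol(el) > 0) g <- igraph::add_edges(g, as.vector(el))
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Keep only the largest connected component of a mask
#'
#' Components are 8-connected. On a tie in area, the component containing
#' the first foreground pixel in row-major scan order wins, making the
#' result deterministic. An empty input yields an empty output with
#' attribute `status = "empty"`.
#'
#' @param mask binary matrix.
#' @return integer matrix holding the single largest component.
#' @export
largest_component <- function(mask) {
  lab <- label_components8(mask)
  if (max(lab) == 0L) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "status") <- "empty"
    return(out)
  }
  sizes <- tabulate(lab[lab > 0])
  best_size <- max(sizes)
  # row-major scan order over pixels; first pixel of a maximal component wins
  idx <- which(t(lab) > 0, arr.ind = FALSE)
  labs_rowmajor <- t(lab)[idx]
  winner <- labs_rowmajor[sizes[labs_rowmajor] == best_size][1]
  out <- matrix(as.integer(lab == winner), nrow(mask), ncol(mask))
  out
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the foreground pixel coordinates.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @return numeric `(row, col)`.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cannot compute the centroid of an empty mask")
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Extract a fixed-size square region of interest around a center
#'
#' Crops `size` x `size` pixels centered on the rounded center, shifting
#' (clamping) the window so it lies fully inside the slice. The returned
#' specification records the 0-based top-left `offset`, so ROI coordinates
#' map back to slice coordinates as `slice = roi + offset`.
#'
#' @param slice_image numeric matrix, at least `size` pixels in each
#'   dimension.
#' @param center numeric `(row, col)` proposed orbit center.
#' @param size ROI side length in pixels (128, the working ROI of the local
#'   network).
#' @return list with `roi` (the crop) and `spec` (list with `center`,
#'   `size`, `offset`).
#' @export
extract_roi <- function(slice_image, center, size = 128L) {
  nr <- nrow(slice_image); nc <- ncol(slice_image)
  if (nr < size || nc < size) {
    stop(sprintf("slice (%d x %d) smaller than the %d px ROI; resample first",
                 nr, nc, size))
  }
  r0 <- clamp(round(center[1]) - size %/% 2L, 0L, nr - size)
  c0 <- clamp(round(center[2]) - size %/% 2L, 0L, nc - size)
  roi <- slice_image[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), drop = FALSE]
  list(roi = roi,
       spec = list(center = as.numeric(center), size = as.integer(size),
                   offset = c(row = as.integer(r0), col = as.integer(c0))))
}

#' Map ROI coordinates back to full-slice coordinates
#'
#' @param points n x 2 matrix of (row, col) ROI coordinates.
#' @param spec the `spec` element returned by [extract_roi()].
#' @return n x 2 matrix in slice coordinates.
#' @export
roi_to_slice <- function(points, spec) {
  pts <- cbind(points[, 1] + spec$offset[1], points[, 2] + spec$offset[2])
  colnames(pts) <- c("row", "col")
  pts
}

#' Localize the orbit center from a stage-1 region probability map
#'
#' Thresholds the map, fills holes, keeps the largest 8-connected component
#' and returns its centroid. If nothing survives thresholding the status is
#' `"not_found"` and the center is `NULL`; callers fall back to the nearest
#' previously localized slice.
#'
#' @param prob_map matrix of region probabilities in [0, 1].
#' @param threshold binarization threshold (0.5 = two-class argmax).
#' @return list with `center` (numeric `(row, col)` or `NULL`), `status`
#'   (`"ok"` or `"not_found"`), and `mask` (the post-processed component).
#' @export
localize_orbit <- function(prob_map, threshold = 0.5) {
  if (min(prob_map) < 0 || max(prob_map) > 1) {
    stop("probability map values must lie in [0, 1]")
  }
  bin <- matrix(as.integer(prob_map >= threshold), nrow(prob_map), ncol(prob_map))
  if (sum(bin) == 0) {
    return(list(center = NULL, status = "not_found",
                mask = matrix(0L, nrow(prob_map), ncol(prob_map))))
  }
  comp <- largest_component(fill_holes(bin))
  list(center = mask_centroid(comp), status = "ok", mask = comp)
}
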