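# Stage 3: closed-contour extraction from a boundary probability map.
# The ROI is unwrapped into polar coordinates about the proposed center so
# the ring-shaped boundary becomes a near-horizontal band, then the band is
# segmented as a single left-to-right minimum-weight path (Dijkstra with
# edge weights 2 - (P_a + P_b) and movements restricted to horizontal and
# vertical steps), and the path is mapped back to a closed Cartesian
# contour.
#
# Angle convention (single-sourced here): theta = 0 along the +column axis,
# increasing counter-clockwise in (row, col) space with row increasing
# downward, i.e. row = center_row - r sin(theta), col = center_col + r cos(theta).

polar_to_cartesian <- function(center, r, theta) {
  cbind(row = center[1] - r * sin(theta),
        col = center[2] + r * cos(theta))
}

#' Unwrap a probability map into polar coordinates about a center
#'
#' Resamples the map onto a (radius x angle) grid by bilinear interpolation;
#' samples falling outside the map read as 0. The radius axis covers
#' `(0, max_radius]` and the angle axis `[0, 2*pi)`, both uniformly.
#'
#' @param roi_map matrix of boundary probabilities in [0, 1].
#' @param center `(row, col)` unwrapping center, inside the map.
#' @param n_angles number of angular bins (360 keeps arc length <= ~1 px per
#'   bin at the largest radius used here).
#' @param max_radius largest sampled radius in pixels; defaults to the
#'   half-diagonal of the map so the grid covers its corners.
#' @param n_radii number of radius bins; defaults to `ceiling(max_radius)`
#'   (~1 px radial resolution).
#' @return object of class `polar_grid`: `values` (n_radii x n_angles),
#'   `center`, `radii`, `thetas`, `max_radius`, `pad_cols`, `pad_weight_prob`.
#' @export
to_polar <- function(roi_map, center, n_angles = 360L,
                     max_radius = NULL, n_radii = NULL) {
  nr <- nrow(roi_map); nc <- ncol(roi_map)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    stop("unwrapping center lies outside the map")
  }
  if (is.null(max_radius)) max_radius <- sqrt((nr / 2)^2 + (nc / 2)^2)
  if (max_radius <= 0) stop("max_radius must be positive")
  if (is.null(n_radii)) n_radii <- as.integer(ceiling(max_radius))
  radii <- seq_len(n_radii) * max_radius / n_radii
  thetas <- (seq_len(n_angles) - 1L) * 2 * pi / n_angles
  rr <- rep(radii, times = n_angles)
  tt <- rep(thetas, each = n_radii)
  pts <- polar_to_cartesian(center, rr, tt)
  vals <- bilinear_sample(roi_map, pts[, 1], pts[, 2], outside = 0)
  structure(list(values = matrix(vals, n_radii, n_angles),
                 center = as.numeric(center),
                 radii = radii, thetas = thetas,
                 max_radius = max_radius,
                 pad_cols = 0L, pad_weight_prob = NA_real_),
            class = "polar_grid")
}

#' Edge weight between two nodes of the boundary graph
#'
#' `W_ab = 2 - (P_a + P_b)`: the connection between two pixels is weighted
#' inversely to the probability of each being a boundary pixel, so the
#' minimum-weight path follows the boundary. Weights lie in [0, 2] and are
#' symmetric in the two arguments.
#'
#' @param p_a,p_b boundary probabilities in [0, 1] (vectorized).
#' @return numeric edge weight(s).
#' @export
edge_weight <- function(p_a, p_b) {
  if (any(p_a < 0 | p_a > 1) || any(p_b < 0 | p_b > 1)) {
    stop("boundary probabilities must lie in [0, 1]")
  }
  2 - (p_a + p_b)
}

#' Pad a polar grid with low-weight columns on both sides
#'
#' Appends `pad_cols` columns of probability `pad_weight_prob` (close to 1,
#' so incident edges have near-zero weight) to each side of the angle axis.
#' The padding lets the corner-to-corner path snap onto the boundary band
#' regardless of where the band sits; padded columns are stripped again
#' after the search.
#'
#' @param grid a `polar_grid`.
#' @param pad_cols columns added per side (>= 1).
#' @param pad_weight_prob probability assigned to padded nodes; slightly
#'   below 1 keeps all edge weights strictly positive.
#' @return padded `polar_grid`.
#' @export
pad_columns <- function(grid, pad_cols = 2L, pad_weight_prob = 1 - 1e-5) {
  stopifnot(inherits(grid, "polar_grid"), pad_cols >= 1)
  pad <- matrix(pad_weight_prob, nrow(grid$values), pad_cols)
  grid$values <- cbind(pad, grid$values, pad)
  grid$pad_cols <- as.integer(pad_cols)
  grid$pad_weight_prob <- pad_weight_prob
  grid
}

#' Minimum-weight corner-to-corner path through a padded polar grid
#'
#' Finds the minimum-total-weight path from the top-left node to the
#' bottom-right node of the grid under 4-connectivity (horizontal and
#' vertical moves only; restricting out diagonal moves stops the radius from
#' drifting along the path). Edge weights follow [edge_weight()]. The path
#' is then collapsed to one radius per angle column: where the path visits a
#' column at several radii, the radius at which it exits rightward is kept.
#'
#' @param grid a padded `polar_grid` (see [pad_columns()]).
#' @return object of class `polar_path`: `radius_bins` (one per grid
#'   column), `cost` (sum of edge weights along the path), `n_radii`,
#'   `pad_cols`.
#' @export
dijkstra_path <- function(grid) {
  stopifnot(inherits(grid, "polar_grid"))
  V <- grid$values
  nr <- nrow(V); nc <- ncol(V)
  g <- igraph::make_lattice(c(nr, nc))   # first dimension varies fastest
  el <- igraph::as_edgelist(g, names = FALSE)
  P <- as.vector(V)                      # column-major: node = (c-1)*nr + r
  w <- edge_weight(P[el[, 1]], P[el[, 2]])
  sp <- igraph::shortest_paths(g, from = 1, to = nr * nc, weights = w,
                               output = "vpath")
  nodes <- as.integer(sp$vpath[[1]])
  cost <- sum(edge_weight(P[nodes[-length(nodes)]], P[nodes[-1]]))
  rs <- ((nodes - 1L) %% nr) + 1L
  cs <- ((nodes - 1L) %/% nr) + 1L
  # collapse vertical excursions: keep the radius at the rightward exit
  radius_bins <- integer(nc)
  for (k in seq_along(nodes)[-length(nodes)]) {
    if (cs[k + 1L] == cs[k] + 1L) radius_bins[cs[k]] <- rs[k]
  }
  radius_bins[nc] <- rs[length(nodes)]
  structure(list(radius_bins = radius_bins, cost = cost,
                 n_radii = nr, pad_cols = grid$pad_cols),
            class = "polar_path")
}

#' Map a polar path back to a closed Cartesian contour
#'
#' Strips the padded columns, converts each remaining (radius, angle) node
#' to Cartesian coordinates about the grid center, and (optionally) offsets
#' into full-slice coordinates. The result is a closed contour with one
#' point per angle bin.
#'
#' @param path a `polar_path` from [dijkstra_path()].
#' @param grid the (padded) `polar_grid` the path was computed on.
#' @param roi_spec optional ROI specification (from [extract_roi()]); when
#'   given, contour points are offset into full-slice coordinates.
#' @return n_angles x 2 matrix of (row, col) contour points ordered by
#'   angle; the contour closes from the last point back to the first.
#' @export
from_polar <- function(path, grid, roi_spec = NULL) {
  stopifnot(inherits(path, "polar_path"), inherits(grid, "polar_grid"))
  pad <- grid$pad_cols
  nc <- length(path$radius_bins)
  keep <- if (pad > 0) seq.int(pad + 1L, nc - pad) else seq_len(nc)
  bins <- path$radius_bins[keep]
  stopifnot(length(bins) == length(grid$thetas))
  r <- grid$radii[bins]
  pts <- polar_to_cartesian(grid$center, r, grid$thetas)
  if (!is.null(roi_spec)) pts <- roi_to_slice(pts, roi_spec)
  colnames(pts) <- c("row", "col")
  pts
}

# rasterize a closed contour into a filled region mask of size dims
contour_to_mask <- function(contour, dims) {
  m <- matrix(0L, dims[1], dims[2])
  n <- nrow(contour)
  nxt <- c(2:n, 1)
  # densely sample each closing segment so the rasterized outline is
  # gap-free under 4-connected background flood fill
  for (k in seq_len(n)) {
    a <- contour[k, ]; b <- contour[nxt[k], ]
    steps <- max(2L, ceiling(2 * max(abs(b - a))) + 1L)
    t <- seq(0, 1, length.out = steps)
    rr <- clamp(round(a[1] + t * (b[1] - a[1])), 1, dims[1])
    cc <- clamp(round(a[2] + t * (b[2] - a[2])), 1, dims[2])
    m[cbind(rr, cc)] <- 1L
  }
  fill_holes(m)
}

#' Extract the closed orbit contour from a boundary probability map
#'
#' Composition of the polar graph search: unwrap about the center, pad with
#' low-weight columns, run the corner-to-corner Dijkstra search, strip the
#' padding, and map the path back to a closed Cartesian contour plus its
#' filled region mask. A contour is always produced; when the mean boundary
#' probability sampled along it is below `confidence_threshold` the result
#' carries `low_confidence = TRUE`.
#'
#' @param prob_map boundary probability map (matrix in [0, 1]), typically a
#'   128x128 ROI prediction.
#' @param center `(row, col)` unwrapping center in map coordinates.
#' @param n_angles,max_radius,n_radii polar resolution, see [to_polar()].
#' @param pad_cols,pad_weight_prob padding, see [pad_columns()].
#' @param roi_spec optional ROI spec; when given, the returned contour is in
#'   full-slice coordinates and the mask has dimensions `slice_dim`.
#' @param slice_dim dimensions of the mask to rasterize into; defaults to
#'   `dim(prob_map)` (or the full slice implied by `roi_spec`).
#' @param confidence_threshold mean on-path probability below which the
#'   result is flagged low-confidence.
#' @return list with `contour` (n_angles x 2), `mask` (filled region),
#'   `path` (the `polar_path`), `low_confidence`, `mean_path_prob`.
#' @export
extract_boundary <- function(prob_map, center, n_angles = 360L,
                             max_radius = NULL, n_radii = NULL,
                             pad_cols = 2L, pad_weight_prob = 1 - 1e-5,
                             roi_spec = NULL, slice_dim = NULL,
                             confidence_threshold = 0.2) {
  grid <- to_polar(prob_map, center, n_angles = n_angles,
                   max_radius = max_radius, n_radii = n_radii)
  padded <- pad_columns(grid, pad_cols = pad_cols,
                        pad_weight_prob = pad_weight_prob)
  path <- dijkstra_path(padded)
  contour <- from_polar(path, padded, roi_spec = roi_spec)
  keep <- seq.int(pad_cols + 1L, length(path$radius_bins) - pad_cols)
  on_path <- padded$values[cbind(path$radius_bins[keep], keep)]
  mp <- mean(on_path)
  if (is.null(slice_dim)) {
    slice_dim <- if (is.null(roi_spec)) dim(prob_map)
                 else dim(prob_map) + c(roi_spec$offset[1], roi_spec$offset[2])
  }
  mask <- contour_to_mask(contour, slice_dim)
  list(contour = contour, mask = mask, path = path,
       low_confidence = mp < confidence_threshold, mean_path_prob = mp)
}
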