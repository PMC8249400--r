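# Shared fixtures, all generated in code.

# binary disk mask
make_disk <- function(dims, center, radius) {
  rr <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
  cc <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
  matrix(as.integer(sqrt((rr - center[1])^2 + (cc - center[2])^2) <= radius),
         dims[1], dims[2])
}

# Gaussian-blurred ring probability map around an analytic circle
make_ring_map <- function(dims, center, radius, sigma = 1) {
  rr <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
  cc <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  exp(-(d - radius)^2 / (2 * sigma^2))
}

# blurred probability map around an arbitrary contour point set
make_contour_map <- function(dims, contour, sigma = 1) {
  rr <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
  cc <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
  d2 <- matrix(Inf, dims[1], dims[2])
  for (k in seq_len(nrow(contour))) {
    d2 <- pmin(d2, (rr - contour[k, 1])^2 + (cc - contour[k, 2])^2)
  }
  exp(-d2 / (2 * sigma^2))
}

# dense analytic circle point set
circle_points <- function(center, radius, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = center[1] - radius * sin(th), col = center[2] + radius * cos(th))
}

# small noise-free CT-style phantom parameters that fit a 64x64 slice
tiny_ct_params <- function(seed = 1, n_slices = 5, noise_sd = 0,
                           center_jitter = 0, ...) {
  phantom_params("ct", n_slices = n_slices, slice_shape = c(64L, 64L),
                 medial_radius = 9, ring_thickness = 2,
                 noise_sd = noise_sd, outlier_fraction = 0,
                 center_jitter = center_jitter, seed = seed, ...)
}

# exhaustive search over all simple corner-to-corner 4-connected paths with
# sound cost-bound pruning (exact for the nonnegative weights used here);
# independent of the igraph-based implementation under test
oracle_min_path_cost <- function(V) {
  nr <- nrow(V); nc <- ncol(V)
  target <- nr * nc
  visited <- rep(FALSE, nr * nc)
  best <- Inf
  rec <- function(v, cost) {
    if (cost >= best) return(invisible())
    if (v == target) { best <<- cost; return(invisible()) }
    visited[v] <<- TRUE
    r <- (v - 1L) %% nr + 1L
    if (r > 1L)       { u <- v - 1L;  if (!visited[u]) rec(u, cost + 2 - V[v] - V[u]) }
    if (r < nr)       { u <- v + 1L;  if (!visited[u]) rec(u, cost + 2 - V[v] - V[u]) }
    if (v > nr)       { u <- v - nr;  if (!visited[u]) rec(u, cost + 2 - V[v] - V[u]) }
    if (v <= target - nr) { u <- v + nr; if (!visited[u]) rec(u, cost + 2 - V[v] - V[u]) }
    visited[v] <<- FALSE
    invisible()
  }
  rec(1L, 0)
  best
}

# build a padded polar_grid directly from a value matrix (bypassing the
# image-resampling front end) so the search can be tested in isolation
grid_from_values <- function(V, pad_weight_prob = 1 - 1e-5) {
  g <- structure(list(values = V, center = c(1, 1),
                      radii = seq_len(nrow(V)), thetas = numeric(ncol(V)),
                      max_radius = nrow(V), pad_cols = 0L,
                      pad_weight_prob = NA_real_),
                 class = "polar_grid")
  pad_columns(g, pad_cols = 2L, pad_weight_prob = pad_weight_prob)
}
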