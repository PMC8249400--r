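# Polar unwrapping, edge weights, padding, Dijkstra search, and the
# Cartesian round trip.

test_that("edge weight follows W = 2 - (Pa + Pb) and stays in [0, 2]", {
  expect_identical(edge_weight(1, 1), 0)
  expect_identical(edge_weight(0, 0), 2)
  expect_equal(edge_weight(0.6, 0.3), 1.1)
  set.seed(4)
  pa <- runif(100); pb <- runif(100)
  w <- edge_weight(pa, pb)
  expect_true(all(w >= 0 & w <= 2))
  expect_equal(w, edge_weight(pb, pa))
  expect_error(edge_weight(1.2, 0), "\\[0, 1\\]")
})

test_that("polar unwrapping turns rings into horizontal bands", {
  ring <- make_ring_map(c(128, 128), c(64.5, 64.5), 20, sigma = 0.8)
  g <- to_polar(ring, c(64.5, 64.5), n_angles = 90)
  band_bin <- which.min(abs(g$radii - 20))
  # energy concentrates on the radius-20 row for every angle
  peaks <- apply(g$values, 2, which.max)
  expect_true(all(abs(peaks - band_bin) <= 1))
  # constant map stays constant inside the sampled disk
  cg <- to_polar(matrix(0.7, 64, 64), c(32.5, 32.5), n_angles = 36,
                 max_radius = 20)
  expect_true(all(abs(cg$values - 0.7) < 1e-9))
  # point probe: a pixel exactly at center + r0 along theta = 0
  probe <- matrix(0, 64, 64); probe[32, 32 + 15] <- 1
  pg <- to_polar(probe, c(32, 32), n_angles = 360)
  hit <- which(pg$values == max(pg$values), arr.ind = TRUE)
  expect_equal(unname(hit[1, 2]), 1)                # angle bin for theta = 0
  expect_lt(abs(pg$radii[hit[1, 1]] - 15), 1)       # radius bin for r0
  expect_error(to_polar(probe, c(100, 100)), "outside")
})

test_that("padding adds low-weight columns that the path enters and leaves", {
  ring <- make_ring_map(c(64, 64), c(32.5, 32.5), 12, sigma = 0.8)
  g <- to_polar(ring, c(32.5, 32.5), n_angles = 60)
  padded <- pad_columns(g, pad_cols = 2)
  expect_equal(ncol(padded$values), 60 + 4)
  # an edge between two padded nodes has near-zero weight
  expect_equal(edge_weight(padded$pad_weight_prob, padded$pad_weight_prob),
               2e-5, tolerance = 1e-9)
  path <- dijkstra_path(padded)
  expect_equal(length(path$radius_bins), 64)
  # and the contour built from it never references padded bins
  contour <- from_polar(path, padded)
  expect_equal(nrow(contour), 60)
})

test_that("the search cost matches exhaustive enumeration on small grids", {
  set.seed(11)
  for (rep in 1:25) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    g <- grid_from_values(matrix(runif(nr * nc), nr, nc))
    got <- dijkstra_path(g)
    expect_equal(got$cost, oracle_min_path_cost(g$values), tolerance = 1e-12)
  }
})

test_that("equal probabilities make all monotone paths tie", {
  V <- matrix(0.4, 3, 3)
  g <- structure(list(values = V, center = c(1, 1), radii = 1:3,
                      thetas = numeric(3), max_radius = 3,
                      pad_cols = 0L, pad_weight_prob = NA_real_),
                 class = "polar_grid")
  path <- dijkstra_path(g)
  # any monotone corner-to-corner path has 4 edges of weight 2 - 0.8
  expect_equal(path$cost, 4 * (2 - 0.8))
})

test_that("a probability-1 band captures the path away from the corners", {
  V <- matrix(0.05, 9, 20)
  V[5, ] <- 1
  g <- grid_from_values(V)
  path <- dijkstra_path(g)
  interior <- path$radius_bins[3:(length(path$radius_bins) - 2)]
  expect_true(all(interior == 5))
})

test_that("raising an on-path probability never increases the optimal cost", {
  set.seed(21)
  for (rep in 1:10) {
    V <- matrix(runif(30), 5, 6)
    g <- grid_from_values(V)
    base <- dijkstra_path(g)
    keep <- 3:(length(base$radius_bins) - 2)
    col <- sample(keep, 1)
    V2 <- V
    V2[base$radius_bins[col], col - 2] <-
      min(1, V[base$radius_bins[col], col - 2] + runif(1, 0, 0.5))
    expect_lte(dijkstra_path(grid_from_values(V2))$cost, base$cost + 1e-12)
  }
})

test_that("polar round trip reproduces analytic circles to subpixel accuracy", {
  center <- c(64.5, 64.5)
  for (r0 in c(10, 25, 40)) {
    ring <- make_ring_map(c(128, 128), center, r0, sigma = 1)
    eb <- extract_boundary(ring, center)
    rad <- sqrt((eb$contour[, 1] - center[1])^2 + (eb$contour[, 2] - center[2])^2)
    expect_lt(mean(abs(rad - r0)), 0.5)
    expect_lt(hausdorff_distance(eb$contour, circle_points(center, r0)), 1.5)
    expect_false(eb$low_confidence)
  }
})

test_that("an all-zero map still yields a contour, flagged low-confidence", {
  eb <- extract_boundary(matrix(0, 64, 64), c(32.5, 32.5))
  expect_equal(nrow(eb$contour), 360)
  expect_true(eb$low_confidence)
})

test_that("constant-radius paths map back to circles with offset bookkeeping", {
  ring <- make_ring_map(c(128, 128), c(64.5, 64.5), 20, sigma = 1)
  spec <- list(center = c(200, 300), size = 128L,
               offset = c(row = 136L, col = 236L))
  eb <- extract_boundary(ring, c(64.5, 64.5), roi_spec = spec,
                         slice_dim = c(352L, 512L))
  rad <- sqrt((eb$contour[, 1] - 200.5)^2 + (eb$contour[, 2] - 300.5)^2)
  expect_lt(mean(abs(rad - 20)), 0.6)
  expect_equal(dim(eb$mask), c(352L, 512L))
  expect_lt(abs(sum(eb$mask) - pi * 20.5^2) / (pi * 20.5^2), 0.06)
})
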