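# Synthetic orbit phantoms: seeded CT-like and MRI-like volumes with exact
# ground truth (filled region masks, closed contours, true centers), used in
# place of clinical data for training and evaluating every pipeline stage.

#' Parameters of a synthetic orbit phantom volume
#'
#' Describes one subject's coronal stack. The orbit cross-section is a
#' star-shaped region whose radius profile tapers geometrically away from
#' the medial slice and whose shape blends smoothly from a circle towards a
#' rounded triangle in the posterior (small) slices:
#' `r(theta) = r_s * (1 + g * t_s * cos(3 theta)) / (1 + g * t_s)`,
#' with `t_s` growing linearly with distance from the medial slice. The
#' maximal radius of every slice is therefore exactly `r_s`, and slice
#' extents are strictly non-increasing away from the medial slice whenever
#' `taper < 1`. Every slice contains the orbit as a closed contour.
#'
#' Intensity styles: `"ct"` renders a bright, high-contrast bone ring over a
#' uniform background, optionally with a sparse fraction of extreme-valued
#' outlier pixels (to exercise percentile saturation); `"mri"` renders a
#' lower-contrast ring modulated by a smooth multiplicative field plus
#' stronger Gaussian noise (texture). Ground truth is always noise free.
#'
#' @param modality `"ct"` or `"mri"`; selects intensity defaults and whether
#'   outlier pixels may occur (CT only).
#' @param n_slices number of coronal slices (>= 3).
#' @param slice_shape `(rows, cols)` in pixels. The orbit is centered in the
#'   left half of the image (a single orbit per half-image).
#' @param medial_radius maximal orbit radius at the medial slice, pixels.
#' @param taper per-slice geometric radius decay in (0, 1]; 1 disables
#'   tapering.
#' @param triangularity_gain strength `g >= 0` of the circle-to-triangle
#'   blend in posterior slices; 0 keeps all slices circular.
#' @param ring_thickness bone ring thickness in pixels (>= 1).
#' @param bone_intensity,cavity_intensity,background_intensity normalized
#'   intensity levels; `NULL` picks per-modality defaults
#'   (CT 0.90/0.30/0.10, MRI 0.62/0.42/0.32).
#' @param noise_sd Gaussian intensity noise standard deviation; `NULL` picks
#'   0.02 (CT) or 0.05 (MRI).
#' @param outlier_fraction fraction in [0, 0.05] of pixels replaced by
#'   extreme values (CT only); `NULL` picks 0.002 (CT) or 0 (MRI).
#' @param center_jitter per-slice uniform jitter of the orbit center, pixels.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `phantom_params`.
#' @seealso [generate_volume()], [generate_dataset()]
#' @export
phantom_params <- function(modality = c("ct", "mri"),
                           n_slices = 9L,
                           slice_shape = c(128L, 128L),
                           medial_radius = 20,
                           taper = 0.92,
                           triangularity_gain = 0.6,
                           ring_thickness = 3,
                           bone_intensity = NULL,
                           cavity_intensity = NULL,
                           background_intensity = NULL,
                           noise_sd = NULL,
                           outlier_fraction = NULL,
                           center_jitter = 2,
                           seed = 1L) {
  modality <- match.arg(modality)
  if (n_slices < 3) stop("n_slices must be >= 3")
  if (medial_radius <= 0) stop("medial_radius must be positive")
  if (taper <= 0 || taper > 1) stop("taper must lie in (0, 1]")
  if (triangularity_gain < 0) stop("triangularity_gain must be >= 0")
  if (ring_thickness < 1) stop("ring_thickness must be >= 1")
  def <- if (modality == "ct") {
    list(bone = 0.90, cavity = 0.30, background = 0.10,
         noise = 0.02, outlier = 0.002)
  } else {
    list(bone = 0.62, cavity = 0.42, background = 0.32,
         noise = 0.05, outlier = 0)
  }
  p <- list(
    modality = modality,
    n_slices = as.integer(n_slices),
    slice_shape = as.integer(slice_shape),
    medial_radius = medial_radius,
    taper = taper,
    triangularity_gain = triangularity_gain,
    ring_thickness = ring_thickness,
    bone_intensity = bone_intensity %||% def$bone,
    cavity_intensity = cavity_intensity %||% def$cavity,
    background_intensity = background_intensity %||% def$background,
    noise_sd = noise_sd %||% def$noise,
    outlier_fraction = outlier_fraction %||% def$outlier,
    center_jitter = center_jitter,
    spacing_mm = c(0.5, 0.5, 0.5),
    seed = as.integer(seed)
  )
  if (p$outlier_fraction < 0 || p$outlier_fraction > 0.05) {
    stop("outlier_fraction must lie in [0, 0.05]")
  }
  if (modality == "mri" && p$outlier_fraction > 0) {
    stop("outlier pixels are a CT-style feature; set outlier_fraction = 0 for mri")
  }
  # the orbit (max radius + ring + jitter) must fit inside the left half
  extent <- p$medial_radius + p$ring_thickness + p$center_jitter + 2
  if (extent > p$slice_shape[1] / 2 || extent > p$slice_shape[2] / 4) {
    stop("slice_shape too small to contain the orbit ",
         "(need medial_radius + ring_thickness + center_jitter to fit ",
         "inside the left half-image)")
  }
  class(p) <- "phantom_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-slice maximal radius and triangularity blend factor
phantom_radius_profile <- function(p) {
  medial <- (p$n_slices + 1L) %/% 2L
  d <- abs(seq_len(p$n_slices) - medial)
  list(medial = medial,
       radius = p$medial_radius * p$taper^d,
       tri = if (max(d) > 0) d / max(d) else rep(0, p$n_slices))
}

# star-shaped cross-section radius as a function of angle
phantom_shape_radius <- function(r_slice, gain, tri, theta) {
  r_slice * (1 + gain * tri * cos(3 * theta)) / (1 + gain * tri)
}

#' Generate one synthetic orbit phantom volume
#'
#' Renders intensities plus exact ground truth (filled region mask, closed
#' boundary contour and true center per slice) for one subject. Fully
#' deterministic given `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @return object of class `phantom_volume` with elements `intensities`
#'   (list of matrices), `region_masks`, `contours` (each a matrix of
#'   (row, col) points ordered by angle), `centers` (n_slices x 2 matrix of
#'   mask centroids), `spacing_mm`, and `params`.
#' @export
generate_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  nr <- p$slice_shape[1]; nc <- p$slice_shape[2]
  prof <- phantom_radius_profile(p)
  set.seed(p$seed)
  base_center <- c(nr / 2, nc / 4)   # orbit sits in the left half-image
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)

  intensities <- vector("list", p$n_slices)
  masks <- vector("list", p$n_slices)
  contours <- vector("list", p$n_slices)
  centers <- matrix(NA_real_, p$n_slices, 2,
                    dimnames = list(NULL, c("row", "col")))

  # one smooth multiplicative field per subject (MRI texture)
  if (p$modality == "mri") {
    fr <- runif(2, 0.5, 1.5); ph <- runif(2, 0, 2 * pi)
    field <- 1 + 0.12 * sin(2 * pi * fr[1] * rows / nr + ph[1]) *
                    cos(2 * pi * fr[2] * cols / nc + ph[2])
  }

  for (s in seq_len(p$n_slices)) {
    jit <- runif(2, -p$center_jitter, p$center_jitter)
    ctr <- base_center + jit
    dr <- rows - ctr[1]; dc <- cols - ctr[2]
    dist <- sqrt(dr^2 + dc^2)
    theta <- atan2(-dr, dc)          # theta = 0 along +col, CCW, row down
    rb <- phantom_shape_radius(prof$radius[s], p$triangularity_gain,
                               prof$tri[s], theta)
    mask <- matrix(as.integer(dist <= rb), nr, nc)
    ring <- dist > rb & dist <= rb + p$ring_thickness

    img <- matrix(p$background_intensity, nr, nc)
    img[mask > 0] <- p$cavity_intensity
    img[ring] <- p$bone_intensity
    if (p$modality == "mri") img <- img * field
    if (p$noise_sd > 0) img <- img + rnorm(nr * nc, sd = p$noise_sd)
    if (p$modality == "ct" && p$outlier_fraction > 0) {
      n_out <- max(1L, floor(p$outlier_fraction * nr * nc))
      at <- sample.int(nr * nc, n_out)
      img[at] <- rep_len(c(4 * p$bone_intensity, -2 * p$bone_intensity), n_out)
    }

    intensities[[s]] <- img
    masks[[s]] <- mask
    centers[s, ] <- mask_centroid(mask)
    contours[[s]] <- mask_contour(mask, center = centers[s, ])
  }

  structure(list(intensities = intensities,
                 region_masks = masks,
                 contours = contours,
                 centers = centers,
                 spacing_mm = p$spacing_mm,
                 params = p),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  p <- x$params
  cat(sprintf("<phantom_volume> %s-like, %d slices of %d x %d px, 0.5 mm isotropic\n",
              p$modality, p$n_slices, p$slice_shape[1], p$slice_shape[2]))
  cat(sprintf("  medial radius %.1f px, taper %.2f, triangularity %.2f, seed %d\n",
              p$medial_radius, p$taper, p$triangularity_gain, p$seed))
  invisible(x)
}

#' Generate a cohort of phantom subjects
#'
#' Draws per-subject perturbations (radius, intensity levels, taper) from a
#' seeded stream, then renders each subject with [generate_volume()] under a
#' derived per-subject seed, so subjects are mutually distinct yet the whole
#' cohort is reproducible.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param params template [phantom_params()]; per-subject parameters are
#'   perturbed around it.
#' @param seed cohort-level seed (independent of `params$seed`).
#' @return list of `phantom_volume`, one per subject, each carrying its
#'   perturbed parameters.
#' @export
generate_dataset <- function(n_subjects, params, seed = 1L) {
  stopifnot(n_subjects >= 1, inherits(params, "phantom_params"))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  radius_f <- runif(n_subjects, 0.85, 1.15)
  bone_f <- runif(n_subjects, 0.92, 1.08)
  taper_d <- runif(n_subjects, -0.02, 0.02)
  lapply(seq_len(n_subjects), function(i) {
    p <- params
    p$medial_radius <- params$medial_radius * radius_f[i]
    p$bone_intensity <- min(0.98, params$bone_intensity * bone_f[i])
    p$taper <- clamp(params$taper + taper_d[i], 0.05, 1)
    p$seed <- sub_seeds[i]
    generate_volume(p)
  })
}

#' Write a phantom volume to disk in plain interchange formats
#'
#' Slices are written as 16-bit grayscale TIFF (intensities clamped to
#' [0, 1] and scaled), region masks as 8-bit TIFF (0/255), contours as one
#' CSV (`slice_index, point_index, row, col`), and the generating parameters
#' as a YAML sidecar.
#'
#' @param volume a `phantom_volume`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(volume, dir) {
  stopifnot(inherits(volume, "phantom_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(volume$intensities)
  for (s in seq_len(n)) {
    img <- clamp(volume$intensities[[s]], 0, 1)
    tiff::writeTIFF(img, file.path(dir, sprintf("slice_%03d.tif", s)),
                    bits.per.sample = 16)
    tiff::writeTIFF(volume$region_masks[[s]] * 1.0,
                    file.path(dir, sprintf("mask_%03d.tif", s)),
                    bits.per.sample = 8)
  }
  ct <- do.call(rbind, lapply(seq_len(n), function(s) {
    k <- volume$contours[[s]]
    data.frame(slice_index = s, point_index = seq_len(nrow(k)),
               row = k[, 1], col = k[, 2])
  }))
  write.csv(ct, file.path(dir, "contours.csv"), row.names = FALSE)
  pr <- volume$params; class(pr) <- NULL
  yaml::write_yaml(pr, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a phantom volume written by [write_phantom()]
#'
#' @param dir directory containing `slice_*.tif`, `mask_*.tif`,
#'   `contours.csv` and `params.yaml`.
#' @return a `phantom_volume` (intensities quantized to 16-bit precision).
#' @export
read_phantom <- function(dir) {
  pr <- yaml::read_yaml(file.path(dir, "params.yaml"))
  slices <- sort(list.files(dir, "^slice_\\d+\\.tif$", full.names = TRUE))
  masks <- sort(list.files(dir, "^mask_\\d+\\.tif$", full.names = TRUE))
  intens <- lapply(slices, function(f) as.matrix(tiff::readTIFF(f)))
  msk <- lapply(masks, function(f) {
    m <- as.matrix(tiff::readTIFF(f)); matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  })
  ct <- read.csv(file.path(dir, "contours.csv"))
  contours <- lapply(seq_along(intens), function(s) {
    k <- ct[ct$slice_index == s, c("row", "col")]
    as.matrix(k)
  })
  centers <- do.call(rbind, lapply(msk, mask_centroid))
  colnames(centers) <- c("row", "col")
  p <- pr; class(p) <- "phantom_params"
  structure(list(intensities = intens, region_masks = msk,
                 contours = contours, centers = centers,
                 spacing_mm = pr$spacing_mm, params = p),
            class = "phantom_volume")
}
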