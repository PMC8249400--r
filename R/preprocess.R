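# Slice preprocessing: min-max normalization, CT percentile saturation,
# isotropic resampling, half-image cropping, and paired geometric
# augmentation for training.

#' Min-max normalize an image to [0, 1]
#'
#' Affine map taking the image minimum to 0 and maximum to 1; pixel ordering
#' is preserved. A constant image maps to all zeros (with a warning) rather
#' than failing on the zero range.
#'
#' @param image numeric matrix.
#' @return matrix with values in [0, 1].
#' @export
normalize_minmax <- function(image) {
  if (length(image) == 0) stop("image is empty")
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    warning("constant image: normalize_minmax returns all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - lo) / (hi - lo)
}

#' Saturate extreme intensities at empirical percentiles
#'
#' Clips values below the `low_pct` percentile and above the `high_pct`
#' percentile of the image's own intensity distribution. Used on CT slices
#' feeding the global network, before normalization, to stop extreme outlier
#' pixels from compressing the useful intensity range. Monotone
#' non-decreasing pixel-wise and idempotent.
#'
#' @param image numeric matrix.
#' @param low_pct,high_pct percentile bounds, `0 <= low_pct < high_pct <= 100`.
#' @return clipped matrix.
#' @export
saturate_percentiles <- function(image, low_pct = 1, high_pct = 99) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    stop("need 0 <= low_pct < high_pct <= 100")
  }
  # order-statistic (type 1) quantiles: clipping at actual pixel values
  # makes the operation exactly idempotent
  q <- quantile(image, c(low_pct, high_pct) / 100, names = FALSE, type = 1)
  clamp(image, q[1], q[2])
}

#' Resample a volume to isotropic in-plane spacing
#'
#' Interpolates each slice so the in-plane pixel spacing becomes
#' `target_spacing_mm` (0.5 mm by default, the working resolution of the
#' pipeline). Intensities use bilinear interpolation; masks must use
#' `interp = "nearest"` so they stay binary.
#'
#' @param volume list with elements `slices` (list of matrices) and
#'   `spacing_mm` (length >= 2: row, col spacing in mm), or a
#'   `phantom_volume` (its intensities are resampled).
#' @param target_spacing_mm target in-plane spacing, mm.
#' @param interp "bilinear" or "nearest".
#' @return volume of the same shape with resampled slices and updated
#'   spacing.
#' @export
resample_isotropic <- function(volume, target_spacing_mm = 0.5,
                               interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  slices <- if (inherits(volume, "phantom_volume")) volume$intensities else volume$slices
  sp <- volume$spacing_mm
  if (is.null(sp) || any(!is.finite(sp[1:2])) || any(sp[1:2] <= 0)) {
    stop("volume has missing or non-positive spacing metadata")
  }
  if (isTRUE(all.equal(sp[1], target_spacing_mm)) &&
      isTRUE(all.equal(sp[2], target_spacing_mm))) {
    return(volume)
  }
  fr <- sp[1] / target_spacing_mm; fc <- sp[2] / target_spacing_mm
  out <- lapply(slices, function(img) {
    nr2 <- max(1L, round(nrow(img) * fr)); nc2 <- max(1L, round(ncol(img) * fc))
    # output pixel centers mapped back into source coordinates
    src_r <- ((seq_len(nr2) - 0.5) / fr) + 0.5
    src_c <- ((seq_len(nc2) - 0.5) / fc) + 0.5
    rr <- rep(src_r, times = nc2); cc <- rep(src_c, each = nr2)
    v <- if (interp == "bilinear") bilinear_sample(img, rr, cc, outside = min(img))
         else nearest_sample(img, rr, cc, outside = 0)
    matrix(v, nr2, nc2)
  })
  res <- volume
  if (inherits(volume, "phantom_volume")) res$intensities <- out else res$slices <- out
  res$spacing_mm <- c(target_spacing_mm, target_spacing_mm,
                      if (length(sp) >= 3) sp[3] else target_spacing_mm)
  res
}

#' Crop the left or right half of a slice
#'
#' Only one orbit is segmented per scan, so the half-image containing it is
#' fed to the global network. The returned matrix carries a
#' `crop_offset` attribute (0-based column offset of the crop within the
#' full slice) so ROI and contour coordinates can be mapped back.
#'
#' @param image numeric matrix with at least 2 columns.
#' @param side `"left"` or `"right"`.
#' @return matrix of width `floor(ncol/2)` with attribute `crop_offset`.
#' @export
crop_half <- function(image, side = c("left", "right")) {
  side <- match.arg(side)
  w <- ncol(image)
  if (w < 2) stop("image must be at least 2 pixels wide")
  hw <- w %/% 2L
  cols <- if (side == "left") seq_len(hw) else seq.int(w - hw + 1L, w)
  out <- image[, cols, drop = FALSE]
  attr(out, "crop_offset") <- cols[1] - 1L
  out
}

#' Training-time augmentation configuration
#'
#' Horizontal reflection with probability `flip_probability` and rotation by
#' an angle drawn uniformly from `[-rotation_range_deg, +rotation_range_deg]`
#' degrees, applied identically to an image and its mask. When `seed` is
#' given the configuration carries its own reproducible random stream,
#' independent of the session RNG.
#'
#' @param flip_probability probability of horizontal reflection, in [0, 1].
#' @param rotation_range_deg symmetric rotation bound in degrees (>= 0).
#' @param seed optional integer seed for a private stream.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(flip_probability = 0.5, rotation_range_deg = 10,
                           seed = NULL) {
  if (flip_probability < 0 || flip_probability > 1) {
    stop("flip_probability must lie in [0, 1]")
  }
  if (rotation_range_deg < 0) stop("rotation_range_deg must be >= 0")
  cfg <- new.env(parent = emptyenv())
  cfg$flip_probability <- flip_probability
  cfg$rotation_range_deg <- rotation_range_deg
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    cfg$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  class(cfg) <- "augment_config"
  cfg
}

# draw from the config's private stream if it has one, else the session RNG
with_aug_rng <- function(cfg, expr) {
  if (is.null(cfg$state)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", cfg$state, globalenv())
  on.exit({
    cfg$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  eval.parent(substitute(expr))
}

#' Apply one random augmentation identically to an image and its mask
#'
#' Draws a horizontal-flip decision and a rotation angle, then applies the
#' same geometric transform to both inputs: bilinear interpolation for the
#' image (border filled with the image minimum), nearest-neighbour for the
#' mask (border filled with 0), both about the image center.
#'
#' @param image numeric matrix.
#' @param mask congruent binary matrix.
#' @param cfg an [augment_config()].
#' @return list with transformed `image` and `mask`, plus the realized
#'   `flipped` and `angle_deg`.
#' @export
augment_pair <- function(image, mask, cfg = augment_config()) {
  stopifnot(all(dim(image) == dim(mask)))
  draws <- with_aug_rng(cfg, {
    list(flip = runif(1) < cfg$flip_probability,
         angle = if (cfg$rotation_range_deg > 0)
                   runif(1, -cfg$rotation_range_deg, cfg$rotation_range_deg)
                 else 0)
  })
  img <- image; msk <- mask
  if (draws$flip) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (draws$angle != 0) {
    img <- rotate_image(img, draws$angle, interp = "bilinear", fill = min(img))
    msk <- rotate_image(msk, draws$angle, interp = "nearest", fill = 0)
  }
  storage.mode(msk) <- "integer"
  list(image = img, mask = msk, flipped = draws$flip, angle_deg = draws$angle)
}
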