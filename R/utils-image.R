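# Shared low-level image helpers. Images are plain numeric matrices indexed
# [row, col] with row 1 at the top; all public geometry in the package uses
# this convention.

#' Bilinear sampling of an image at real-valued coordinates
#'
#' Samples `img` at the (fractional) positions given by `rows` and `cols`.
#' Positions outside the image evaluate to `outside`.
#'
#' @param img numeric matrix.
#' @param rows,cols numeric vectors of equal length, 1-based pixel
#'   coordinates (pixel centers at integer positions).
#' @param outside value returned for samples outside the image extent.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, rows, cols, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  # clamp the four corner indices; weight of out-of-range corners is zeroed
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    if (any(ok)) v[ok] <- img[cbind(r[ok], c[ok])]
    v[!ok] <- NA_real_
    v
  }
  v00 <- get(r0,     c0)
  v01 <- get(r0,     c0 + 1)
  v10 <- get(r0 + 1, c0)
  v11 <- get(r0 + 1, c0 + 1)
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc);       w11 <- fr * fc
  # treat missing corners as `outside`
  fix <- function(v) { v[is.na(v)] <- outside; v }
  out <- fix(v00) * w00 + fix(v01) * w01 + fix(v10) * w10 + fix(v11) * w11
  fully_out <- rows < 0.5 - 1e-9 | rows > nr + 0.5 + 1e-9 |
               cols < 0.5 - 1e-9 | cols > nc + 0.5 + 1e-9
  out[fully_out] <- outside
  out
}

#' Nearest-neighbour sampling of an image at real-valued coordinates
#' @inheritParams bilinear_sample
#' @keywords internal
nearest_sample <- function(img, rows, cols, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r <- round(rows); c <- round(cols)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  v <- rep(outside, length(r))
  if (any(ok)) v[ok] <- img[cbind(r[ok], c[ok])]
  v
}

#' Rotate an image about its center
#'
#' Output has the same dimensions as the input; pixels whose pre-image falls
#' outside the input are filled with `fill`.
#'
#' @param img numeric matrix.
#' @param degrees rotation angle, counter-clockwise in the displayed image.
#' @param interp "bilinear" (intensities) or "nearest" (label masks).
#' @param fill fill value for pixels rotated in from outside the image;
#'   defaults to the image minimum so no spurious bright border is created.
#' @return rotated matrix of the same dimensions.
#' @export
rotate_image <- function(img, degrees,
                         interp = c("bilinear", "nearest"),
                         fill = min(img)) {
  interp <- match.arg(interp)
  if (degrees == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  # inverse map: for each output pixel find the source position
  rr <- rep(seq_len(nr), times = nc) - cr
  cl <- rep(seq_len(nc), each = nr) - cc
  src_r <- cr + co * rr + si * cl
  src_c <- cc - si * rr + co * cl
  v <- if (interp == "bilinear") {
    bilinear_sample(img, src_r, src_c, outside = fill)
  } else {
    nearest_sample(img, src_r, src_c, outside = fill)
  }
  matrix(v, nr, nc)
}

# binary dilation with a 3x3 structuring element, `iter` times
dilate3 <- function(mask, iter = 1) {
  m <- mask > 0
  for (k in seq_len(iter)) {
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    out[-1, ]  <- out[-1, ]  | m[-nr, ]
    out[-nr, ] <- out[-nr, ] | m[-1, ]
    out[, -1]  <- out[, -1]  | m[, -nc]
    out[, -nc] <- out[, -nc] | m[, -1]
    out[-1, -1]   <- out[-1, -1]   | m[-nr, -nc]
    out[-1, -nc]  <- out[-1, -nc]  | m[-nr, -1]
    out[-nr, -1]  <- out[-nr, -1]  | m[-1, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
    m <- out
  }
  storage.mode(m) <- "integer"
  m
}

# boundary pixels of a binary mask: foreground pixels with at least one
# 4-neighbour outside the mask (or on the image border)
mask_boundary <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(rep(FALSE, nc), m[-nr, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], rep(FALSE, nc))
  lf <- cbind(rep(FALSE, nr), m[, -nc, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], rep(FALSE, nr))
  b <- m & !(up & dn & lf & rt)
  storage.mode(b) <- "integer"
  b
}

#' Ordered boundary contour of a star-shaped binary mask
#'
#' Returns the mask's boundary pixels ordered by angle about the mask
#' centroid, as a closed contour. Adequate for the star-shaped (convex to
#' rounded-triangular) orbit cross-sections this package works with.
#'
#' @param mask binary matrix.
#' @param center optional (row, col) ordering center; defaults to the mask
#'   centroid.
#' @return n x 2 matrix of (row, col) boundary points ordered
#'   counter-clockwise, not repeating the first point.
#' @export
mask_contour <- function(mask, center = NULL) {
  b <- mask_boundary(mask)
  idx <- which(b > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty; no contour exists")
  if (is.null(center)) center <- mask_centroid(mask)
  ang <- atan2(-(idx[, 1] - center[1]), idx[, 2] - center[2])
  out <- idx[order(ang), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
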