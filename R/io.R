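# Plain-text I/O for segmentation results: contours as CSV, masks as 8-bit
# TIFF, summary tables as CSV (round-trippable), reports as JSON.

#' Write per-slice contours to CSV
#'
#' One row per contour point: `slice_index, point_index, row, col`.
#'
#' @param contours list of n x 2 (row, col) matrices.
#' @param path output CSV path.
#' @param slice_indices original slice numbers (defaults to 1..n).
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path,
                               slice_indices = seq_along(contours)) {
  rows <- do.call(rbind, lapply(seq_along(contours), function(j) {
    k <- contours[[j]]
    if (nrow(k) == 0) return(NULL)
    data.frame(slice_index = slice_indices[j], point_index = seq_len(nrow(k)),
               row = k[, 1], col = k[, 2])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read contours written by [write_contours_csv()]
#'
#' @param path CSV path.
#' @return named list of (row, col) matrices, one per slice index present.
#' @export
read_contours_csv <- function(path) {
  d <- read.csv(path)
  out <- lapply(split(d, d$slice_index), function(g) {
    g <- g[order(g$point_index), ]
    as.matrix(g[, c("row", "col")])
  })
  out
}

#' Write binary masks as 8-bit TIFF slices
#'
#' @param masks list of binary matrices.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_masks_tiff <- function(masks, dir, prefix = "mask") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(masks)) {
    tiff::writeTIFF((masks[[s]] > 0) * 1.0,
                    file.path(dir, sprintf("%s_%03d.tif", prefix, s)),
                    bits.per.sample = 8)
  }
  invisible(dir)
}

#' Write and re-read a numeric summary table
#'
#' The CSV writer preserves full double precision, so
#' `read_table_csv(write_table_csv(tab, f))` reproduces the numbers
#' exactly.
#'
#' @param table data frame with one character `run` column and numeric
#'   metric columns.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  write.csv(format(table, digits = 17, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  for (cn in names(d)[-1]) d[[cn]] <- as.numeric(d[[cn]])
  d
}
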