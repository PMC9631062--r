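#' Region-of-interest mask
#'
#' A binary raster selecting the fluorescence-positive pixels of a cell.
#'
#' @param mask Logical (or 0/1) matrix, `height x width`.
#' @return An `roi_mask` with fields `mask` and `n_pixels`.
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask > 0
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  structure(list(mask = mask, height = nrow(mask), width = ncol(mask),
                 n_pixels = sum(mask)),
            class = "roi_mask")
}

#' ROI mask from a cell footprint
#'
#' Selects pixels whose footprint weight exceeds a threshold (by default
#' every non-zero pixel, i.e. annulus plus interior).
#'
#' @param footprint A [cell_footprint()].
#' @param threshold Minimum weight for inclusion.
#' @return An `roi_mask`.
#' @export
roi_from_footprint <- function(footprint, threshold = 0) {
  stopifnot(inherits(footprint, "cell_footprint"))
  roi_mask(footprint$weight_map > threshold)
}

#' Write / read an ROI mask as a CSV boolean raster
#'
#' @param roi An `roi_mask`.
#' @param path CSV path.
#' @return `path` (write) or an `roi_mask` (read).
#' @export
write_roi_csv <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  utils::write.table(roi$mask * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  roi_mask(m)
}

#' Write / read an ROI mask as run-length JSON
#'
#' Rows are encoded as `(row, col_start, length)` runs of member pixels.
#'
#' @param roi An `roi_mask`.
#' @param path JSON path.
#' @return `path` (write) or an `roi_mask` (read).
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  runs <- list()
  for (r in seq_len(roi$height)) {
    v <- roi$mask[r, ]
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (j in which(rl$values))
      runs[[length(runs) + 1]] <- c(r, starts[j], rl$lengths[j])
  }
  jsonlite::write_json(list(height = roi$height, width = roi$width,
                            runs = runs),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  m <- matrix(FALSE, d$height, d$width)
  runs <- d$runs
  if (is.list(runs)) runs <- do.call(rbind, runs)
  for (i in seq_len(nrow(runs)))
    m[runs[i, 1], runs[i, 2]:(runs[i, 2] + runs[i, 3] - 1)] <- TRUE
  roi_mask(m)
}
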