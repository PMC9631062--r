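#' Bit-plane stack container
#'
#' Holds a sequence of binary frames (bit planes) from a SPAD array plus
#' acquisition metadata.
#'
#' @param planes Integer array `height x width x n_planes` with values in
#'   {0, 1}.
#' @param frame_rate_Hz Acquisition rate in Hz.
#' @param metadata Free-form named list.
#' @return A `bit_plane_stack` object.
#' @export
bit_plane_stack <- function(planes, frame_rate_Hz, metadata = list()) {
  if (!is.array(planes) || length(dim(planes)) != 3L)
    stop("`planes` must be a 3-d array (height x width x n_planes)",
         call. = FALSE)
  check_scalar(frame_rate_Hz, "frame_rate_Hz")
  if (dim(planes)[3] < 1L) stop("need at least one plane", call. = FALSE)
  storage.mode(planes) <- "integer"
  rng <- range(planes)
  if (rng[1] < 0L || rng[2] > 1L)
    stop("bit-plane values must be 0 or 1", call. = FALSE)
  structure(list(planes = planes,
                 height = dim(planes)[1], width = dim(planes)[2],
                 n_planes = dim(planes)[3],
                 frame_rate_Hz = frame_rate_Hz,
                 metadata = metadata),
            class = "bit_plane_stack")
}

#' @export
print.bit_plane_stack <- function(x, ...) {
  cat(sprintf("<bit_plane_stack> %d x %d px, %d planes @ %.4f Hz, occupancy %.4f\n",
              x$width, x$height, x$n_planes, x$frame_rate_Hz,
              mean(x$planes)))
  invisible(x)
}

#' Compose an intensity image by summing bit planes
#'
#' Per-pixel integer sum of the binary values over a contiguous plane
#' interval; summing ~10^4 planes of a 1 s recording yields a grey-scale
#' image of the field of view.
#'
#' @param stack A [bit_plane_stack()].
#' @param range Plane interval `c(first, last)` (1-based, inclusive);
#'   default all planes.
#' @return A `composed_image` with fields `values` (height x width),
#'   `n_planes_summed` and `corrected` flags.
#' @export
compose_image <- function(stack, range = c(1L, stack$n_planes)) {
  stopifnot(inherits(stack, "bit_plane_stack"))
  range <- as.integer(range)
  if (length(range) != 2L || range[1] > range[2])
    stop("empty or invalid plane interval", call. = FALSE)
  if (range[1] < 1L || range[2] > stack$n_planes)
    stop(sprintf("plane interval [%d, %d] outside stack (1..%d)",
                 range[1], range[2], stack$n_planes), call. = FALSE)
  vals <- rowSums(stack$planes[, , range[1]:range[2], drop = FALSE],
                  dims = 2)
  structure(list(values = vals, width = stack$width, height = stack$height,
                 n_planes_summed = range[2] - range[1] + 1L,
                 frame_rate_Hz = stack$frame_rate_Hz,
                 corrected = c(dark = FALSE, log = FALSE)),
            class = "composed_image")
}

#' Correct a composed image for pixel nonlinearity and dark counts
#'
#' Inverts the binary pixel response: per-pixel occupancy
#' \eqn{\hat p = \mathrm{sum} / n} is mapped to
#' \eqn{\hat\lambda = -\ln(1 - \hat p)} (expected photons per exposure),
#' then the expected dark contribution `dark_count_rate_cps * exposure_s`
#' is subtracted and the result clipped at 0. Saturated pixels
#' (\eqn{\hat p = 1}) are capped at \eqn{-\ln(1 / (2n))} so downstream
#' statistics stay finite.
#'
#' @param img A `composed_image` from [compose_image()], uncorrected.
#' @param sensor A [sensor_model()] supplying the dark count rate and
#'   exposure; pass one with `dark_count_rate_cps = 0` to skip dark
#'   subtraction.
#' @return A `composed_image` with `values` in photons per exposure and
#'   `corrected = c(dark = TRUE, log = TRUE)`.
#' @export
correct_image <- function(img, sensor) {
  stopifnot(inherits(img, "composed_image"), inherits(sensor, "sensor_model"))
  if (any(img$corrected))
    stop("image is already corrected", call. = FALSE)
  n <- img$n_planes_summed
  if (n == 0L) stop("n_planes_summed is zero", call. = FALSE)
  p <- img$values / n
  p <- pmin(p, 1 - 1 / (2 * n))      # saturation cap
  lam <- -log1p(-p)
  lam <- pmax(0, lam - sensor$dark_count_rate_cps * sensor$exposure_s)
  img$values <- lam
  img$corrected <- c(dark = TRUE, log = TRUE)
  img
}

#' Export a composed image
#'
#' Writes either a 16-bit grey-scale TIFF (values scaled by the image
#' maximum) or a CSV matrix.
#'
#' @param img A `composed_image`.
#' @param path Output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_composed_image <- function(img, path) {
  stopifnot(inherits(img, "composed_image"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mx <- max(img$values, 1e-12)
    tiff::writeTIFF(img$values / mx, path, bits.per.sample = 16L)
  } else {
    utils::write.table(img$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
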