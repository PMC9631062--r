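# Packed bit-plane (.spb) container.
#
# Layout (little-endian), 32-byte header:
#   bytes 0-3   magic "SPB1"
#   byte  4     version (1)
#   bytes 5-7   reserved (0)
#   bytes 8-9   width  (uint16)
#   bytes 10-11 height (uint16)
#   bytes 12-15 n_planes (uint32)
#   bytes 16-23 frame_rate_Hz (float64)
#   bytes 24-27 flags (uint32, 0)
#   bytes 28-31 metadata byte length (uint32)
# then optional UTF-8 JSON metadata, then the planes in time order, each
# plane row-major with bits packed MSB-first and padded to a byte boundary.

uint_to_raw <- function(x, nbytes) {
  x <- as.double(x)
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_uint <- function(r) {
  sum(as.double(as.integer(r)) * 256^(seq_along(r) - 1))
}

pack_bits_msb <- function(bits) {
  n <- length(bits)
  pad <- (-n) %% 8
  if (pad > 0) bits <- c(bits, integer(pad))
  m <- matrix(as.logical(bits), nrow = 8)
  packBits(as.vector(m[8:1, , drop = FALSE]), type = "raw")
}

unpack_bits_msb <- function(bytes, n_bits) {
  b <- matrix(as.integer(rawToBits(bytes)), nrow = 8)
  as.vector(b[8:1, , drop = FALSE])[seq_len(n_bits)]
}

#' Write a bit-plane stack to a packed `.spb` file
#'
#' Lossless, bit-exact serialization; see the package vignette for the byte
#' layout. `read_stack(write_stack(s))` reproduces `s` exactly.
#'
#' @param stack A [bit_plane_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "bit_plane_stack"))
  meta <- charToRaw(jsonlite::toJSON(stack$metadata, auto_unbox = TRUE,
                                     digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SPB1"), con)
  writeBin(as.raw(c(1, 0, 0, 0)), con)          # version + reserved
  writeBin(uint_to_raw(stack$width, 2), con)
  writeBin(uint_to_raw(stack$height, 2), con)
  writeBin(uint_to_raw(stack$n_planes, 4), con)
  writeBin(stack$frame_rate_Hz, con, size = 8, endian = "little")
  writeBin(uint_to_raw(0, 4), con)              # flags
  writeBin(uint_to_raw(length(meta), 4), con)
  if (length(meta)) writeBin(meta, con)
  for (t in seq_len(stack$n_planes)) {
    # row-major: transpose the height x width matrix
    bits <- as.integer(t(stack$planes[, , t]))
    writeBin(pack_bits_msb(bits), con)
  }
  invisible(path)
}

#' Read a bit-plane stack from a packed `.spb` file
#'
#' @param path File written by [write_stack()].
#' @return A [bit_plane_stack()].
#' @export
read_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || !identical(rawToChar(magic), "SPB1"))
    stop("not an SPB file: bad magic at offset 0", call. = FALSE)
  ver <- readBin(con, "raw", 4)
  if (as.integer(ver[1]) != 1L)
    stop(sprintf("unsupported SPB version %d at offset 4", as.integer(ver[1])),
         call. = FALSE)
  width <- raw_to_uint(readBin(con, "raw", 2))
  height <- raw_to_uint(readBin(con, "raw", 2))
  n_planes <- raw_to_uint(readBin(con, "raw", 4))
  frame_rate <- readBin(con, "double", 1, size = 8, endian = "little")
  readBin(con, "raw", 4)                         # flags
  meta_len <- raw_to_uint(readBin(con, "raw", 4))
  metadata <- list()
  if (meta_len > 0) {
    meta_raw <- readBin(con, "raw", meta_len)
    if (length(meta_raw) < meta_len)
      stop("truncated metadata at offset 32", call. = FALSE)
    metadata <- jsonlite::fromJSON(rawToChar(meta_raw))
  }
  bytes_per_plane <- ceiling(width * height / 8)
  planes <- array(0L, dim = c(height, width, n_planes))
  offset <- 32 + meta_len
  for (t in seq_len(n_planes)) {
    b <- readBin(con, "raw", bytes_per_plane)
    if (length(b) < bytes_per_plane)
      stop(sprintf("truncated plane %d at offset %.0f", t, offset),
           call. = FALSE)
    planes[, , t] <- matrix(unpack_bits_msb(b, width * height),
                            nrow = height, byrow = TRUE)
    offset <- offset + bytes_per_plane
  }
  bit_plane_stack(planes, frame_rate_Hz = frame_rate, metadata = metadata)
}

#' Export a bit-plane stack as a multipage 8-bit TIFF
#'
#' Interchange path for viewers and other toolchains; binary values are
#' stored as 0/1 in 8-bit pages.
#'
#' @param stack A [bit_plane_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "bit_plane_stack"))
  pages <- lapply(seq_len(stack$n_planes),
                  function(t) stack$planes[, , t] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Import a bit-plane stack from a multipage TIFF
#'
#' Accepts 1-bit or 8-bit pages; any pixel value >= `threshold` (on the
#' 0--1 scale the TIFF reader returns) is taken as a detected photon.
#'
#' @param path Multipage TIFF.
#' @param frame_rate_Hz Acquisition rate to attach (TIFF carries none).
#' @param threshold Binarisation threshold on the 0--1 scale.
#' @return A [bit_plane_stack()].
#' @export
read_stack_tiff <- function(path, frame_rate_Hz, threshold = 0.5 / 255) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  planes <- array(0L, dim = c(h, w, length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    planes[, , t] <- as.integer(pg >= threshold)
  }
  bit_plane_stack(planes, frame_rate_Hz = frame_rate_Hz,
                  metadata = list(source = basename(path)))
}
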