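# Minimal baseline TIFF support: single-channel, 16-bit unsigned,
# uncompressed, little-endian. This is all the scene artifacts need; no
# TIFF package is assumed. Pixel values are stored row-major top-to-bottom,
# matching the usual image convention (origin top-left).

TIFF_TAG <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples = 277L,
  rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L
)

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' Writes an uncompressed, little-endian, single-strip baseline TIFF.
#' Values must already be inside the unsigned 16-bit range; out-of-range
#' data raises a dynamic-range error (the caller must rescale), as quantified
#' intensities must never be silently clipped.
#'
#' @param img Numeric matrix (rows = image rows, origin top-left). Values are
#'   rounded to the nearest integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff16()]
#' @export
write_tiff16 <- function(img, path) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_param("parameter error: `img` must be a numeric matrix")
  }
  v <- round(img)
  if (anyNA(v) || min(v) < 0 || max(v) > 65535) {
    stop_param("dynamic-range error: pixel values outside [0, 65535]; ",
               "rescale before writing 16-bit TIFF")
  }
  h <- nrow(v); w <- ncol(v)
  px <- as.integer(t(v))              # row-major
  px[px > 32767L] <- px[px > 32767L] - 65536L  # reinterpret as signed for writeBin

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  data_offset <- 8L
  n_bytes <- 2L * h * w
  ifd_offset <- data_offset + n_bytes

  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(px, con, size = 2, endian = "little")

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  entries <- list(
    list(TIFF_TAG[["width"]], 4L, 1L, w),
    list(TIFF_TAG[["length"]], 4L, 1L, h),
    list(TIFF_TAG[["bits"]], 3L, 1L, 16L),
    list(TIFF_TAG[["compression"]], 3L, 1L, 1L),
    list(TIFF_TAG[["photometric"]], 3L, 1L, 1L),
    list(TIFF_TAG[["strip_offsets"]], 4L, 1L, data_offset),
    list(TIFF_TAG[["samples"]], 3L, 1L, 1L),
    list(TIFF_TAG[["rows_per_strip"]], 4L, 1L, h),
    list(TIFF_TAG[["strip_bytes"]], 4L, 1L, n_bytes),
    list(TIFF_TAG[["sample_format"]], 3L, 1L, 1L)
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) do.call(entry, e)
  writeBin(0L, con, size = 4, endian = "little")  # no further IFD
  invisible(path)
}

#' Read a 16-bit grayscale TIFF written by this package
#'
#' Supports uncompressed little-endian single-sample 16-bit baseline TIFFs
#' (possibly multi-strip). Returns the image as a numeric matrix with origin
#' top-left.
#'
#' @param path TIFF file path.
#' @return Numeric matrix of pixel values in `[0, 65535]`.
#' @seealso [write_tiff16()]
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) {
    sum(as.integer(raw[off + 1:2]) * c(1L, 256L))
  }
  u32 <- function(off) {
    sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42) {
    stop_param("format error: not a little-endian TIFF file")
  }
  ifd <- u32(4)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
    elt_size <- unname(c(`1` = 1, `3` = 2, `4` = 4)[as.character(type)])
    if (is.na(elt_size)) next
    total <- elt_size * count
    voff <- if (total <= 4) off + 8 else u32(off + 8)
    vals <- vapply(seq_len(count) - 1, function(j) {
      if (elt_size == 1) as.numeric(raw[voff + j + 1])
      else if (elt_size == 2) u16(voff + 2 * j)
      else u32(voff + 4 * j)
    }, numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) {
    v <- tags[[as.character(TIFF_TAG[[tag]])]]
    if (is.null(v)) stop_param("format error: missing TIFF tag `", tag, "`")
    v
  }
  if (need("compression")[1] != 1) stop_param("format error: compressed TIFF unsupported")
  if (need("bits")[1] != 16) stop_param("format error: only 16-bit TIFF supported")
  w <- need("width")[1]; h <- need("length")[1]
  offsets <- need("strip_offsets"); nbytes <- need("strip_bytes")
  px <- numeric(0)
  for (s in seq_along(offsets)) {
    n <- nbytes[s] / 2
    seg <- raw[offsets[s] + seq_len(2 * n)]
    idx <- seq(1, 2 * n, by = 2)
    px <- c(px, as.numeric(seg[idx]) + 256 * as.numeric(seg[idx + 1]))
  }
  if (length(px) != w * h) stop_param("format error: strip sizes inconsistent with dimensions")
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
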