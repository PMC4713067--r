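# Minimal baseline TIFF 6.0 reader/writer: little-endian, uncompressed,
# single strip per page, one grayscale sample per pixel, IEEE float samples
# (SampleFormat 3, 32- or 64-bit). This subset is what the pipeline needs to
# exchange image stacks; no TIFF package exists in the installed R stack.
# Files written here are readable by standard readers (e.g. Python tifffile).

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, PhotometricInterpretation = 262L,
  StripOffsets = 273L, RowsPerStrip = 278L, StripByteCounts = 279L,
  SampleFormat = 339L
)

#' Write a multi-page grayscale TIFF
#'
#' Pages are numeric matrices written as IEEE-float samples, so intensities
#' round-trip without quantization (`bits = 64`, the default) or with float32
#' precision (`bits = 32`).
#'
#' @param pages list of numeric matrices, all of the same dimension.
#' @param path output file path.
#' @param bits 32 or 64, bits per (float) sample.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits = 64L) {
  stopifnot(is.list(pages), length(pages) > 0, bits %in% c(32L, 64L))
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("all pages must share the same dimensions")
  nr <- nrow(pages[[1L]]); nc <- ncol(pages[[1L]])
  bytes_px <- bits / 8L
  strip_bytes <- nr * nc * bytes_px
  n <- length(pages)

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  # Layout: 8-byte header, then per page [pixel strip][IFD].
  header_len <- 8
  ifd_len <- 2 + 9 * 12 + 4                     # 9 tags
  page_block <- strip_bytes + ifd_len

  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42)
  w4(header_len + strip_bytes)                  # offset of first IFD

  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_len(n)) {
    strip_off <- header_len + (i - 1) * page_block
    ifd_off <- strip_off + strip_bytes
    next_ifd <- if (i < n) header_len + i * page_block + strip_bytes else 0L
    # strip: row-major pixel data
    writeBin(as.numeric(t(pages[[i]])), con, size = bytes_px, endian = "little")
    w2(9L)                                      # entry count
    entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, nc)
    entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["PhotometricInterpretation"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L, strip_off)
    entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, strip_bytes)
    entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, 3L)
    w4(next_ifd)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports the baseline subset used by this package: little-endian,
#' uncompressed, one float sample per pixel, one strip per page.
#'
#' @param path TIFF file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  u2 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u4 <- function(off) sum(as.integer(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II" || u2(2) != 42L)
    stop("not a little-endian TIFF file: ", path)

  pages <- list()
  ifd_off <- u4(4)
  while (ifd_off != 0) {
    n_entries <- u2(ifd_off)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- u2(base); type <- u2(base + 2)
      val <- if (type == 3L) u2(base + 8) else u4(base + 8)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) stop("TIFF page missing required tag ", tag)
      v
    }
    if (need("Compression") != 1L) stop("only uncompressed TIFF is supported")
    if (!is.null(tags[["339"]]) && tags[["339"]] != 3L)
      stop("only float SampleFormat is supported")
    nc <- need("ImageWidth"); nr <- need("ImageLength")
    bits <- need("BitsPerSample")
    if (!bits %in% c(32L, 64L)) stop("unsupported BitsPerSample: ", bits)
    off <- need("StripOffsets")
    vals <- readBin(raw_all[(off + 1):(off + nr * nc * bits / 8)],
                    "numeric", n = nr * nc, size = bits / 8, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    ifd_off <- u4(ifd_off + 2 + n_entries * 12)
  }
  pages
}
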