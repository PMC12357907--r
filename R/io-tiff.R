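# Minimal baseline TIFF codec (little-endian, uncompressed, greyscale,
# 8- or 16-bit, multi-page). No R TIFF bindings ship with this toolchain, so
# the subset of the format the pipeline needs is implemented here directly.
# Matrices are row/col indexed; TIFF stores row-major scanlines.

tif_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
tif_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

tif_entry <- function(tag, type, count, value_raw) {
  # value_raw must already be padded to 4 bytes (inline value) or be an
  # offset encoded with tif_u32
  c(tif_u16(tag), tif_u16(type), tif_u32(count), value_raw)
}

#' Write greyscale images as a multi-page TIFF
#'
#' Writes one TIFF page per matrix: baseline, uncompressed, little-endian,
#' single strip, 8-bit (default) or 16-bit unsigned grey.
#'
#' @param pages a matrix or list of numeric matrices; values are rounded and
#'   clamped to the range of `bits`.
#' @param path output file path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits = 8) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(bits %in% c(8L, 16L), length(pages) >= 1)
  maxv <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), tif_u16(42L)), con)
  n_entries <- 8L
  ifd_len <- 2L + n_entries * 12L + 4L
  # first pass: encode pixel data and lay out offsets; each page stores its
  # (word-aligned) strip first, followed by its IFD
  datas <- vector("list", length(pages))
  data_offs <- ifd_offs <- integer(length(pages))
  offset <- 8L
  for (k in seq_along(pages)) {
    v <- pmin(pmax(round(pages[[k]]), 0), maxv)
    vals <- as.integer(t(v))                       # row-major scanlines
    data <- if (bits == 8L) as.raw(vals) else
      writeBin(vals, raw(), size = 2, endian = "little")
    if (length(data) %% 2 == 1) data <- c(data, as.raw(0))
    datas[[k]] <- data
    data_offs[k] <- offset
    ifd_offs[k] <- offset + length(data)
    offset <- ifd_offs[k] + ifd_len
  }
  writeBin(tif_u32(ifd_offs[1]), con)
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    nbytes <- length(as.integer(t(m))) * (bits %/% 8L)
    entries <- c(
      tif_entry(256L, 4L, 1L, tif_u32(ncol(m))),       # ImageWidth
      tif_entry(257L, 4L, 1L, tif_u32(nrow(m))),       # ImageLength
      tif_entry(258L, 3L, 1L, c(tif_u16(bits), tif_u16(0L))),  # BitsPerSample
      tif_entry(259L, 3L, 1L, c(tif_u16(1L), tif_u16(0L))),    # Compression
      tif_entry(262L, 3L, 1L, c(tif_u16(1L), tif_u16(0L))),    # BlackIsZero
      tif_entry(273L, 4L, 1L, tif_u32(data_offs[k])),  # StripOffsets
      tif_entry(278L, 4L, 1L, tif_u32(nrow(m))),       # RowsPerStrip
      tif_entry(279L, 4L, 1L, tif_u32(nbytes))         # StripByteCounts
    )
    next_off <- if (k < length(pages)) ifd_offs[k + 1] else 0L
    writeBin(c(datas[[k]], tif_u16(n_entries), entries, tif_u32(next_off)),
             con)
  }
  invisible(path)
}

rd_u16 <- function(raw, off) {  # off is 0-based
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
rd_u32 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256 * as.integer(raw[off + 2]) +
    65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
}

tif_tag_values <- function(raw, entry_off) {
  type <- rd_u16(raw, entry_off + 2)
  count <- rd_u32(raw, entry_off + 4)
  size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
  if (is.na(size)) return(NULL)
  total <- size * count
  voff <- if (total <= 4) entry_off + 8 else rd_u32(raw, entry_off + 8)
  vapply(seq_len(count) - 1L, function(k) {
    if (size == 1L) as.numeric(raw[voff + k + 1])
    else if (size == 2L) as.numeric(rd_u16(raw, voff + 2 * k))
    else as.numeric(rd_u32(raw, voff + 4 * k))
  }, numeric(1))
}

#' Read a greyscale multi-page TIFF
#'
#' Supports the baseline subset written by [write_tiff()]: little-endian,
#' uncompressed, single-sample greyscale, 8- or 16-bit, one or more strips.
#'
#' @param path file path.
#' @return a list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || rd_u16(raw, 2) != 42L)
    stop("not a little-endian baseline TIFF: ", path, call. = FALSE)
  ifd_off <- rd_u32(raw, 4)
  pages <- list()
  while (ifd_off != 0) {
    n <- rd_u16(raw, ifd_off)
    tags <- list()
    for (e in seq_len(n) - 1L) {
      off <- ifd_off + 2 + 12 * e
      tag <- rd_u16(raw, off)
      tags[[as.character(tag)]] <- tif_tag_values(raw, off)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags)))
      stop("TIFF page missing required tags", call. = FALSE)
    comp <- if (!is.null(tags[["259"]])) tags[["259"]][1] else 1
    if (comp != 1) stop("only uncompressed TIFF supported", call. = FALSE)
    bits <- if (!is.null(tags[["258"]])) tags[["258"]][1] else 8
    if (!bits %in% c(8, 16))
      stop("only 8/16-bit greyscale TIFF supported", call. = FALSE)
    nc <- tags[["256"]][1]; nr <- tags[["257"]][1]
    offs <- tags[["273"]]; counts <- tags[["279"]]
    data <- raw(0)
    for (s in seq_along(offs))
      data <- c(data, raw[(offs[s] + 1):(offs[s] + counts[s])])
    vals <- if (bits == 8) as.integer(data) else {
      idx <- seq(1, length(data), by = 2)
      as.integer(data[idx]) + 256L * as.integer(data[idx + 1])
    }
    pages[[length(pages) + 1]] <- matrix(vals, nrow = nr, ncol = nc,
                                         byrow = TRUE)
    ifd_off <- rd_u32(raw, ifd_off + 2 + 12 * n)
  }
  pages
}
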