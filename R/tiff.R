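# Minimal baseline TIFF I/O (uncompressed, little-endian, grayscale).
#
# The pipeline only needs to round-trip its own single-channel stacks, so
# the writer emits one 32-bit IEEE float strip per page and stores the
# stack metadata (timestamps, channel, z flag) as JSON in the first page's
# ImageDescription tag. The reader additionally accepts 8/16/32-bit
# unsigned integer pages so externally produced uncompressed grayscale
# TIFFs (e.g. ImageJ exports) can be measured.

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, description = 270L, strip_offsets = 273L,
                 samples = 277L, rows_per_strip = 278L,
                 strip_bytes = 279L, sample_format = 339L)

#' Write an image stack as a multi-page TIFF
#'
#' Writes one uncompressed 32-bit float grayscale page per frame
#' (little-endian baseline TIFF). Timestamps, channel label and the z flag
#' are stored as JSON in the ImageDescription tag so [read_tiff()]
#' round-trips the stack exactly (up to float32 precision of intensities).
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  h <- dim(stack$frames[[1]])[1]; w <- dim(stack$frames[[1]])[2]
  n <- length(stack$frames)
  desc <- jsonlite::toJSON(list(timestamps = stack$timestamps,
                                channel = stack$channel, z = stack$z),
                           auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  data_bytes <- as.integer(h) * as.integer(w) * 4L
  n_entries <- function(p) if (p == 1L) 11L else 10L
  ifd_size <- function(p) 2L + 12L * n_entries(p) + 4L

  # layout: header(8) | description | page1 data | page1 IFD | page2 data | ...
  desc_off <- 8L
  off <- desc_off + length(desc_raw)
  data_off <- integer(n); ifd_off <- integer(n)
  for (p in seq_len(n)) {
    data_off[p] <- off; off <- off + data_bytes
    ifd_off[p] <- off; off <- off + ifd_size(p)
  }

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  writeBin(desc_raw, con)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {            # SHORT inline, pad to 4
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {                                    # LONG (or offset)
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (p in seq_len(n)) {
    writeBin(writeBin(as.numeric(t(stack$frames[[p]])), raw(),
                      size = 4, endian = "little"), con)
    writeBin(n_entries(p), con, size = 2, endian = "little")
    entry(TIFF_TAG$width, 4L, 1L, w)
    entry(TIFF_TAG$length, 4L, 1L, h)
    entry(TIFF_TAG$bits, 3L, 1L, 32L)
    entry(TIFF_TAG$compression, 3L, 1L, 1L)
    entry(TIFF_TAG$photometric, 3L, 1L, 1L)
    if (p == 1L) entry(TIFF_TAG$description, 2L, length(desc_raw), desc_off)
    entry(TIFF_TAG$strip_offsets, 4L, 1L, data_off[p])
    entry(TIFF_TAG$samples, 3L, 1L, 1L)
    entry(TIFF_TAG$rows_per_strip, 4L, 1L, h)
    entry(TIFF_TAG$strip_bytes, 4L, 1L, data_bytes)
    entry(TIFF_TAG$sample_format, 3L, 1L, 3L)
    writeBin(if (p < n) ifd_off[p + 1] else 0L, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Reads uncompressed little-endian grayscale TIFFs: 32-bit float pages (as
#' written by [write_tiff()]) and 8/16/32-bit unsigned integer pages.
#' Timestamps and channel are recovered from the JSON ImageDescription when
#' present; otherwise frames are numbered 0, 1, 2, ... seconds.
#'
#' @param path TIFF file path.
#' @return an [image_stack()].
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.double(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II")
    stopf("only little-endian TIFF is supported")
  if (u16(2) != 42L) stopf("not a TIFF file")

  frames <- list(); desc <- NULL
  ifd <- u32(4)
  while (ifd != 0) {
    n_ent <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_ent)) {
      o <- ifd + 2 + 12 * (e - 1)
      tag <- u16(o); type <- u16(o + 2); count <- u32(o + 4)
      size <- c(1, 1, 2, 4, 8)[type]
      if (is.na(size)) next
      nbytes <- size * count
      voff <- if (nbytes <= 4) o + 8 else u32(o + 8)
      vals <- switch(as.character(type),
        "3" = vapply(seq_len(count), function(i) u16(voff + 2 * (i - 1)), 0),
        "4" = vapply(seq_len(count), function(i) u32(voff + 4 * (i - 1)), 0),
        "2" = rawToChar(raw_all[voff + seq_len(max(count - 1, 0))]),
        "1" = as.double(raw_all[voff + seq_len(count)]),
        NULL)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    if (!identical(g(TIFF_TAG$compression, 1), 1))
      stopf("compressed TIFF is not supported")
    if (!identical(g(TIFF_TAG$samples, 1), 1))
      stopf("only single-sample (grayscale) TIFF is supported")
    w <- g(TIFF_TAG$width); h <- g(TIFF_TAG$length)
    bits <- g(TIFF_TAG$bits, 1)[1]
    fmt <- g(TIFF_TAG$sample_format, 1)[1]
    if (is.null(desc)) desc <- g(TIFF_TAG$description)
    offs <- g(TIFF_TAG$strip_offsets)
    cnts <- g(TIFF_TAG$strip_bytes)
    buf <- raw(0)
    for (s in seq_along(offs)) buf <- c(buf, raw_all[offs[s] + seq_len(cnts[s])])
    px <- if (fmt == 3 && bits == 32) {
      readBin(buf, "double", n = w * h, size = 4, endian = "little")
    } else if (fmt %in% c(1, 4) && bits %in% c(8, 16, 32)) {
      readBin(buf, "integer", n = w * h, size = bits / 8,
              signed = bits > 16, endian = "little")
    } else stopf("unsupported TIFF pixel format (bits=%d, format=%d)", bits, fmt)
    frames[[length(frames) + 1L]] <- matrix(as.numeric(px), nrow = h,
                                            ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2 + 12 * n_ent)
  }

  meta <- if (!is.null(desc) && grepl("^\\s*\\{", desc))
    tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL) else NULL
  ts <- if (!is.null(meta$timestamps) && length(meta$timestamps) == length(frames))
    meta$timestamps else seq_along(frames) - 1
  image_stack(frames, ts,
              channel = if (!is.null(meta$channel)) meta$channel else "unknown",
              z = isTRUE(meta$z))
}
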