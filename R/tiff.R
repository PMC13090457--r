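# Minimal multi-page TIFF stack reader (read-only, uncompressed, grayscale).
# TIFF carries no trustworthy 3D spacing, so callers must supply spacing_mm.
# Supports both byte orders, 8/16-bit unsigned integer and 32-bit float
# samples, strip-organized data. Anything fancier (compression, tiles,
# multi-sample pixels) is rejected with a clear error.

TIFF_TAG <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
              strip_offsets = 273L, samples = 277L, rows_per_strip = 278L,
              strip_counts = 279L, sample_format = 339L)

read_tiff_stack <- function(path, spacing_mm, origin_mm = c(0, 0, 0)) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  rd <- function(offset, what, n, size, signed = TRUE)
    readBin(raw_all[(offset + 1):(offset + n * size)], what, n, size = size,
            signed = signed, endian = endian)
  if (rd(2, "integer", 1, 2) != 42L) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifd_offset <- rd(4, "integer", 1, 4)
  while (ifd_offset != 0) {
    n_entries <- rd(ifd_offset, "integer", 1, 2, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_offset + 2 + (e - 1) * 12
      tag <- rd(base, "integer", 1, 2, signed = FALSE)
      type <- rd(base + 2, "integer", 1, 2, signed = FALSE)
      count <- rd(base + 4, "integer", 1, 4)
      type_size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
      if (is.na(type_size)) next  # skip rationals/strings we don't need
      total <- type_size * count
      val_off <- if (total <= 4) base + 8 else rd(base + 8, "integer", 1, 4)
      vals <- rd(val_off, "integer", count, type_size,
                 signed = (type_size == 4L))
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(TIFF_TAG[[id]])]]
      if (is.null(v)) default else v
    }
    width <- g("width"); height <- g("height")
    if (is.null(width) || is.null(height))
      stop("TIFF page missing width/height: ", path)
    if (!identical(g("compression", 1L)[1], 1L))
      stop("only uncompressed TIFF is supported: ", path)
    if (!identical(g("samples", 1L)[1], 1L))
      stop("only single-sample (grayscale) TIFF is supported: ", path)
    bits <- g("bits", 8L)[1]
    fmt <- g("sample_format", 1L)[1]
    offsets <- g("strip_offsets")
    counts <- g("strip_counts", as.integer(width * height * bits / 8))
    if (is.null(offsets)) stop("TIFF page missing strip offsets: ", path)
    bytes <- unlist(lapply(seq_along(offsets), function(i)
      raw_all[(offsets[i] + 1):(offsets[i] + counts[i])]))
    n_px <- as.integer(width) * as.integer(height)
    px <- if (bits == 8L && fmt == 1L) {
      readBin(bytes, "integer", n_px, size = 1, signed = FALSE)
    } else if (bits == 16L && fmt == 1L) {
      readBin(bytes, "integer", n_px, size = 2, signed = FALSE, endian = endian)
    } else if (bits == 32L && fmt == 3L) {
      readBin(bytes, "double", n_px, size = 4, endian = endian)
    } else {
      stop(sprintf("unsupported TIFF sample layout (%d bits, format %d): %s",
                   bits, fmt, path))
    }
    # rows are stored top-to-bottom, pixels left-to-right: x fastest
    pages[[length(pages) + 1L]] <- matrix(as.numeric(px), nrow = width)
    ifd_offset <- rd(ifd_offset + 2 + 12 * n_entries, "integer", 1, 4)
  }
  if (!length(pages)) stop("TIFF file contains no pages: ", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have inconsistent dimensions: ", path)
  vol <- array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages)))
  volume3d(vol, spacing_mm = spacing_mm, origin_mm = origin_mm)
}
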