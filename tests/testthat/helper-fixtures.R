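# Minimal multi-page TIFF writer used only to build test fixtures for the
# package's TIFF reader (little-endian, uncompressed, one strip per page).
write_test_tiff <- function(vol, path, bits = 8L) {
  dims <- dim(vol)
  w <- dims[1]; h <- dims[2]; npages <- dims[3]
  con <- file(path, "wb")
  on.exit(close(con))
  i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL); i16(42L)

  bytes_pp <- bits / 8L
  strip_bytes <- w * h * bytes_pp
  n_entries <- 9L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  entry <- function(tag, type, count, value) {
    i16(tag); i16(type); i32(count); i32(value)
  }
  # layout: [8-byte header][page1 data][page1 IFD][page2 data][page2 IFD]...
  data_offs <- 8L + (seq_len(npages) - 1L) * (strip_bytes + ifd_bytes)
  ifd_offs <- data_offs + strip_bytes
  i32(ifd_offs[1])   # offset of first IFD
  for (p in seq_len(npages)) {
    page <- vol[, , p]
    if (bits == 8L) {
      writeBin(as.integer(page), con, size = 1)
    } else if (bits == 32L) {
      writeBin(as.numeric(page), con, size = 4, endian = "little")
    } else stop("helper supports 8- or 32-bit only")
    i16(n_entries)
    entry(256L, 4L, 1L, w)                       # ImageWidth
    entry(257L, 4L, 1L, h)                       # ImageLength
    entry(258L, 3L, 1L, bits)                    # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_offs[p])            # StripOffsets
    entry(278L, 4L, 1L, h)                       # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, if (bits == 32L) 3L else 1L)  # SampleFormat
    i32(if (p < npages) ifd_offs[p + 1] else 0L) # next IFD
  }
  invisible(path)
}

# A small phantom world shared by several tests: ~1.4 ml kidney at 0.1 mm
# spacing (min semi-axis ~59 px, so 50-px shells are meaningful) with the
# default regime parameters untouched.
small_phantom_spec <- function(volume_ml = 1.4) {
  aspect <- c(66.4, 50, 45)
  half <- aspect / 2
  s <- (volume_ml * 1000 * 3 / (4 * pi) / prod(half))^(1 / 3)
  phantom_spec(semi_axes_mm = half * s)
}

# Scaled-down study world for simulation tests: same pixel-denominated
# regime and depth defaults, kidneys ~1/4 linear scale and near-spherical
# (a compact shape minimizes the voxel count needed to keep 50-px shells
# meaningful; ellipsoid eccentricity is exercised elsewhere).
scaled_study_config <- function(...) {
  study_config(kidney_volume_ml_range = c(0.8, 1.0),
               aspect = c(1.05, 1.0, 0.95), depths_px = 50L, ...)
}
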