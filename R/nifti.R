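# Minimal NIfTI-1 reader/writer. Only the features this pipeline needs:
# single-file .nii / .nii.gz, axis-aligned grids, isotropic spacing,
# datatypes uint8 / int16 / int32 / float32 / float64 / uint16.
# No installed R package in this stack reads NIfTI, hence the hand-rolled
# implementation; the format is a fixed 348-byte header plus raw voxels.

NIFTI_DT_UINT8   <- 2L
NIFTI_DT_INT16   <- 4L
NIFTI_DT_INT32   <- 8L
NIFTI_DT_FLOAT32 <- 16L
NIFTI_DT_FLOAT64 <- 64L
NIFTI_DT_UINT16  <- 512L

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

write_nifti <- function(obj, path) {
  stopifnot(is_grid_object(obj))
  is_mask <- inherits(obj, "binary_mask")
  d <- dim(obj$data)
  sp <- obj$spacing_mm
  org <- obj$origin_mm
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(10 + 18)                    # data_type, db_name (unused)
  w_i32(0L); w_i16(0L); w_raw(2)    # extents, session_error, regular, dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))   # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)      # intent_p1..3, intent_code
  w_i16(if (is_mask) NIFTI_DT_UINT8 else NIFTI_DT_FLOAT32)  # datatype
  w_i16(if (is_mask) 8L else 32L)   # bitpix
  w_i16(0L)                         # slice_start
  w_f32(c(1, sp, sp, sp, 0, 0, 0, 0))  # pixdim[8]
  w_f32(352)                        # vox_offset
  w_f32(c(1, 0))                    # scl_slope, scl_inter
  w_i16(0L); w_raw(1)               # slice_end, slice_code
  writeBin(as.raw(2L), con)         # xyzt_units: NIFTI_UNITS_MM
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(80 + 24)                    # descrip, aux_file
  w_i16(c(0L, 1L))                  # qform_code, sform_code
  w_f32(c(0, 0, 0))                 # quatern_b, c, d
  w_f32(org)                        # qoffset_x, y, z
  w_f32(c(sp, 0, 0, org[1],  0, sp, 0, org[2],  0, 0, sp, org[3]))  # srow
  w_raw(16)                         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4)                          # no header extensions

  if (is_mask) {
    writeBin(as.integer(obj$data), con, size = 1)
  } else {
    w_f32(obj$data)
  }
  invisible(NULL)
}

read_nifti <- function(path, spacing_mm = NULL) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    sz_big <- .swap_int32(sz)
    if (sz_big != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    endian <- "big"
  }
  r_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = endian)
  r_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = endian)
  r_f32 <- function(n) readBin(con, "double", n, size = 4, endian = endian)
  skip <- function(n) invisible(readBin(con, "raw", n))

  skip(10 + 18 + 4 + 2 + 1 + 1)
  dims <- r_i16(8)
  ndim <- dims[1]
  d <- dims[2:4]
  if (ndim < 3L) d[seq.int(ndim + 1L, 3L)] <- 1L
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L))
    stop("only 3D NIfTI volumes are supported: ", path)
  skip(12 + 2)                        # intent_p*, intent_code
  datatype <- r_i16(1)
  skip(2 + 2)                         # bitpix, slice_start
  pixdim <- r_f32(8)
  vox_offset <- r_f32(1)
  scl <- r_f32(2)
  skip(2 + 1 + 1 + 16)                # slice_end..toffset
  skip(8 + 80 + 24)                   # glmax/glmin, descrip, aux_file
  qform_code <- r_i16(1)
  sform_code <- r_i16(1)
  skip(12)                            # quaternions
  qoffset <- r_f32(3)
  srow <- r_f32(12)
  skip(16)
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop("unsupported NIfTI variant (expected single-file 'n+1' magic): ", path)

  sp3 <- pixdim[2:4]
  if (is.null(spacing_mm)) {
    if (any(sp3 <= 0)) stop("non-positive voxel spacing in header: ", path)
    if (diff(range(sp3)) > 1e-5 * max(sp3))
      stop(sprintf("anisotropic voxel spacing (%s); the pipeline assumes isotropic voxels",
                   paste(signif(sp3, 6), collapse = " x ")))
    spacing_mm <- signif(sp3[1], 7)   # undo float32 representation error
  }
  origin <- if (sform_code > 0) srow[c(4, 8, 12)]
            else if (qform_code > 0) qoffset else c(0, 0, 0)
  origin <- signif(origin, 7)

  to_skip <- round(vox_offset) - 348L   # header bytes consumed so far
  if (to_skip > 0) skip(to_skip)
  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2"   = readBin(con, "integer", n, size = 1, signed = FALSE),
    "4"   = readBin(con, "integer", n, size = 2, endian = endian),
    "8"   = readBin(con, "integer", n, size = 4, endian = endian),
    "16"  = readBin(con, "double",  n, size = 4, endian = endian),
    "64"  = readBin(con, "double",  n, size = 8, endian = endian),
    "512" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(vals) != n) stop("truncated NIfTI data: ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  volume3d(array(as.numeric(vals), d), spacing_mm = spacing_mm,
           origin_mm = origin)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, size = 4, endian = "little")
}
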