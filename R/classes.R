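#' 3D intensity volume with isotropic voxel spacing
#'
#' A `volume3d` is the package's container for a microCT image (or a rendered
#' phantom): a 3D numeric array plus an isotropic voxel edge length in mm and
#' a physical origin. The physical position of the center of voxel
#' `(i, j, k)` (1-based) is `origin_mm + (c(i, j, k) - 0.5) * spacing_mm`.
#'
#' @param data 3D numeric array of finite, non-negative intensities.
#' @param spacing_mm isotropic voxel edge length in mm (default 0.1, the
#'   scanner resolution the pipeline is designed around).
#' @param origin_mm physical position (mm) of the corner of voxel (1,1,1).
#' @return An object of class `volume3d` with fields `data`, `spacing_mm`,
#'   `origin_mm`.
#' @seealso [binary_mask()], [read_volume()], [write_volume()]
#' @export
volume3d <- function(data, spacing_mm = 0.1, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  if (length(origin_mm) != 3L || !all(is.finite(origin_mm)))
    stop("`origin_mm` must be a finite 3-vector")
  storage.mode(data) <- "double"
  if (anyNA(data) || !all(is.finite(data)))
    stop("intensities must be finite")
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "volume3d")
}

#' 3D binary mask aligned with a volume
#'
#' Strictly two-valued (logical) grid sharing the shape, spacing and origin
#' of the volumes it is combined with. Used for kidney masks, segmented
#' vessel/particle masks, eroded masks and cortical shells.
#'
#' @param data 3D logical array (numeric 0/1 is coerced; anything else errors).
#' @inheritParams volume3d
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing_mm = 0.1, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask data must be two-valued (0/1 or logical)")
    data <- array(data != 0, dim(data))
  }
  if (!is.logical(data)) stop("mask data must be logical or 0/1 numeric")
  if (anyNA(data)) stop("mask data must not contain NA")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "binary_mask")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %g mm, range [%g, %g]\n",
              d[1], d[2], d[3], x$spacing_mm, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels @ %g mm, %d foreground\n",
              d[1], d[2], d[3], x$spacing_mm, sum(x$data)))
  invisible(x)
}

#' Convert a two-valued volume to a binary mask
#'
#' @param volume a `volume3d` whose intensities are all 0 or 1 (e.g. a mask
#'   read back from disk).
#' @return A `binary_mask` with the same geometry.
#' @export
as_binary_mask <- function(volume) {
  stopifnot(inherits(volume, "volume3d"))
  binary_mask(volume$data, volume$spacing_mm, volume$origin_mm)
}

is_grid_object <- function(x) inherits(x, c("volume3d", "binary_mask"))

# Internal fast-path constructors: skip validation for data the package
# itself produced (validation on multi-million-voxel grids is measurable).
new_volume3d <- function(data, spacing_mm, origin_mm) {
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "volume3d")
}

new_binary_mask <- function(data, spacing_mm, origin_mm) {
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "binary_mask")
}

# Grids from one analysis must agree exactly in shape and spacing; the
# pipeline never resamples, it refuses.
check_same_geometry <- function(a, b, what = "grids") {
  stopifnot(is_grid_object(a), is_grid_object(b))
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s have different shapes (%s vs %s)", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  if (!isTRUE(all.equal(a$spacing_mm, b$spacing_mm, tolerance = 1e-9)))
    stop(sprintf("%s have different voxel spacing (%g vs %g mm); resampling is not supported",
                 what, a$spacing_mm, b$spacing_mm))
  invisible(TRUE)
}

#' Mask volume in millilitres
#'
#' Foreground voxel count times the voxel volume, `spacing_mm^3 / 1000` ml.
#' This is the default kidney-volume normalizer for embolization efficiency.
#'
#' @param mask a `binary_mask`.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * mask$spacing_mm^3 / 1000
}
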