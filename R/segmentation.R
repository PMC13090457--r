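#' Segmentation parameters
#'
#' The pipeline replaces interactive pixel-classifier segmentation with a
#' deterministic rule: global intensity threshold followed by removal of
#' connected components below a minimum size. Radiopaque beads are designed
#' to be high-contrast, so a threshold plus size filter excludes parenchyma
#' reproducibly.
#'
#' @param threshold intensity cutoff; voxels strictly above it are kept.
#' @param min_component_voxels components smaller than this are removed
#'   (default 1, i.e. no size filtering).
#' @param connectivity 6, 18 or 26 (default 26: sub-voxel beads can touch
#'   diagonally after noise, and 26-connectivity avoids splitting one bead
#'   into two counts).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(threshold, min_component_voxels = 1L,
                                connectivity = 26L) {
  if (!is.numeric(threshold) || length(threshold) != 1L)
    stop("`threshold` must be a single number")
  min_component_voxels <- as.integer(min_component_voxels)
  if (min_component_voxels < 1L) stop("`min_component_voxels` must be >= 1")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(threshold = threshold,
                 min_component_voxels = min_component_voxels,
                 connectivity = connectivity),
            class = "segmentation_params")
}

#' Segment embolic particles from an intensity volume
#'
#' Threshold the volume, then drop connected components smaller than
#' `min_component_voxels`. Monotone in the threshold: raising it never adds
#' a foreground voxel.
#'
#' @param volume a [volume3d()].
#' @param params a [segmentation_params()].
#' @return A [binary_mask()] of embolic/vessel voxels.
#' @export
segment_particles <- function(volume, params) {
  stopifnot(inherits(volume, "volume3d"),
            inherits(params, "segmentation_params"))
  fg <- volume$data > params$threshold   # keeps dim
  if (params$min_component_voxels > 1L && any(fg)) {
    lab <- .label_components_cpp(fg, dim(fg), params$connectivity)
    if (lab$count > 0) {
      sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$count)
      small <- which(sizes < params$min_component_voxels)
      if (length(small)) fg[lab$labels %in% small] <- FALSE
    }
  }
  new_binary_mask(fg, volume$spacing_mm, volume$origin_mm)
}

#' Label 3D connected components
#'
#' Standard connected-component labeling under 6- (faces), 18- (faces and
#' edges) or 26- (faces, edges and corners) connectivity. Labels run
#' 1..count; background is 0.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26.
#' @return A list with `labels` (integer array, same shape as the mask) and
#'   `count` (number of components).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  .label_components_cpp(as.logical(mask$data), dim(mask$data), connectivity)
}

#' Default segmentation for a rendered phantom
#'
#' Threshold midway between the phantom's background and particle intensity
#' levels, no size filter, 26-connectivity.
#'
#' @param spec a [phantom_spec()].
#' @return A [segmentation_params()].
#' @export
default_segmentation_params <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  segmentation_params(
    threshold = (spec$background_intensity + spec$particle_intensity) / 2)
}
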