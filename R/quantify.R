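#' Count voxels present in both masks
#'
#' The intersection of a segmented vessel/particle mask with a region mask:
#' with binary volumes, positive voxels of the elementwise AND mark CT
#' presence of embolic in the region.
#'
#' @param vessel_mask,region_mask aligned [binary_mask()] objects.
#' @return Integer voxel count.
#' @export
count_intersection_voxels <- function(vessel_mask, region_mask) {
  check_same_geometry(vessel_mask, region_mask, "masks")
  sum(vessel_mask$data & region_mask$data)
}

#' Embolization efficiency
#'
#' Intersecting voxel count normalized by kidney volume: the number of
#' vessel-mask voxels found in a region divided by the kidney volume in ml,
#' making the CT signal comparable across kidneys of different size.
#'
#' @param intersect_voxels non-negative voxel count.
#' @param kidney_volume_ml kidney volume in ml, > 0.
#' @return Efficiency in voxels per ml.
#' @export
embolization_efficiency <- function(intersect_voxels, kidney_volume_ml) {
  if (kidney_volume_ml <= 0) stop("`kidney_volume_ml` must be positive")
  if (intersect_voxels < 0) stop("`intersect_voxels` must be >= 0")
  intersect_voxels / kidney_volume_ml
}

#' Percent embolized cortex
#'
#' Fraction (in percent) of the cortical shell occupied by embolic voxels:
#' `100 * intersect / shell_voxels`. The shell's own voxel count is the
#' default denominator ("percentage of the embolized cortex" read as a
#' fraction of cortex); a whole-kidney denominator is available in
#' [quantify_kidney()].
#'
#' @param intersect_voxels_in_shell embolic voxels inside the shell.
#' @param shell_voxels shell voxel count, > 0.
#' @return Percent in `[0, 100]`.
#' @export
percent_embolized_cortex <- function(intersect_voxels_in_shell, shell_voxels) {
  if (shell_voxels <= 0) stop("shell is empty; percent undefined")
  if (intersect_voxels_in_shell < 0 || intersect_voxels_in_shell > shell_voxels)
    stop("`intersect_voxels_in_shell` must lie in [0, shell_voxels]")
  100 * intersect_voxels_in_shell / shell_voxels
}

# Rounded voxel centroids of labeled components; rows indexed by label.
component_centroid_voxels <- function(labels, count) {
  if (count == 0L) return(matrix(integer(0), 0, 3))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  coords <- arrayInd(idx, dim(labels))
  sums <- rowsum(coords, lab, reorder = TRUE)
  n_per <- tabulate(lab, nbins = count)
  cent <- round(sums / n_per)
  dims <- dim(labels)
  for (ax in 1:3) cent[, ax] <- pmin(pmax(cent[, ax], 1), dims[ax])
  cent
}

#' Count particles whose centroid lies in a region
#'
#' A "particle" is a connected component of the segmented mask; it is
#' assigned to the region containing its rounded voxel centroid, so the
#' shell/inner split partitions the components of a kidney. Merged beads
#' count as one particle (the counting convention is declared, not inferred
#' from intensity).
#'
#' @param labels integer label array from [label_components()].
#' @param count number of components.
#' @param region_mask a [binary_mask()] aligned with the label grid.
#' @return Integer particle count.
#' @export
count_particles_in_region <- function(labels, count, region_mask) {
  stopifnot(inherits(region_mask, "binary_mask"))
  if (!identical(dim(labels), dim(region_mask$data)))
    stop("label grid and region mask have different shapes")
  if (count == 0L) return(0L)
  cent <- component_centroid_voxels(labels, count)
  sum(region_mask$data[cent])
}

#' Embolic-to-kidney volume ratio
#'
#' Injected embolic volume over kidney parenchymal volume (both ml).
#'
#' @param embolic_ml injected embolic volume (ml), >= 0.
#' @param kidney_ml kidney volume (ml), > 0.
#' @return Dimensionless ratio.
#' @export
embolic_to_kidney_ratio <- function(embolic_ml, kidney_ml) {
  if (kidney_ml <= 0) stop("`kidney_ml` must be positive")
  if (embolic_ml < 0) stop("`embolic_ml` must be >= 0")
  embolic_ml / kidney_ml
}

#' Percent difference relative to a baseline
#'
#' `100 * (a - b) / b`; note the asymmetry (the second argument is the
#' baseline).
#'
#' @param a value to compare.
#' @param b baseline, non-zero.
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  if (b == 0) stop("baseline `b` must be non-zero")
  100 * (a - b) / b
}

#' Sum per-subject particle counts
#'
#' @param per_subject_counts vector of non-negative integer counts.
#' @return Their sum (0 for an empty vector).
#' @export
sum_particle_counts <- function(per_subject_counts) {
  if (length(per_subject_counts) == 0) return(0L)
  if (any(per_subject_counts < 0)) stop("counts must be non-negative")
  as.integer(round(sum(per_subject_counts)))
}

#' Quantify one kidney
#'
#' Full per-kidney quantification: for each stratification depth, the
#' embolic-voxel intersection with the cortical shell, the shell size, the
#' particle (component-centroid) count in the shell, the volume-normalized
#' embolization efficiency and the percent embolized cortex; plus the total
#' particle count and kidney volume.
#'
#' @param vessel_mask segmented embolic [binary_mask()].
#' @param kidney_mask whole-kidney [binary_mask()].
#' @param depths_px stratification depths (pixels), default `c(50, 100)`.
#' @param kidney_volume_source `"mask"` (voxel count x voxel volume, the
#'   default) or `"ellipsoid"` (ultrasound-style estimate from
#'   `ellipsoid_axes_mm`).
#' @param ellipsoid_axes_mm full axis lengths (mm) when
#'   `kidney_volume_source = "ellipsoid"`.
#' @param embolic_ml injected embolic volume (ml), `NA` if unknown.
#' @param connectivity component connectivity for particle counting.
#' @param cortex_denominator `"shell"` (default) or `"whole"`: denominator
#'   of percent embolized cortex.
#' @param kidney_id free-form identifier carried into the output.
#' @param dist optional precomputed [surface_distance_field()] of the
#'   kidney mask.
#' @return A `kidney_quantification`: list with `kidney_id`,
#'   `kidney_volume_ml`, `embolic_ml`, `total_particles`, and `per_depth`
#'   (data.frame with one row per depth).
#' @export
quantify_kidney <- function(vessel_mask, kidney_mask,
                            depths_px = c(50L, 100L),
                            kidney_volume_source = c("mask", "ellipsoid"),
                            ellipsoid_axes_mm = NULL,
                            embolic_ml = NA_real_,
                            connectivity = 26L,
                            cortex_denominator = c("shell", "whole"),
                            kidney_id = "",
                            dist = NULL) {
  check_same_geometry(vessel_mask, kidney_mask, "vessel and kidney masks")
  kidney_volume_source <- match.arg(kidney_volume_source)
  cortex_denominator <- match.arg(cortex_denominator)
  kidney_volume_ml <- if (kidney_volume_source == "mask") {
    mask_volume_ml(kidney_mask)
  } else {
    if (is.null(ellipsoid_axes_mm) || length(ellipsoid_axes_mm) != 3L)
      stop("`ellipsoid_axes_mm` (three full axis lengths) is required for the ellipsoid volume source")
    ellipsoid_volume_ml(ellipsoid_axes_mm[1], ellipsoid_axes_mm[2],
                        ellipsoid_axes_mm[3])
  }
  lab <- label_components(vessel_mask, connectivity)
  depths_px <- as.integer(depths_px)
  if (is.unsorted(depths_px, strictly = TRUE) || any(depths_px <= 0))
    stop("`depths_px` must be strictly increasing positive integers")
  if (is.null(dist)) dist <- surface_distance_field(kidney_mask)
  # fused one-pass tally; identical to stratify + count_intersection_voxels
  # (the dual-route equivalence is asserted in the test suite)
  stats <- .region_stats_cpp(vessel_mask$data, kidney_mask$data, dist,
                             as.numeric(depths_px))
  whole_voxels <- stats$kidney_voxels
  cent <- component_centroid_voxels(lab$labels, lab$count)
  cent_depth <- if (nrow(cent)) dist[cent] else numeric(0)
  per_depth <- do.call(rbind, lapply(seq_along(depths_px), function(i) {
    iv <- stats$intersect_voxels[i]
    sv <- stats$shell_voxels[i]
    denom <- if (cortex_denominator == "shell") sv else whole_voxels
    data.frame(
      depth_px = depths_px[i],
      intersect_voxels = as.integer(iv),
      shell_voxels = as.integer(sv),
      particle_count = sum(cent_depth > 0 & cent_depth <= depths_px[i]),
      efficiency_per_ml = embolization_efficiency(iv, kidney_volume_ml),
      percent_embolized_cortex = if (denom > 0) 100 * iv / denom else NA_real_)
  }))
  structure(list(kidney_id = kidney_id,
                 kidney_volume_ml = kidney_volume_ml,
                 embolic_ml = embolic_ml,
                 total_particles = lab$count,
                 per_depth = per_depth),
            class = "kidney_quantification")
}
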