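#' Read a volumetric image
#'
#' Reads a 3D scalar volume from NIfTI-1 (`.nii` / `.nii.gz`, the canonical
#' format) or a multi-page TIFF stack (read-only). NIfTI spacing comes from
#' the header and must be isotropic; TIFF carries no reliable 3D spacing, so
#' `spacing_mm` is mandatory for TIFF input.
#'
#' @param path file to read.
#' @param format `"nifti"`, `"tiff"`, or `NULL` to infer from the extension.
#' @param spacing_mm voxel spacing override in mm; required for TIFF,
#'   optional for NIfTI (header value used when `NULL`).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, format = NULL, spacing_mm = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff"
              else "nifti"
  }
  format <- match.arg(format, c("nifti", "tiff"))
  if (format == "tiff") {
    if (is.null(spacing_mm))
      stop("TIFF stacks carry no 3D spacing metadata; supply `spacing_mm` explicitly")
    read_tiff_stack(path, spacing_mm = spacing_mm)
  } else {
    read_nifti(path, spacing_mm = spacing_mm)
  }
}

#' Read a binary mask
#'
#' Convenience wrapper: [read_volume()] followed by [as_binary_mask()].
#' Errors if the stored values are not strictly two-valued.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, format = NULL, spacing_mm = NULL) {
  as_binary_mask(read_volume(path, format = format, spacing_mm = spacing_mm))
}

#' Write a volume or mask to NIfTI
#'
#' Masks are stored as uint8, volumes as float32 (lossless for masks and for
#' integer-valued volumes up to 2^24). Paths ending in `.gz` are gzip
#' compressed. TIFF output is intentionally unsupported.
#'
#' @param obj a [volume3d()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param format only `"nifti"` is accepted.
#' @export
write_volume <- function(obj, path, format = "nifti") {
  format <- match.arg(format, "nifti")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  write_nifti(obj, path)
  invisible(path)
}

#' Write study results to CSV and JSON
#'
#' Writes the per-kidney, per-depth quantification table as CSV (one row per
#' subject x kidney x depth) and the group summaries plus paired-test
#' results as JSON.
#'
#' @param study a `paired_study_result` from [run_study()].
#' @param csv_path output CSV path, or `NULL` to skip.
#' @param json_path output JSON path, or `NULL` to skip.
#' @return Invisibly, a list with the written paths.
#' @export
write_results <- function(study, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(study, "paired_study_result"))
  if (!is.null(csv_path)) {
    utils::write.csv(study$quant, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(study_summary_list(study), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}

# JSON-friendly view of the summaries and tests of a paired study.
study_summary_list <- function(study) {
  tests <- lapply(study$tests, function(tl)
    lapply(tl, function(t) list(statistic = t$statistic,
                                p_two_sided = t$p_two_sided,
                                method = t$method,
                                n_effective = t$n_effective)))
  list(n_subjects = study$config$n_subjects,
       depths_px = study$config$depths_px,
       summary = study$summary,
       tests = tests)
}
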