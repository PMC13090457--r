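#' Write particle ground truth as CSV
#'
#' One row per particle: `center_x_mm`, `center_y_mm`, `center_z_mm`,
#' `radius_um`, `depth_px` (realized voxel depth) and `depth_drawn_px`
#' (the depth drawn from the regime distribution before binning).
#'
#' @param particles a `particle_set` from [sample_particles()].
#' @param path output CSV path.
#' @export
write_particles <- function(particles, path) {
  cols <- c("center_x_mm", "center_y_mm", "center_z_mm", "radius_um",
            "depth_px", "depth_drawn_px")
  utils::write.csv(particles[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration from a flat key=value file
#'
#' Lines of the form `key = value`; `#` starts a comment; comma-separated
#' values for vectors. Unknown keys error. Recognized keys (all optional,
#' defaults as in [study_config()] and [regime_spec()]):
#' `n_subjects`, `depths_px`, `spacing_mm`, `kidney_volume_ml_range`,
#' `kidney_jitter`, `aspect`, `noise_sigma`, `background_intensity`,
#' `particle_intensity`, `cortex_denominator`, and per-regime
#' `continuous_depth_scale_px`, `continuous_particle_count_mean`,
#' `continuous_embolic_ml_range` (plus the `pulsed_` equivalents).
#'
#' @param path config file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  num <- function(v) as.numeric(trimws(strsplit(v, ",", fixed = TRUE)[[1]]))
  get1 <- function(key, default) {
    i <- match(key, keys)
    if (is.na(i)) default else num(vals[i])
  }
  known <- c("n_subjects", "depths_px", "spacing_mm",
             "kidney_volume_ml_range", "kidney_jitter", "aspect",
             "noise_sigma", "background_intensity", "particle_intensity",
             "cortex_denominator",
             paste0(rep(c("continuous_", "pulsed_"), each = 3),
                    c("depth_scale_px", "particle_count_mean",
                      "embolic_ml_range")))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  regime_from <- function(name) {
    p <- paste0(name, "_")
    regime_spec(name,
                depth_scale_px = get1(paste0(p, "depth_scale_px"), NULL),
                particle_count_mean = get1(paste0(p, "particle_count_mean"), NULL),
                embolic_ml_range = get1(paste0(p, "embolic_ml_range"), NULL))
  }
  cd <- if ("cortex_denominator" %in% keys)
          vals[match("cortex_denominator", keys)] else "shell"
  study_config(
    n_subjects = get1("n_subjects", 7),
    depths_px = get1("depths_px", c(50, 100)),
    continuous = regime_from("continuous"),
    pulsed = regime_from("pulsed"),
    kidney_volume_ml_range = get1("kidney_volume_ml_range", c(46, 138)),
    kidney_jitter = get1("kidney_jitter", 0.1),
    aspect = get1("aspect", c(66.4, 50, 45)),
    spacing_mm = get1("spacing_mm", 0.1),
    noise_sigma = get1("noise_sigma", 30),
    background_intensity = get1("background_intensity", 100),
    particle_intensity = get1("particle_intensity", 400),
    cortex_denominator = cd)
}
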