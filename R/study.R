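#' Left/right regime assignment
#'
#' Alternating side assignment: in odd-numbered subjects (1-based) the left
#' kidney gets the pulsed technique and the right the continuous technique;
#' in even-numbered subjects the sides are swapped.
#'
#' @param n_subjects number of subjects, >= 1.
#' @return data.frame with columns `subject`, `left_regime`, `right_regime`.
#' @export
assign_sides <- function(n_subjects) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1")
  odd <- seq_len(n_subjects) %% 2L == 1L
  data.frame(subject = seq_len(n_subjects),
             left_regime = ifelse(odd, "pulsed", "continuous"),
             right_regime = ifelse(odd, "continuous", "pulsed"),
             stringsAsFactors = FALSE)
}

#' Paired phantom study configuration
#'
#' The stated world of the synthetic study: 7 subjects, two kidneys each,
#' one per technique with alternating side assignment; kidney volumes drawn
#' uniformly per subject over the observed porcine range (46-138 ml), with
#' each of a subject's two kidneys jittered within +/-10% of the subject
#' draw (a pig's kidneys are close in size, which is what makes the paired
#' design informative); ellipsoid aspect fixed at 66.4:50:45; cortical
#' depths 50 and 100 pixels at 0.1 mm spacing. `kidney_volume_ml_range` and
#' `aspect` can be scaled down for desk-scale simulation studies without
#' touching the pixel-denominated regime and depth defaults.
#'
#' @param n_subjects number of subjects (default 7).
#' @param depths_px stratification depths in pixels (default `c(50, 100)`).
#' @param continuous,pulsed [regime_spec()] objects for the two arms.
#' @param kidney_volume_ml_range per-subject kidney volume range (ml).
#' @param kidney_jitter half-width of the within-subject relative volume
#'   jitter (default 0.1).
#' @param aspect relative ellipsoid axis proportions (full axes).
#' @param spacing_mm voxel spacing (default 0.1 mm).
#' @param noise_sigma,background_intensity,particle_intensity rendering
#'   parameters, see [phantom_spec()].
#' @param cortex_denominator see [quantify_kidney()].
#' @return A `study_config`.
#' @export
study_config <- function(n_subjects = 7L,
                         depths_px = c(50L, 100L),
                         continuous = regime_spec("continuous"),
                         pulsed = regime_spec("pulsed"),
                         kidney_volume_ml_range = c(46, 138),
                         kidney_jitter = 0.1,
                         aspect = c(66.4, 50, 45),
                         spacing_mm = 0.1,
                         noise_sigma = 30,
                         background_intensity = 100,
                         particle_intensity = 400,
                         cortex_denominator = "shell") {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1")
  depths_px <- as.integer(depths_px)
  if (is.unsorted(depths_px, strictly = TRUE) || any(depths_px <= 0))
    stop("`depths_px` must be strictly increasing positive integers")
  stopifnot(inherits(continuous, "regime_spec"), inherits(pulsed, "regime_spec"))
  if (length(kidney_volume_ml_range) != 2L ||
      kidney_volume_ml_range[1] <= 0 ||
      kidney_volume_ml_range[1] > kidney_volume_ml_range[2])
    stop("`kidney_volume_ml_range` must be (low, high) with 0 < low <= high")
  structure(list(n_subjects = n_subjects, depths_px = depths_px,
                 continuous = continuous, pulsed = pulsed,
                 kidney_volume_ml_range = as.numeric(kidney_volume_ml_range),
                 kidney_jitter = kidney_jitter,
                 aspect = as.numeric(aspect),
                 spacing_mm = spacing_mm, noise_sigma = noise_sigma,
                 background_intensity = background_intensity,
                 particle_intensity = particle_intensity,
                 cortex_denominator = cortex_denominator),
            class = "study_config")
}

# Semi-axes (mm) of an ellipsoid with the config's aspect and given volume.
semi_axes_for_volume <- function(volume_ml, aspect) {
  prod_target <- volume_ml * 1000 * 3 / (4 * pi)   # a*b*c in mm^3
  half <- aspect / 2
  half * (prod_target / prod(half))^(1 / 3)
}

# One kidney through the whole pipeline: phantom -> noise -> segmentation ->
# stratification -> quantification. RNG must be seeded by the caller.
run_one_kidney <- function(config, regime, volume_ml, kidney_id) {
  semi <- semi_axes_for_volume(volume_ml, config$aspect)
  pspec <- phantom_spec(semi_axes_mm = semi, spacing_mm = config$spacing_mm,
                        noise_sigma = config$noise_sigma,
                        background_intensity = config$background_intensity,
                        particle_intensity = config$particle_intensity)
  kidney <- generate_kidney_mask(pspec)
  dist <- surface_distance_field(kidney)
  particles <- sample_particles(regime, pspec, kidney, dist = dist)
  embolic_ml <- stats::runif(1, regime$embolic_ml_range[1],
                             regime$embolic_ml_range[2])
  vol <- rasterize_particles(particles, dim(kidney$data), pspec$spacing_mm,
                             pspec, origin_mm = kidney$origin_mm)
  vol <- add_ct_noise(vol, pspec$noise_sigma)
  vessel <- segment_particles(vol, default_segmentation_params(pspec))
  q <- quantify_kidney(vessel, kidney, depths_px = config$depths_px,
                       embolic_ml = embolic_ml,
                       cortex_denominator = config$cortex_denominator,
                       kidney_id = kidney_id, dist = dist)
  list(quant = q, n_true_particles = nrow(particles))
}

#' Run a full paired phantom study
#'
#' Simulates the complete design: for every subject, one kidney per
#' technique (alternating sides), each taken through phantom rendering,
#' noise, segmentation, stratification and quantification; then paired
#' tests (paired t and exact Wilcoxon) and median/range group summaries per
#' metric. Fully deterministic given `seed`: each kidney uses the child
#' seed `seed + 10 * subject + side` (side 1 = left, 2 = right), so any
#' kidney can be regenerated in isolation.
#'
#' @param config a [study_config()].
#' @param seed integer top-level seed.
#' @return A `paired_study_result`: list with `quant` (data.frame, one row
#'   per subject x kidney x depth), `kidneys` (per-kidney records), `pairs`
#'   (per-metric [paired_sample()]s), `tests` (per-metric paired t and
#'   Wilcoxon results), `summary` (per-group median/range), `config`,
#'   `seed`.
#' @export
run_study <- function(config, seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  sides <- assign_sides(config$n_subjects)
  rows <- list(); kidneys <- list()
  for (s in seq_len(config$n_subjects)) {
    set.seed(seed + 10L * s)
    vr <- config$kidney_volume_ml_range
    subject_volume <- stats::runif(1, vr[1], vr[2])
    for (side_i in 1:2) {
      side <- c("left", "right")[side_i]
      regime_name <- if (side == "left") sides$left_regime[s]
                     else sides$right_regime[s]
      regime <- config[[regime_name]]
      set.seed(seed + 10L * s + side_i)
      jit <- stats::runif(1, 1 - config$kidney_jitter,
                          1 + config$kidney_jitter)
      kid <- run_one_kidney(config, regime, subject_volume * jit,
                            kidney_id = sprintf("s%02d_%s_%s", s, side,
                                                regime_name))
      q <- kid$quant
      kidneys[[length(kidneys) + 1L]] <- list(
        subject = s, side = side, regime = regime_name, quant = q,
        n_true_particles = kid$n_true_particles)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, side = side, regime = regime_name,
        kidney_id = q$kidney_id,
        kidney_volume_ml = q$kidney_volume_ml,
        embolic_ml = q$embolic_ml,
        embolic_kidney_ratio = embolic_to_kidney_ratio(q$embolic_ml,
                                                       q$kidney_volume_ml),
        total_particles = q$total_particles,
        q$per_depth)
    }
  }
  quant <- do.call(rbind, rows)
  res <- structure(list(quant = quant, kidneys = kidneys, config = config,
                        seed = seed),
                   class = "paired_study_result")
  res$pairs <- study_paired_samples(res)
  res$tests <- lapply(res$pairs, function(p) {
    list(paired_t = try_test(paired_t_test, p),
         wilcoxon = try_test(wilcoxon_signed_rank, p))
  })
  res$summary <- study_group_summaries(res)
  res
}

try_test <- function(fun, sample) {
  tryCatch(fun(sample), error = function(e)
    new_test_result(NA_real_, NA_real_, paste0("undefined: ", conditionMessage(e)),
                    length(sample$x)))
}

# Per-metric paired samples (continuous arm = x, pulsed arm = y).
study_paired_samples <- function(res) {
  q <- res$quant
  depths <- res$config$depths_px
  one_per_kidney <- q[q$depth_px == depths[1],
                      c("subject", "regime", "kidney_volume_ml", "embolic_ml",
                        "embolic_kidney_ratio", "total_particles")]
  pair_of <- function(df, col) {
    xc <- df[df$regime == "continuous", ]
    xp <- df[df$regime == "pulsed", ]
    xc <- xc[order(xc$subject), ]; xp <- xp[order(xp$subject), ]
    paired_sample(xc[[col]], xp[[col]], subject_ids = xc$subject)
  }
  pairs <- list(
    kidney_volume_ml = pair_of(one_per_kidney, "kidney_volume_ml"),
    embolic_ml = pair_of(one_per_kidney, "embolic_ml"),
    embolic_kidney_ratio = pair_of(one_per_kidney, "embolic_kidney_ratio"),
    total_particles = pair_of(one_per_kidney, "total_particles"))
  for (d in depths) {
    qd <- q[q$depth_px == d, ]
    pairs[[sprintf("pct_cortex_%d", d)]] <-
      pair_of(qd, "percent_embolized_cortex")
    pairs[[sprintf("efficiency_%d", d)]] <- pair_of(qd, "efficiency_per_ml")
    pairs[[sprintf("particles_%d", d)]] <- pair_of(qd, "particle_count")
  }
  pairs
}

study_group_summaries <- function(res) {
  lapply(res$pairs, function(p)
    list(continuous = median_and_range(p$x),
         pulsed = median_and_range(p$y)))
}

#' @export
print.paired_study_result <- function(x, ...) {
  cat(sprintf("<paired_study_result> %d subjects, depths %s px, seed %d\n",
              x$config$n_subjects,
              paste(x$config$depths_px, collapse = "/"), x$seed))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    t <- x$tests[[m]]
    cat(sprintf("  %-22s continuous %.3g (%.3g-%.3g) vs pulsed %.3g (%.3g-%.3g), wilcoxon p = %.3g\n",
                m, s$continuous$median, s$continuous$min, s$continuous$max,
                s$pulsed$median, s$pulsed$min, s$pulsed$max,
                t$wilcoxon$p_two_sided))
  }
  invisible(x)
}
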