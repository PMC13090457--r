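test_that("side assignment alternates by subject parity", {
  a <- assign_sides(7)
  expect_equal(a$left_regime[1], "pulsed")     # odd: left pulsed
  expect_equal(a$right_regime[1], "continuous")
  expect_equal(a$left_regime[2], "continuous") # even: left continuous
  expect_equal(a$right_regime[2], "pulsed")
  expect_equal(sum(a$left_regime == "pulsed"), 4)
  expect_equal(sum(a$left_regime == "continuous"), 3)
  expect_error(assign_sides(0), ">= 1")
})

micro_config <- function(n_subjects = 2L, ...) {
  study_config(
    n_subjects = n_subjects, depths_px = c(5L, 10L),
    continuous = regime_spec("continuous", particle_count_mean = 120),
    pulsed = regime_spec("pulsed", particle_count_mean = 100),
    kidney_volume_ml_range = c(0.15, 0.2), ...)
}

test_that("a study is deterministic given the seed and balanced by design", {
  res1 <- run_study(micro_config(3L), seed = 9)
  res2 <- run_study(micro_config(3L), seed = 9)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  write_results(res1, f1); write_results(res2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  q <- res1$quant
  expect_equal(nrow(q), 3 * 2 * 2)             # subjects x kidneys x depths
  per_kid <- unique(q[, c("subject", "side", "regime")])
  expect_equal(nrow(per_kid), 6)
  tab <- table(per_kid$subject, per_kid$regime)
  expect_true(all(tab == 1))                   # one kidney per regime per subject

  res3 <- run_study(micro_config(3L), seed = 10)
  expect_false(identical(res1$quant, res3$quant))
})

test_that("noise does not change particle counts on non-merging phantoms", {
  # segmentation exactness propagates end-to-end: with well-separated beads
  # and default contrast, the noisy and noiseless pipelines count alike
  spec <- small_phantom_spec(0.5)
  set.seed(61)
  kidney <- generate_kidney_mask(spec)
  dist <- surface_distance_field(kidney)
  reg <- regime_spec("continuous", particle_count_mean = 250)
  particles <- sample_particles(reg, spec, kidney, dist = dist,
                                min_separation_px = 3)
  clean <- rasterize_particles(particles, dim(kidney$data), spec$spacing_mm,
                               spec, kidney$origin_mm)
  noisy <- add_ct_noise(clean, spec$noise_sigma)
  params <- default_segmentation_params(spec)
  q_clean <- quantify_kidney(segment_particles(clean, params), kidney,
                             depths_px = c(15L, 30L), dist = dist)
  q_noisy <- quantify_kidney(segment_particles(noisy, params), kidney,
                             depths_px = c(15L, 30L), dist = dist)
  expect_equal(q_noisy$total_particles, q_clean$total_particles)
  expect_equal(q_noisy$per_depth$particle_count,
               q_clean$per_depth$particle_count)
})

test_that("identical regimes in both arms keep the false-positive rate nominal", {
  # null configuration at an extra-small phantom scale (runtime only; the
  # type-I property is scale-free)
  null_cfg <- study_config(
    n_subjects = 7L, depths_px = 10L,
    continuous = regime_spec("continuous", depth_scale_px = 15,
                             particle_count_mean = 150,
                             embolic_ml_range = c(1, 2)),
    pulsed = regime_spec("pulsed", depth_scale_px = 15,
                         particle_count_mean = 150,
                         embolic_ml_range = c(1, 2)),
    kidney_volume_ml_range = c(0.15, 0.2))
  n_rep <- 60
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    res <- run_study(null_cfg, seed = 5000 * r)
    reject[r] <- res$tests$pct_cortex_10$wilcoxon$p_two_sided <= 0.05
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(reject), 0.05 + 3 * se)
})

test_that("study configs round-trip through the flat key=value format", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "study.cfg")
  writeLines(c(
    "# scaled-down demo study",
    "n_subjects = 3",
    "depths_px = 10, 20",
    "kidney_volume_ml_range = 0.5, 0.9",
    "continuous_depth_scale_px = 25",
    "pulsed_particle_count_mean = 900",
    "noise_sigma = 12"), p)
  cfg <- read_study_config(p)
  expect_equal(cfg$n_subjects, 3L)
  expect_equal(cfg$depths_px, c(10L, 20L))
  expect_equal(cfg$kidney_volume_ml_range, c(0.5, 0.9))
  expect_equal(cfg$continuous$depth_scale_px, 25)
  expect_equal(cfg$continuous$particle_count_mean, 3400)  # default kept
  expect_equal(cfg$pulsed$particle_count_mean, 900)
  expect_equal(cfg$noise_sigma, 12)
  writeLines("not_a_key = 1", p)
  expect_error(read_study_config(p), "unknown")
})

test_that("particle ground truth writes the documented CSV columns", {
  spec <- small_phantom_spec(0.2)
  set.seed(62)
  kidney <- generate_kidney_mask(spec)
  pp <- sample_particles(regime_spec("pulsed", particle_count_mean = 50),
                         spec, kidney)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "truth.csv")
  write_particles(pp, f)
  back <- read.csv(f)
  expect_equal(names(back), c("center_x_mm", "center_y_mm", "center_z_mm",
                              "radius_um", "depth_px", "depth_drawn_px"))
  expect_equal(nrow(back), nrow(pp))
})
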