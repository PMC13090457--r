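test_that("intersection counting equals elementwise-AND enumeration", {
  dims <- c(4, 4, 4)
  a <- binary_mask(array(FALSE, dims)); a$data[1:2, , ] <- TRUE
  b <- binary_mask(array(FALSE, dims)); b$data[3:4, , ] <- TRUE
  expect_equal(count_intersection_voxels(a, b), 0)          # disjoint

  sub <- binary_mask(array(FALSE, dims)); sub$data[1, 1:2, 1] <- TRUE
  expect_equal(count_intersection_voxels(sub, a), sum(sub$data))  # subset

  set.seed(41)
  for (rep in 1:10) {
    d <- sample(3:20, 3, replace = TRUE)
    x <- binary_mask(random_mask(d)); y <- binary_mask(random_mask(d))
    # direct enumeration oracle
    n <- 0L
    for (i in seq_along(x$data)) if (x$data[i] && y$data[i]) n <- n + 1L
    expect_equal(count_intersection_voxels(x, y), n)
  }
})

test_that("efficiency, cortex percentage and ratios follow their definitions", {
  expect_equal(embolization_efficiency(0, 80), 0)
  expect_equal(embolization_efficiency(1000, 80), 12.5)
  expect_equal(embolization_efficiency(500, 40),
               2 * embolization_efficiency(500, 80))   # halves when volume doubles
  expect_error(embolization_efficiency(10, 0), "positive")

  expect_equal(percent_embolized_cortex(0, 1234), 0)
  expect_equal(percent_embolized_cortex(1234, 1234), 100)
  expect_error(percent_embolized_cortex(1, 0), "empty")

  expect_equal(embolic_to_kidney_ratio(14.0, 78.1), 14.0 / 78.1)
  expect_equal(embolic_to_kidney_ratio(0, 5), 0)
  expect_equal(embolic_to_kidney_ratio(3, 7) * embolic_to_kidney_ratio(7, 3), 1)
  expect_error(embolic_to_kidney_ratio(1, 0), "positive")

  expect_equal(percent_difference(0.20, 0.16), 25)
  expect_equal(percent_difference(4.2, 4.2), 0)
  expect_equal(percent_difference(0.16, 0.20), -20)
  expect_error(percent_difference(1, 0), "baseline")

  expect_equal(sum_particle_counts(c(3688, 3118)), 6806L)
  expect_equal(sum_particle_counts(integer(0)), 0L)
  expect_error(sum_particle_counts(c(3, -1)), "non-negative")
})

test_that("centroid-rule particle counts partition components across regions", {
  dims <- c(12, 12, 12)
  m <- array(FALSE, dims)
  m[2, 2, 2] <- TRUE                 # in left half
  m[9:10, 9, 9] <- TRUE              # in right half
  m[6:7, 6, 6] <- TRUE               # centroid at 6.5 -> rounds to 6, left
  bm <- binary_mask(m)
  lab <- label_components(bm, 26)
  left <- binary_mask(array(FALSE, dims)); left$data[1:6, , ] <- TRUE
  right <- binary_mask(array(FALSE, dims)); right$data[7:12, , ] <- TRUE
  whole <- binary_mask(array(TRUE, dims))
  expect_equal(count_particles_in_region(lab$labels, lab$count, whole), 3)
  nl <- count_particles_in_region(lab$labels, lab$count, left)
  nr <- count_particles_in_region(lab$labels, lab$count, right)
  expect_equal(nl, 2)
  expect_equal(nl + nr, lab$count)
  empty_lab <- label_components(binary_mask(array(FALSE, dims)))
  expect_equal(count_particles_in_region(empty_lab$labels, empty_lab$count,
                                         whole), 0)
})

test_that("per-kidney quantification recovers phantom ground truth", {
  spec <- small_phantom_spec(0.8)
  set.seed(43)
  kidney <- generate_kidney_mask(spec)
  dist <- surface_distance_field(kidney)
  reg <- regime_spec("continuous", particle_count_mean = 400)
  particles <- sample_particles(reg, spec, kidney, dist = dist,
                                min_separation_px = 2)
  clean <- rasterize_particles(particles, dim(kidney$data), spec$spacing_mm,
                               spec, kidney$origin_mm)
  vessel <- segment_particles(clean, default_segmentation_params(spec))
  depths <- c(15L, 30L)
  q <- quantify_kidney(vessel, kidney, depths_px = depths, embolic_ml = 2,
                       dist = dist)

  # particle counts per shell equal ground-truth depth tallies exactly
  for (i in seq_along(depths)) {
    expect_equal(q$per_depth$particle_count[i],
                 sum(particles$depth_px <= depths[i]))
    # percent embolized cortex matches the direct count ratio
    expect_equal(q$per_depth$percent_embolized_cortex[i],
                 100 * q$per_depth$intersect_voxels[i] /
                   q$per_depth$shell_voxels[i])
    # sub-voxel beads: one voxel each, all inside their shell
    expect_equal(q$per_depth$intersect_voxels[i],
                 sum(particles$depth_px <= depths[i]))
  }
  expect_equal(q$total_particles, nrow(particles))

  # nesting across depths
  expect_true(all(diff(q$per_depth$intersect_voxels) >= 0))
  expect_true(all(diff(q$per_depth$particle_count) >= 0))

  # dual route: the fused per-depth tally equals explicit stratification
  # plus mask intersection
  strata <- stratify(kidney, depths_px = depths, dist = dist)
  lab0 <- label_components(vessel, 26)
  for (i in seq_along(depths)) {
    expect_equal(q$per_depth$shell_voxels[i], sum(strata[[i]]$shell$data))
    expect_equal(q$per_depth$intersect_voxels[i],
                 count_intersection_voxels(vessel, strata[[i]]$shell))
    expect_equal(q$per_depth$particle_count[i],
                 count_particles_in_region(lab0$labels, lab0$count,
                                           strata[[i]]$shell))
  }

  # conservation: shell + interior counts equal the total
  st <- stratify(kidney, depths_px = depths[1], dist = dist)[[1]]
  lab <- label_components(vessel, 26)
  expect_equal(count_particles_in_region(lab$labels, lab$count, st$shell) +
                 count_particles_in_region(lab$labels, lab$count, st$eroded),
               lab$count)

  # mask-derived vs ellipsoid normalizer
  expect_equal(q$kidney_volume_ml, mask_volume_ml(kidney))
  q2 <- quantify_kidney(vessel, kidney, depths_px = 15L,
                        kidney_volume_source = "ellipsoid",
                        ellipsoid_axes_mm = 2 * spec$semi_axes_mm,
                        dist = dist)
  expect_equal(q2$kidney_volume_ml,
               ellipsoid_volume_ml(2 * spec$semi_axes_mm[1],
                                   2 * spec$semi_axes_mm[2],
                                   2 * spec$semi_axes_mm[3]))
})

test_that("whole-kidney cortex denominator is available behind the switch", {
  spec <- small_phantom_spec(0.3)
  set.seed(44)
  kidney <- generate_kidney_mask(spec)
  reg <- regime_spec("continuous", particle_count_mean = 100)
  particles <- sample_particles(reg, spec, kidney)
  clean <- rasterize_particles(particles, dim(kidney$data), spec$spacing_mm,
                               spec, kidney$origin_mm)
  vessel <- segment_particles(clean, default_segmentation_params(spec))
  qs <- quantify_kidney(vessel, kidney, depths_px = 10L, dist = NULL)
  qw <- quantify_kidney(vessel, kidney, depths_px = 10L,
                        cortex_denominator = "whole")
  expect_equal(qw$per_depth$percent_embolized_cortex,
               100 * qw$per_depth$intersect_voxels / sum(kidney$data))
  expect_gte(qs$per_depth$percent_embolized_cortex,
             qw$per_depth$percent_embolized_cortex)
})
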