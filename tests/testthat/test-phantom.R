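test_that("ellipsoid volume matches the closed form and a fine-grid oracle", {
  expect_equal(ellipsoid_volume_ml(10, 10, 10), pi / 6, tolerance = 1e-9)
  expect_equal(ellipsoid_volume_ml(0, 50, 60), 0)
  expect_error(ellipsoid_volume_ml(-1, 2, 3), "non-negative")

  # fine-grid integration oracle on a 0.05 mm lattice: count voxel centers
  # inside the ellipsoid, column-by-column in closed lattice arithmetic
  lattice_ellipsoid_ml <- function(L, W, H, h = 0.05) {
    a <- L / 2; b <- W / 2; cc <- H / 2
    nx <- ceiling(a / h); ny <- ceiling(b / h)
    x <- (seq(-nx, nx - 1) + 0.5) * h
    y <- (seq(-ny, ny - 1) + 0.5) * h
    q <- outer((x / a)^2, (y / b)^2, "+")
    inside <- q < 1
    nz <- floor(cc * sqrt(pmax(0, 1 - q[inside])) / h + 0.5)
    sum(2 * nz) * h^3 / 1000
  }
  v_closed <- ellipsoid_volume_ml(66.4, 50, 45)
  v_grid <- lattice_ellipsoid_ml(66.4, 50, 45)
  expect_lt(abs(v_closed - v_grid) / v_grid, 0.005)
})

test_that("kidney mask rasterization matches center-inequality enumeration", {
  # semi-axes of exactly one voxel in a 5^3 grid: center + 6 face neighbors
  spec1 <- phantom_spec(semi_axes_mm = c(0.1, 0.1, 0.1))
  m1 <- generate_kidney_mask(spec1, grid_shape = c(5L, 5L, 5L))
  expect_equal(sum(m1$data), 7)
  # brute-force enumeration of voxel centers against the inequality
  # (in voxel units, where the arithmetic is exact)
  brute <- array(FALSE, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    brute[i, j, k] <- sum((c(i, j, k) - 0.5 - 2.5)^2) <= 1
  expect_identical(m1$data, brute)

  # voxelized volume within 2% of (4/3) pi a b c for semi-axes >= 20 voxels
  spec2 <- phantom_spec(semi_axes_mm = c(2.0, 2.2, 2.4))
  m2 <- generate_kidney_mask(spec2)
  v_mask <- mask_volume_ml(m2)
  v_true <- 4 * pi / 3 * prod(c(2.0, 2.2, 2.4)) / 1000
  expect_lt(abs(v_mask - v_true) / v_true, 0.02)

  expect_error(generate_kidney_mask(spec2, grid_shape = c(30L, 30L, 30L)),
               "grid")
})

test_that("sampled depths follow the truncated-exponential regime model", {
  set.seed(101)
  spec <- small_phantom_spec()
  kidney <- generate_kidney_mask(spec)
  dist <- surface_distance_field(kidney)
  d_max <- max(dist)
  reg_c <- regime_spec("continuous")   # scale 40 px
  reg_p <- regime_spec("pulsed")       # scale 60 px

  pc <- sample_particles(reg_c, spec, kidney, dist = dist, n_particles = 1e5)
  # pre-binning draws match the closed-form truncated-exponential mean
  expect_lt(abs(mean(pc$depth_drawn_px) - trunc_exp_mean(40, d_max)) /
              trunc_exp_mean(40, d_max), 0.02)
  # realized voxel depths track the draws to within the 1-px binning
  expect_lt(abs(mean(pc$depth_px) - mean(pc$depth_drawn_px)), 1)

  # continuous penetrates shallower: CDF at 50 px ordered as closed form
  pp <- sample_particles(reg_p, spec, kidney, dist = dist, n_particles = 1e5)
  emp_c <- mean(pc$depth_px <= 50)
  emp_p <- mean(pp$depth_px <= 50)
  expect_gt(emp_c, emp_p)
  expect_gt(trunc_exp_cdf(50, 40, d_max), trunc_exp_cdf(50, 60, d_max))
  expect_lt(abs(emp_c - trunc_exp_cdf(50, 40, d_max)), 0.02)
  expect_lt(abs(emp_p - trunc_exp_cdf(50, 60, d_max)), 0.02)

  # scale -> 0+ limit: every particle lands in the outermost depth bin
  reg0 <- regime_spec("continuous", depth_scale_px = 1e-6)
  p0 <- sample_particles(reg0, spec, kidney, dist = dist, n_particles = 200)
  expect_true(all(ceiling(p0$depth_px) == 1))

  # every center lies inside the kidney, depths non-negative
  expect_true(all(kidney$data[cbind(pc$vx, pc$vy, pc$vz)]))
  expect_true(all(pc$depth_px >= 0))
  expect_true(all(pc$radius_um >= 37.5 & pc$radius_um <= 50))

  expect_error(sample_particles(reg_c, spec,
                                binary_mask(array(FALSE, c(3, 3, 3)))),
               "empty")
})

test_that("particle rasterization marks the right voxels", {
  spec <- phantom_spec()
  one <- data.frame(center_x_mm = 0.55, center_y_mm = 0.55,
                    center_z_mm = 0.55, radius_um = 40)
  v <- rasterize_particles(one, c(11, 11, 11), 0.1, spec)
  expect_equal(sum(v$data > spec$background_intensity), 1)
  expect_equal(v$data[6, 6, 6], spec$particle_intensity)

  # disjoint particles contribute additively
  two <- data.frame(center_x_mm = c(0.25, 0.85), center_y_mm = c(0.25, 0.85),
                    center_z_mm = c(0.25, 0.85), radius_um = c(40, 40))
  v2 <- rasterize_particles(two, c(11, 11, 11), 0.1, spec)
  expect_equal(sum(v2$data > spec$background_intensity), 2)

  # a 5-voxel-radius sphere fills ~(4/3) pi r^3 voxels (hand-built record;
  # the radius range check applies to sampled beads, not to this helper)
  big <- data.frame(center_x_mm = 1.55, center_y_mm = 1.55,
                    center_z_mm = 1.55, radius_um = 500)
  vb <- rasterize_particles(big, c(31, 31, 31), 0.1, spec)
  n_vox <- sum(vb$data > spec$background_intensity)
  expect_lt(abs(n_vox - 4 * pi / 3 * 125) / (4 * pi / 3 * 125), 0.05)

  expect_error(rasterize_particles(
    data.frame(center_x_mm = 5, center_y_mm = 0.1, center_z_mm = 0.1,
               radius_um = 40), c(11, 11, 11), 0.1, spec), "outside")
})

test_that("CT noise is zero-mean Gaussian, clamped, and seed-reproducible", {
  v <- volume3d(array(100, c(100, 100, 100)))
  expect_identical(add_ct_noise(v, 0), v)
  set.seed(5); a <- add_ct_noise(v, 10)
  set.seed(5); b <- add_ct_noise(v, 10)
  expect_identical(a$data, b$data)
  # sample mean within 3 standard errors of the clean value
  se <- 10 / sqrt(1e6)
  expect_lt(abs(mean(a$data) - 100), 3 * se)
  expect_true(all(a$data >= 0))
  expect_error(add_ct_noise(v, -1), "sigma")
})

test_that("phantoms are fully reproducible from spec + seed", {
  spec <- small_phantom_spec(0.3)
  reg <- regime_spec("continuous", particle_count_mean = 150)
  gen <- function() {
    k <- generate_kidney_mask(spec)
    p <- sample_particles(reg, spec, k)
    v <- add_ct_noise(rasterize_particles(p, dim(k$data), spec$spacing_mm,
                                          spec, k$origin_mm),
                      spec$noise_sigma)
    list(p = p, v = v)
  }
  set.seed(77); r1 <- gen()
  set.seed(77); r2 <- gen()
  expect_identical(r1$p, r2$p)
  expect_identical(r1$v$data, r2$v$data)
})
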