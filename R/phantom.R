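#' Injection regime specification
#'
#' A regime is modeled phenomenologically as a penetration-depth
#' distribution, not a hemodynamic simulation: the depth of each deposited
#' microsphere below the organ surface follows a truncated exponential with
#' mean `depth_scale_px` (truncated at the deepest interior voxel). The
#' continuous technique (steady 1 ml/s to stasis) penetrates more distally
#' (smaller scale) and deposits more particles than the pulsed technique
#' (1 ml boluses with 1 s pauses).
#'
#' @param name `"continuous"` or `"pulsed"`.
#' @param depth_scale_px mean of the (untruncated) exponential depth
#'   distribution, in pixels. Defaults: continuous 40, pulsed 60.
#' @param particle_count_mean expected particles per kidney (Poisson mean).
#'   Defaults: continuous 3400, pulsed 3100, matching the per-kidney counts
#'   of roughly 3,000-3,700 observed in embolized porcine kidneys.
#' @param embolic_ml_range range (ml) of the injected embolic volume, drawn
#'   uniformly per kidney. Defaults: continuous (12, 20), pulsed (8, 22).
#' @return A `regime_spec` object.
#' @export
regime_spec <- function(name = c("continuous", "pulsed"),
                        depth_scale_px = NULL,
                        particle_count_mean = NULL,
                        embolic_ml_range = NULL) {
  name <- match.arg(name)
  defaults <- list(
    continuous = list(scale = 40, count = 3400, embolic = c(12, 20)),
    pulsed     = list(scale = 60, count = 3100, embolic = c(8, 22)))[[name]]
  if (is.null(depth_scale_px)) depth_scale_px <- defaults$scale
  if (is.null(particle_count_mean)) particle_count_mean <- defaults$count
  if (is.null(embolic_ml_range)) embolic_ml_range <- defaults$embolic
  if (depth_scale_px <= 0) stop("`depth_scale_px` must be positive")
  if (particle_count_mean <= 0) stop("`particle_count_mean` must be positive")
  if (length(embolic_ml_range) != 2L || embolic_ml_range[1] <= 0 ||
      embolic_ml_range[1] > embolic_ml_range[2])
    stop("`embolic_ml_range` must be (low, high) with 0 < low <= high")
  structure(list(name = name, depth_scale_px = depth_scale_px,
                 particle_count_mean = particle_count_mean,
                 embolic_ml_range = embolic_ml_range),
            class = "regime_spec")
}

#' Kidney phantom specification
#'
#' Geometry and rendering parameters for a synthetic ellipsoid kidney with
#' radiopaque microsphere deposits. The default semi-axes reproduce a
#' median-sized (~78 ml) porcine kidney; beads are 75-100 um in diameter,
#' sub-voxel at the default 0.1 mm scanner resolution. Intensity levels and
#' noise are calibration-free stand-ins (no bead/scanner SNR figures exist
#' to calibrate against): contrast is 10x the noise standard deviation.
#'
#' @param semi_axes_mm ellipsoid semi-axes (mm), default `c(33.2, 25, 22.5)`.
#' @param spacing_mm isotropic voxel spacing (mm), default 0.1.
#' @param particle_radius_um_range bead radius range in um, default
#'   `c(37.5, 50)` (i.e. 75-100 um diameters).
#' @param noise_sigma Gaussian CT noise standard deviation (intensity units).
#' @param background_intensity,particle_intensity intensity levels of tissue
#'   background and bead voxels; `particle_intensity` must exceed
#'   `background_intensity`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(semi_axes_mm = c(33.2, 25, 22.5),
                         spacing_mm = 0.1,
                         particle_radius_um_range = c(37.5, 50),
                         noise_sigma = 30,
                         background_intensity = 100,
                         particle_intensity = 400) {
  if (length(semi_axes_mm) != 3L || any(semi_axes_mm <= 0))
    stop("`semi_axes_mm` must be three positive lengths")
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive")
  r <- particle_radius_um_range
  if (length(r) != 2L || r[1] > r[2] || r[1] < 37.5 || r[2] > 50)
    stop("`particle_radius_um_range` must lie within [37.5, 50] um (75-100 um diameter beads)")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (particle_intensity <= background_intensity)
    stop("`particle_intensity` must exceed `background_intensity`")
  structure(list(semi_axes_mm = as.numeric(semi_axes_mm),
                 spacing_mm = spacing_mm,
                 particle_radius_um_range = as.numeric(r),
                 noise_sigma = noise_sigma,
                 background_intensity = background_intensity,
                 particle_intensity = particle_intensity),
            class = "phantom_spec")
}

#' Ellipsoid volume (ultrasound "ellipsoid method")
#'
#' The standard sonographic organ-volume estimate from three orthogonal
#' full-axis lengths: V = (pi/6) L W H.
#'
#' @param l_mm,w_mm,h_mm full axis lengths in mm (NOT semi-axes).
#' @return Volume in ml.
#' @examples
#' ellipsoid_volume_ml(10, 10, 10)   # 10 mm sphere: ~0.524 ml
#' ellipsoid_volume_ml(66.4, 50, 45) # median porcine kidney: ~78 ml
#' @export
ellipsoid_volume_ml <- function(l_mm, w_mm, h_mm) {
  if (any(c(l_mm, w_mm, h_mm) < 0)) stop("axis lengths must be non-negative")
  pi / 6 * l_mm * w_mm * h_mm / 1000
}

#' Rasterize an ellipsoid kidney mask
#'
#' A voxel is foreground iff its center satisfies
#' sum(((c - center) / a)^2) <= 1, with the ellipsoid centered in the grid.
#' The ellipsoid must leave at least one voxel of background on every grid
#' face: erosion needs an exterior.
#'
#' @param spec a [phantom_spec()].
#' @param grid_shape integer 3-vector of grid dimensions; `NULL` sizes the
#'   grid to the ellipsoid plus a `margin_vox` margin per face.
#' @param margin_vox background margin (voxels) when auto-sizing.
#' @param origin_mm physical origin of the grid.
#' @return A [binary_mask()].
#' @export
generate_kidney_mask <- function(spec, grid_shape = NULL, margin_vox = 2L,
                                 origin_mm = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  a_vox <- spec$semi_axes_mm / sp
  if (is.null(grid_shape))
    grid_shape <- as.integer(ceiling(2 * a_vox) + 2L * margin_vox)
  grid_shape <- as.integer(grid_shape)
  if (any(2 * a_vox >= grid_shape - 2))   # need >= 1 background voxel per face
    stop("ellipsoid touches or exceeds the grid bounds; enlarge `grid_shape`")
  m <- .ellipsoid_mask_cpp(grid_shape, grid_shape / 2, a_vox)
  new_binary_mask(m, spacing_mm = sp, origin_mm = as.numeric(origin_mm))
}

#' Sample microsphere deposits for one kidney
#'
#' Deposits particles according to the regime's penetration-depth model:
#' the particle count is Poisson(`particle_count_mean`); each depth is drawn
#' from Exponential(`depth_scale_px`) truncated at the mask's maximum
#' interior depth; the particle is placed uniformly at random among the
#' voxels of the nearest available integer depth bin (bins are
#' `ceiling(surface distance)`, the same distance field the stratification
#' step uses, so generator and analyzer share one geometry). Radii are
#' uniform on the spec's range. Uses the current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param regime a [regime_spec()].
#' @param spec a [phantom_spec()].
#' @param kidney_mask the kidney [binary_mask()].
#' @param dist optional precomputed [surface_distance_field()] of
#'   `kidney_mask` (recomputed when `NULL`).
#' @param n_particles override the Poisson draw with a fixed count.
#' @param min_separation_px if > 0, enforce pairwise Chebyshev separation of
#'   at least this many voxels between particle centers by rejection
#'   sampling (used to build guaranteed non-merging phantoms for validation;
#'   biases the depth distribution slightly at high densities).
#' @return A `particle_set`: data.frame with columns `center_x_mm`,
#'   `center_y_mm`, `center_z_mm`, `radius_um`, `depth_px` (realized voxel
#'   depth), `depth_drawn_px` (the pre-binning draw) plus the voxel indices
#'   used (`vx`, `vy`, `vz`).
#' @export
sample_particles <- function(regime, spec, kidney_mask, dist = NULL,
                             n_particles = NULL, min_separation_px = 0) {
  stopifnot(inherits(regime, "regime_spec"), inherits(spec, "phantom_spec"),
            inherits(kidney_mask, "binary_mask"))
  if (!any(kidney_mask$data)) stop("kidney mask is empty")
  if (is.null(dist)) dist <- surface_distance_field(kidney_mask)
  fg <- which(kidney_mask$data)
  depth_bin <- as.integer(ceiling(dist[fg]))
  # group foreground voxels by integer depth bin (radix sort; a split()
  # over millions of voxels is measurably slower)
  ord <- order(depth_bin, method = "radix")
  rl <- rle(depth_bin[ord])
  bins <- rl$values                       # sorted ascending
  bin_end <- cumsum(rl$lengths)
  bin_start <- bin_end - rl$lengths + 1L
  cand_for <- function(bi) fg[ord[bin_start[bi]:bin_end[bi]]]
  d_max <- max(dist[fg])

  n <- if (is.null(n_particles)) stats::rpois(1, regime$particle_count_mean)
       else as.integer(n_particles)
  sp <- kidney_mask$spacing_mm
  dims <- dim(kidney_mask$data)
  scale <- regime$depth_scale_px
  trunc_mass <- 1 - exp(-d_max / scale)

  # position of the nearest available bin for each target depth
  # (ties go to the shallower bin)
  nearest_bin_pos <- function(bt) {
    pos <- findInterval(bt, bins)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(bins))
    take_lo <- pos >= 1L &
      (pos == length(bins) | (bt - bins[lo]) <= (bins[hi] - bt))
    ifelse(take_lo, lo, hi)
  }

  chosen <- integer(n)
  t_drawn <- numeric(n)
  if (min_separation_px > 0) {
    occupied <- new.env(hash = TRUE, size = max(1024L, 2L * n))
    s <- as.integer(min_separation_px)
    off <- as.matrix(expand.grid(x = -(s - 1L):(s - 1L),
                                 y = -(s - 1L):(s - 1L),
                                 z = -(s - 1L):(s - 1L)))
    for (i in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        t <- -scale * log(1 - stats::runif(1) * trunc_mass)
        cand <- cand_for(nearest_bin_pos(as.integer(ceiling(t))))
        v <- cand[sample.int(length(cand), 1L)]
        ci <- arrayInd(v, dims)
        keys <- sprintf("%d_%d_%d", ci[1] + off[, 1], ci[2] + off[, 2],
                        ci[3] + off[, 3])
        if (!any(vapply(keys, exists, logical(1), envir = occupied,
                        inherits = FALSE))) {
          assign(sprintf("%d_%d_%d", ci[1], ci[2], ci[3]), TRUE,
                 envir = occupied)
          chosen[i] <- v
          t_drawn[i] <- t
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place particles at the requested separation; lower the density")
    }
  } else if (n > 0) {
    t_drawn <- -scale * log(1 - stats::runif(n) * trunc_mass)  # truncated exp
    b <- nearest_bin_pos(as.integer(ceiling(t_drawn)))
    for (bu in unique(b)) {
      sel <- which(b == bu)
      cand <- cand_for(bu)
      chosen[sel] <- cand[sample.int(length(cand), length(sel),
                                     replace = TRUE)]
    }
  }

  idx <- arrayInd(chosen, dims)
  r_rng <- spec$particle_radius_um_range
  out <- data.frame(
    center_x_mm = kidney_mask$origin_mm[1] + (idx[, 1] - 0.5) * sp,
    center_y_mm = kidney_mask$origin_mm[2] + (idx[, 2] - 0.5) * sp,
    center_z_mm = kidney_mask$origin_mm[3] + (idx[, 3] - 0.5) * sp,
    radius_um = stats::runif(n, r_rng[1], r_rng[2]),
    depth_px = dist[chosen],
    depth_drawn_px = t_drawn,
    vx = idx[, 1], vy = idx[, 2], vz = idx[, 3])
  class(out) <- c("particle_set", "data.frame")
  out
}

#' Render particles into an intensity volume
#'
#' Voxels whose centers fall inside any particle sphere get
#' `particle_intensity`; every particle additionally marks at least the
#' voxel containing its center, so sub-voxel 75-100 um beads at 0.1 mm
#' spacing remain detectable. All other voxels get `background_intensity`.
#'
#' @param particles a `particle_set` from [sample_particles()].
#' @param grid_shape integer 3-vector.
#' @param spacing_mm voxel spacing (mm).
#' @param spec a [phantom_spec()] (intensity levels).
#' @param origin_mm grid origin.
#' @return A [volume3d()].
#' @export
rasterize_particles <- function(particles, grid_shape, spacing_mm, spec,
                                origin_mm = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid_shape <- as.integer(grid_shape)
  vol <- array(spec$background_intensity, grid_shape)
  n <- nrow(particles)
  if (n == 0)
    return(volume3d(vol, spacing_mm, origin_mm))
  ctr <- cbind(particles$center_x_mm, particles$center_y_mm,
               particles$center_z_mm)
  home <- floor(sweep(ctr, 2, origin_mm) / spacing_mm) + 1
  if (any(home < 1) || any(sweep(home, 2, grid_shape) > 0))
    stop("particle center outside the grid")
  r_vox <- particles$radius_um / 1000 / spacing_mm
  big <- which(r_vox >= 0.5)          # may cover neighbors' centers
  # fast path: sub-voxel particles mark exactly their containing voxel
  vol[home[setdiff(seq_len(n), big), , drop = FALSE]] <- spec$particle_intensity
  for (i in big) {
    r <- r_vox[i]
    c_vox <- (ctr[i, ] - origin_mm) / spacing_mm + 0.5  # fractional index
    lo <- pmax(1L, as.integer(floor(c_vox - r)))
    hi <- pmin(grid_shape, as.integer(ceiling(c_vox + r)))
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    d2 <- outer(outer((gx - c_vox[1])^2, (gy - c_vox[2])^2, "+"),
                (gz - c_vox[3])^2, "+")
    sub <- vol[gx, gy, gz, drop = FALSE]
    sub[d2 <= r^2] <- spec$particle_intensity
    vol[gx, gy, gz] <- sub
    vol[home[i, , drop = FALSE]] <- spec$particle_intensity
  }
  new_volume3d(vol, spacing_mm, as.numeric(origin_mm))
}

#' Add Gaussian CT noise
#'
#' Independent zero-mean Gaussian noise, clamped at zero (CT intensities are
#' non-negative). Deterministic under a fixed seed.
#'
#' @param volume a [volume3d()].
#' @param sigma noise standard deviation (intensity units), >= 0.
#' @return A [volume3d()].
#' @export
add_ct_noise <- function(volume, sigma) {
  stopifnot(inherits(volume, "volume3d"))
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(volume)
  new_volume3d(.add_noise_cpp(volume$data, sigma), volume$spacing_mm,
               volume$origin_mm)
}
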