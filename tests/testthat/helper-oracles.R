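# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# Brute-force nearest-background Euclidean distance for every voxel:
# pairwise distances between foreground and background voxel centers.
brute_force_edt <- function(mask_array) {
  dims <- dim(mask_array)
  out <- array(0, dims)
  fg <- which(mask_array)
  bg <- which(!mask_array)
  if (!length(fg) || !length(bg)) return(out)
  cf <- arrayInd(fg, dims)
  cb <- arrayInd(bg, dims)
  for (i in seq_along(fg)) {
    d2 <- (cb[, 1] - cf[i, 1])^2 + (cb[, 2] - cf[i, 2])^2 +
          (cb[, 3] - cf[i, 3])^2
    out[fg[i]] <- sqrt(min(d2))
  }
  out
}

# Brute-force Euclidean-ball erosion: a foreground voxel survives iff no
# in-grid background voxel center lies within distance d of its center.
brute_force_ball_erosion <- function(mask_array, d) {
  dims <- dim(mask_array)
  out <- array(FALSE, dims)
  fg <- which(mask_array)
  bg <- which(!mask_array)
  if (!length(fg)) return(out)
  if (!length(bg)) { out[fg] <- TRUE; return(out) }
  cf <- arrayInd(fg, dims)
  cb <- arrayInd(bg, dims)
  for (i in seq_along(fg)) {
    d2 <- (cb[, 1] - cf[i, 1])^2 + (cb[, 2] - cf[i, 2])^2 +
          (cb[, 3] - cf[i, 3])^2
    out[fg[i]] <- min(d2) > d^2
  }
  out
}

# Positive-direction neighbor offsets for a connectivity (half of the full
# neighborhood; unions are symmetric).
half_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  m <- rowSums(abs(off))
  keep <- m > 0 & switch(as.character(connectivity),
                         "6" = m <= 1, "18" = m <= 2, "26" = m <= 3)
  off <- off[keep, , drop = FALSE]
  # keep one of each +/- pair (lexicographically positive)
  pos <- off[, 3] > 0 | (off[, 3] == 0 &
           (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0)))
  off[pos, , drop = FALSE]
}

# Union-find connected components, built from vectorized adjacent-pair
# lists; returns a root id per voxel (0 for background).
union_find_components <- function(mask_array, connectivity) {
  dims <- dim(mask_array)
  n <- length(mask_array)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]   # path halving
      i <- parent[i]
    }
    i
  }
  offs <- half_offsets(connectivity)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    rx <- max(1, 1 - o[1]):min(dims[1], dims[1] - o[1])
    ry <- max(1, 1 - o[2]):min(dims[2], dims[2] - o[2])
    rz <- max(1, 1 - o[3]):min(dims[3], dims[3] - o[3])
    a <- mask_array[rx, ry, rz, drop = FALSE]
    b <- mask_array[rx + o[1], ry + o[2], rz + o[3], drop = FALSE]
    both <- which(a & b)
    if (!length(both)) next
    ci <- arrayInd(both, dim(a))
    ci[, 1] <- ci[, 1] + rx[1] - 1L
    ci[, 2] <- ci[, 2] + ry[1] - 1L
    ci[, 3] <- ci[, 3] + rz[1] - 1L
    ia <- ci[, 1] + (ci[, 2] - 1L) * dims[1] +
          (ci[, 3] - 1L) * dims[1] * dims[2]
    ib <- ia + o[1] + o[2] * dims[1] + o[3] * dims[1] * dims[2]
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- integer(n)
  fg <- which(mask_array)
  for (v in fg) roots[v] <- find(v)
  roots
}

# TRUE iff two labelings of the same mask induce the same partition.
same_partition <- function(labels_a, labels_b, mask_array) {
  fg <- which(mask_array)
  a <- labels_a[fg]; b <- labels_b[fg]
  pairs <- unique(paste(a, b))
  length(pairs) == length(unique(a)) && length(pairs) == length(unique(b))
}

# Literal 2^n enumeration of the signed-rank null (independent of the
# package's convolution implementation).
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all) >= abs(w) - 1e-9)
}

# Truncated exponential (scale s, truncated at L): closed-form mean and CDF.
trunc_exp_mean <- function(s, L) s - L * exp(-L / s) / (1 - exp(-L / s))
trunc_exp_cdf <- function(t, s, L) (1 - exp(-t / s)) / (1 - exp(-L / s))

# Random blob-ish logical array (union of a few balls plus salt), used for
# morphology property tests.
random_mask <- function(dims, p = 0.35) {
  array(stats::runif(prod(dims)) < p, dims)
}
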