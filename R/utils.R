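# internal numeric helpers

# Gaussian blur with sigma in micrometres, separable, spacing-aware.
gauss_blur3d <- function(arr, sigma_um, spacing) {
  if (sigma_um <= 0) return(arr)
  d <- dim(arr)
  out <- as.numeric(arr)
  for (axis in 1:3) {
    s_vox <- sigma_um / spacing[axis]
    r <- max(1L, ceiling(3 * s_vox))
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    k <- k / sum(k)
    out <- cpp_conv1d(out, d, k, axis - 1L)
  }
  array(out, dim = d)
}

# 3-D median filter, radius in voxels per axis
median_filter3d <- function(arr, radius = c(1L, 1L, 1L)) {
  radius <- rep_len(as.integer(radius), 3L)
  array(cpp_median3d(as.numeric(arr), dim(arr), radius[1], radius[2], radius[3]),
        dim = dim(arr))
}

# rescale an array to [0, 1]; constant arrays map to 0
rescale01 <- function(arr) {
  rng <- range(arr)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(arr)))
  (arr - rng[1]) / (rng[2] - rng[1])
}

# Euclidean distance transform: per voxel, micrometre distance to the
# nearest TRUE voxel
edt3d <- function(mask, spacing) {
  array(sqrt(cpp_edt3d(as.logical(mask), dim(mask), as.numeric(spacing))),
        dim = dim(mask))
}

# mirror of C++ lround (round half away from zero)
lround_r <- function(x) trunc(x + 0.5 * sign(x))

# deterministic sub-seed derivation (keeps values well below 2^31)
sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 97 + as.numeric(k) * 7919) %% 2000000011)

# voxel index grid (0-based) for an array dimension, as n x 3 matrix rows
# expand over a bounding box
box_coords <- function(lo, hi) {
  as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
}
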