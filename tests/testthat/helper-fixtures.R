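# deterministic fixture builders used across the suite

make_image <- function(values, dims = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dims)) dims <- dim(values)
  volume_image(array(values, dims), spacing)
}

make_mask <- function(values, dims = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dims)) dims <- dim(values)
  seg_mask(array(values, dims), spacing)
}

# a random gray-level image with a random mask, 6 x 6 x 4 by default
random_masked_scan <- function(seed, dims = c(6, 6, 4), p_mask = 0.7,
                               spacing = c(1, 1, 1)) {
  set.seed(seed)
  img <- make_image(stats::runif(prod(dims)), dims, spacing)
  msk <- make_mask(stats::rbinom(prod(dims), 1, p_mask), dims, spacing)
  if (sum(msk$data) < 8) msk$data[1:8] <- 1L
  list(image = img, mask = msk)
}

# digitized ellipsoid mask, semi-axes in mm
ellipsoid_mask <- function(semi_axes, spacing = c(1, 1, 1), margin = 4) {
  dims <- as.integer(ceiling(2 * semi_axes / spacing)) + 2L * margin
  ctr <- (dims + 1) / 2
  co <- arrayInd(seq_len(prod(dims)), dims)
  r2 <- ((co[, 1] - ctr[1]) * spacing[1] / semi_axes[1])^2 +
    ((co[, 2] - ctr[2]) * spacing[2] / semi_axes[2])^2 +
    ((co[, 3] - ctr[3]) * spacing[3] / semi_axes[3])^2
  m <- array(0L, dims)
  m[r2 <= 1] <- 1L
  seg_mask(m, spacing)
}

# axis-aligned box mask with the given extent in voxels
box_mask <- function(extent_vox, spacing = c(1, 1, 1), margin = 2L) {
  dims <- as.integer(extent_vox) + 2L * margin
  m <- array(0L, dims)
  m[(margin + 1):(margin + extent_vox[1]),
    (margin + 1):(margin + extent_vox[2]),
    (margin + 1):(margin + extent_vox[3])] <- 1L
  seg_mask(m, spacing)
}

# small synthetic cohort for the statistics tests
small_cohort <- function(seed = 1, n = 120, pandemic_fraction = 0.5, ...) {
  generate_cohort(synth_config(n_subjects = n,
                               pandemic_fraction = pandemic_fraction,
                               seed = seed, ...))
}
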