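# Shared fixtures, built in code. The sphere/slab rasterizers here are
# deliberately written independently of the phantom generator so they can
# serve as oracles for it.

# digitized ball: voxel centre inside radius r (mm), centred in a padded grid
digit_sphere_mask <- function(r, spacing = c(1, 1, 1.25), pad = 6L) {
  n <- ceiling(2 * r / spacing) + 2L * pad
  ctr <- (n - 1) * spacing / 2
  x <- (seq_len(n[1]) - 1) * spacing[1]
  y <- (seq_len(n[2]) - 1) * spacing[2]
  z <- (seq_len(n[3]) - 1) * spacing[3]
  d2 <- outer(outer((x - ctr[1])^2, (y - ctr[2])^2, "+"), (z - ctr[3])^2, "+")
  array(d2 <= r^2, n)
}

# axis-aligned slab of nx x ny voxels, one voxel thick, in a padded grid
slab_mask <- function(nx = 20L, ny = 20L, spacing = c(1, 1, 1.25), pad = 4L) {
  d <- c(nx + 2L * pad, ny + 2L * pad, 2L * pad + 1L)
  m <- array(FALSE, d)
  m[pad + seq_len(nx), pad + seq_len(ny), pad + 1L] <- TRUE
  m
}

# density volume built directly from an array of densities
make_density <- function(rho, spacing = c(1, 1, 1.25)) {
  v <- scan_volume(array(as.integer(round(rho + 1024)), dim(rho)), spacing)
  density_volume(v)
}

# canonical partition of a label array: list of sorted voxel-index vectors,
# ordered by smallest member, for label-renaming-invariant comparison
canonical_partition <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  sets <- lapply(ids, function(i) sort(which(labels == i)))
  sets[order(vapply(sets, min, 1L))]
}

# random cheese-like binary mask for oracle equivalence checks
random_mask <- function(d = c(20L, 20L, 20L), p = 0.62) {
  m <- array(stats::runif(prod(d)) < p, d)
  m[10, 10, 10] <- TRUE  # guarantee a wheel seed
  binary_mask(m, spacing = c(1, 1, 1.25))
}

run_wheel <- function(vol, config = pipeline_config()) {
  analyze_scan(vol, config)$summary
}

# match detected cavities to ground-truth spheres by centroid proximity;
# returns the truth row index for each catalog row (NA if unmatched)
match_spheres <- function(catalog, truth) {
  sph <- truth$features[truth$features$class == "sphere", , drop = FALSE]
  if (nrow(catalog) == 0L) return(integer(0))
  vapply(seq_len(nrow(catalog)), function(i) {
    p <- c(catalog$centroid_x_mm[i], catalog$centroid_y_mm[i],
           catalog$centroid_z_mm[i])
    dd <- sqrt((sph$cx_mm - p[1])^2 + (sph$cy_mm - p[2])^2 +
                 (sph$cz_mm - p[3])^2)
    j <- which.min(dd)
    if (length(j) && dd[j] <= pmax(sph$r_mm[j], 2)) j else NA_integer_
  }, integer(1))
}
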