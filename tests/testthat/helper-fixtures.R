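# Build a small voxel_grid from a matrix of 0-based voxel indices.
grid_from_voxels <- function(voxels, dims = c(8, 8, 8),
                             spacing = c(1, 1, 1)) {
  v <- array(0L, dims)
  if (length(voxels)) {
    voxels <- rbind(voxels)
    v[voxels + 1L] <- 1L
  }
  voxel_grid(v, spacing)
}

# Random sparse binary mask.
random_mask <- function(dims, p = 0.02, spacing = c(1, 1, 1)) {
  voxel_grid(array(as.integer(runif(prod(dims)) < p), dims), spacing)
}

# A single-group simulation configuration on a small grid, for fast
# cohort-level tests.
small_sim_config <- function(n = 10, grid = 48L, ...) {
  sim_config(n = n, grid_shape = rep(grid, 3L), ...)
}

one_group_config <- function(n, grid = 64L, p_no_wml = 0, ...) {
  g <- data.frame(label = "G", fraction = 1, count_log_rate_offset = 0,
                  wml_pct_mean = 0.6, wml_sdlog = 0.7, age_mean = 74,
                  age_sd = 8, p_female = 0.5, p_amyloid_pos = 0.4,
                  p_apoe4 = 0.35, p_no_wml = p_no_wml,
                  stringsAsFactors = FALSE)
  sim_config(n = n, grid_shape = rep(grid, 3L), groups = g, ...)
}

# Brute-force boundary: foreground voxels with at least one background
# (or out-of-bounds) face neighbor. Independent of erode_cross.
naive_boundary <- function(mask) {
  v <- mask$values
  d <- dim(v)
  out <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (v[i, j, k] == 0L) next
    nb <- c(
      if (i > 1) v[i - 1, j, k] else 0L,
      if (i < d[1]) v[i + 1, j, k] else 0L,
      if (j > 1) v[i, j - 1, k] else 0L,
      if (j < d[2]) v[i, j + 1, k] else 0L,
      if (k > 1) v[i, j, k - 1] else 0L,
      if (k < d[3]) v[i, j, k + 1] else 0L)
    if (any(nb == 0L)) out[i, j, k] <- 1L
  }
  voxel_grid(out, mask$spacing)
}

# Step-up FDR definition, written directly from the formula.
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

write_tiny_manifest <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE, na = "")
  path
}
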