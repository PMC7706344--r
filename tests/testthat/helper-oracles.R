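# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: occupancy is
# counted by explicit triple loops over cells, histograms by interval
# scans, interception by a hand-stepped ledger.

# Voxel occupancy by triple-nested loop over all cells with half-open
# interval membership tests.
brute_3dvi <- function(cloud, rect, ground, voxel_size = 0.05,
                       ground_band = ground$bin_width) {
  z0 <- ground$ground_z
  keep <- cloud$z >= z0 + ground_band
  x <- cloud$x[keep]; y <- cloud$y[keep]; z <- cloud$z[keep]
  if (length(z) == 0) return(0)
  nx <- ceiling((rect$x_max - rect$x_min) / voxel_size)
  ny <- ceiling((rect$y_max - rect$y_min) / voxel_size)
  nz <- floor((max(z) - z0) / voxel_size) + 1
  occupied <- 0
  for (ix in seq_len(nx) - 1) {
    for (iy in seq_len(ny) - 1) {
      for (iz in seq_len(nz) - 1) {
        inside <- x >= rect$x_min + ix * voxel_size &
          x < rect$x_min + (ix + 1) * voxel_size &
          y >= rect$y_min + iy * voxel_size &
          y < rect$y_min + (iy + 1) * voxel_size &
          z >= z0 + iz * voxel_size &
          z < z0 + (iz + 1) * voxel_size
        if (any(inside)) occupied <- occupied + 1
      }
    }
  }
  occupied / (nx * ny * nz)
}

# Sequential interception profile by an explicit top-down ledger.
brute_3dpi <- function(cloud, ground, layer = 0.01, beams_total = nrow(cloud),
                       ground_band = ground$bin_width) {
  z0 <- ground$ground_z
  z <- cloud$z[cloud$z >= z0 + ground_band]
  if (length(z) == 0) return(0)
  n_layers <- floor((max(z) - z0) / layer) + 1
  total <- 0
  remaining <- beams_total
  for (k in n_layers:1) {
    lo <- z0 + (k - 1) * layer
    hi <- z0 + k * layer
    cnt <- sum(z >= lo & z < hi)
    if (k == n_layers) cnt <- sum(z >= lo)   # top layer is half-open upward
    if (cnt > 0 && remaining > 0) {
      total <- total + cnt / remaining
      remaining <- remaining - cnt
    }
  }
  total
}

# Modal-bin ground elevation by an explicit interval scan.
brute_ground <- function(z, bin_width) {
  z0 <- floor(min(z) / bin_width) * bin_width
  best_count <- -1
  best_lo <- NA
  k <- 0
  while (z0 + k * bin_width <= max(z)) {
    lo <- z0 + k * bin_width
    cnt <- sum(z >= lo & z < lo + bin_width)
    if (cnt > best_count) {       # strict > keeps the lowest bin on ties
      best_count <- cnt
      best_lo <- lo
    }
    k <- k + 1
  }
  mean(z[z >= best_lo & z < best_lo + bin_width])
}

# Point-in-rectangle filter, one point at a time.
brute_segment <- function(cloud, rect) {
  keep <- logical(nrow(cloud))
  for (i in seq_len(nrow(cloud))) {
    keep[i] <- cloud$x[i] >= rect$x_min && cloud$x[i] < rect$x_max &&
      cloud$y[i] >= rect$y_min && cloud$y[i] < rect$y_max
  }
  keep
}

# One-way balanced ANOVA variance components from expected mean squares.
ems_oneway <- function(values, groups) {
  n <- length(values) / length(unique(groups))
  gm <- tapply(values, groups, mean)
  msb <- n * sum((gm - mean(values))^2) / (length(gm) - 1)
  msw <- sum((values - gm[groups])^2) / (length(values) - length(gm))
  list(sigma2_g = max((msb - msw) / n, 0), sigma2_e = msw)
}

# Random small point cloud over a given rectangle.
random_cloud <- function(n, rect, z_max = 0.6) {
  point_cloud(stats::runif(n, rect$x_min, rect$x_max),
              stats::runif(n, rect$y_min, rect$y_max),
              stats::runif(n, 0, z_max))
}

# Small helper design for statistics tests (no geometry needed).
grid_design <- function(genotypes, reps) {
  g <- rep(genotypes, each = reps)
  n <- length(g)
  ncol_f <- ceiling(sqrt(n))
  d <- data.frame(plot_id = sprintf("p%03d", seq_len(n)),
                  genotype = sample(g),
                  row = (seq_len(n) - 1) %/% ncol_f + 1,
                  col = (seq_len(n) - 1) %% ncol_f + 1,
                  stringsAsFactors = FALSE)
  d
}
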