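# LiDAR biomass indices: 3D voxel index (3DVI) and 3D profile index (3DPI).

#' 3D voxel index of a plot
#'
#' The plot's bounding volume — the rectangle footprint from the ground
#' elevation up to the highest canopy return — is divided into cubic voxels
#' (0.05 m by default). 3DVI is the number of voxels containing at least
#' one canopy return divided by the total number of voxels.
#'
#' The voxel grid is anchored at `(x_min, y_min, ground_z)`; cells are
#' half-open, so a point exactly on a voxel boundary belongs to the
#' higher-index voxel, and the top voxel layer is included even when
#' partial. Returns within `ground_band` of the ground elevation are
#' treated as soil and ignored.
#'
#' @param cloud a [point_cloud] segmented to the plot.
#' @param rect the plot's [plot_rect].
#' @param ground a `ground_model` from [estimate_ground()].
#' @param voxel_size voxel edge length in metres (default 0.05).
#' @param ground_band height above `ground_z` below which returns count as
#'   soil; defaults to the ground model's bin width.
#' @return the index, in `(0, 1]`; a bare plot (no canopy returns) yields 0
#'   with a warning rather than an error.
#' @references The voxel-occupancy construction follows the 3DVI of
#'   ground-based phenotyping platforms for cereal canopies.
#' @export
compute_3dvi <- function(cloud, rect, ground, voxel_size = 0.05,
                         ground_band = ground$bin_width) {
  stopifnot(inherits(cloud, "point_cloud"))
  validate_rect(rect)
  assert_scalar_num(voxel_size, "voxel_size", positive = TRUE)
  z0 <- ground$ground_z
  canopy <- cloud[cloud$z >= z0 + ground_band, , drop = FALSE]
  if (nrow(canopy) == 0) {
    warn_pheno("no canopy returns above the ground band; 3DVI = 0",
               "phenolidar_bare_plot")
    return(0)
  }
  nx <- ceiling((rect$x_max - rect$x_min) / voxel_size)
  ny <- ceiling((rect$y_max - rect$y_min) / voxel_size)
  nz <- floor((max(canopy$z) - z0) / voxel_size) + 1L
  ix <- pmin(floor((canopy$x - rect$x_min) / voxel_size), nx - 1L)
  iy <- pmin(floor((canopy$y - rect$y_min) / voxel_size), ny - 1L)
  iz <- floor((canopy$z - z0) / voxel_size)
  occupied <- length(unique(ix + nx * (iy + ny * iz)))
  occupied / (nx * ny * nz)
}

#' 3D profile index of a plot
#'
#' The canopy volume from the ground elevation to the maximum crop height
#' is sliced into horizontal layers (0.01 m by default) and the index sums,
#' over layers, the fraction of beams intercepted in each layer.
#'
#' Two readings of "fractional number of points intercepted" are provided:
#'
#' * `"interception"` (default): layers are processed top-down and each
#'   layer's fraction is the returns in that layer divided by the beams not
#'   yet intercepted above it — a sequential gap-fraction profile. The sum
#'   can exceed 1 for dense canopies.
#' * `"fraction_of_total"`: each layer's fraction is its returns divided by
#'   the total number of returns (ground included). The sum over canopy
#'   layers then collapses to the canopy-return fraction and is bounded by
#'   1; it is retained for comparison but carries no vertical structure.
#'
#' @param cloud a [point_cloud] segmented to the plot.
#' @param ground a `ground_model` from [estimate_ground()].
#' @param layer layer thickness in metres (default 0.01).
#' @param variant `"interception"` or `"fraction_of_total"`.
#' @param beams_total number of emitted beams; defaults to the number of
#'   returns in the cloud (one return per beam).
#' @param ground_band height above `ground_z` below which returns count as
#'   soil (unintercepted); defaults to the ground model's bin width.
#' @return the index, `>= 0`; 0 for a bare plot.
#' @export
compute_3dpi <- function(cloud, ground, layer = 0.01,
                         variant = c("interception", "fraction_of_total"),
                         beams_total = NULL,
                         ground_band = ground$bin_width) {
  stopifnot(inherits(cloud, "point_cloud"))
  variant <- match.arg(variant)
  assert_scalar_num(layer, "layer", positive = TRUE)
  if (is.null(beams_total)) beams_total <- nrow(cloud)
  z0 <- ground$ground_z
  canopy_z <- cloud$z[cloud$z >= z0 + ground_band]
  if (length(canopy_z) == 0) return(0)
  if (variant == "interception" && beams_total < 1) {
    stop_pheno("interception variant needs beams_total >= 1",
               "phenolidar_validation_error")
  }
  n_layers <- floor((max(canopy_z) - z0) / layer) + 1L
  li <- floor((canopy_z - z0) / layer)          # 0 = bottom layer
  counts <- tabulate(li + 1L, nbins = n_layers)
  if (variant == "fraction_of_total") {
    return(sum(counts) / nrow(cloud))
  }
  remaining <- beams_total
  total <- 0
  for (k in rev(seq_len(n_layers))) {           # top-down
    if (counts[k] == 0) next
    if (remaining <= 0) break
    total <- total + counts[k] / remaining
    remaining <- remaining - counts[k]
  }
  total
}
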