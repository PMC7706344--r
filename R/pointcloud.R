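# Point-cloud containers, I/O, plot segmentation, ground elevation and
# crop height.

#' Construct a point cloud
#'
#' A point cloud is a data frame of 3D LiDAR returns in field coordinates
#' (metres, z up). An optional `beam_id` column identifies the emitting
#' beam, which the synthetic scanner uses to guarantee one return per beam.
#'
#' @param x,y,z numeric vectors of equal length, coordinates in metres.
#' @param beam_id optional integer vector of beam identifiers.
#' @return a data frame of class `point_cloud` with columns `x`, `y`, `z`
#'   (and `beam_id` when supplied).
#' @examples
#' pc <- point_cloud(x = c(0, 1), y = c(0, 0), z = c(0.1, 0.8))
#' nrow(pc)
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        beam_id = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop_pheno("x, y, z must have equal lengths", "phenolidar_validation_error")
  }
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))) {
    stop_pheno("point coordinates must all be finite",
               "phenolidar_validation_error")
  }
  cloud <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!is.null(beam_id)) {
    if (length(beam_id) != n) {
      stop_pheno("beam_id length must match coordinates",
                 "phenolidar_validation_error")
    }
    cloud$beam_id <- as.integer(beam_id)
  }
  class(cloud) <- c("point_cloud", "data.frame")
  cloud
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d returns", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", z in [%.3f, %.3f] m", min(x$z), max(x$z)))
  }
  cat(">\n")
  invisible(x)
}

#' Read a point cloud from disk
#'
#' Supports the XYZ CSV interchange format (header `x,y,z`, metres) and
#' LAS 1.2 point format 0.
#'
#' @param path path to the file.
#' @param format `"xyz_csv"` or `"las"`.
#' @return a [point_cloud].
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("xyz_csv", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_pheno(sprintf("file not found: %s", path), "phenolidar_io_error")
  }
  if (format == "xyz_csv") {
    read_cloud_csv(path)
  } else {
    read_las(path)
  }
}

read_cloud_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(raw))) {
    stop_pheno(sprintf("CSV must have columns x,y,z (found: %s)",
                       paste(names(raw), collapse = ",")),
               "phenolidar_parse_error")
  }
  cols <- lapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      # +1 for the header line so the message points at the file line
      stop_pheno(sprintf("non-numeric %s value at line %d of %s",
                         cn, bad[1] + 1L, path),
                 "phenolidar_parse_error")
    }
    v
  })
  point_cloud(cols[[1]], cols[[2]], cols[[3]])
}

#' Write a point cloud to disk
#'
#' @param cloud a [point_cloud].
#' @param path output path.
#' @param format `"xyz_csv"` or `"las"` (LAS 1.2, point format 0,
#'   millimetre scale).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("xyz_csv", "las")) {
  format <- match.arg(format)
  if (format == "xyz_csv") {
    utils::write.csv(cloud[, c("x", "y", "z")], path, row.names = FALSE,
                     quote = FALSE)
  } else {
    write_las(cloud, path)
  }
  invisible(path)
}

# --- Minimal LAS 1.2 (point data record format 0) reader/writer ----------
# Fixed-layout binary records; coordinates stored as scaled 32-bit
# integers. Only the fields needed for xyz interchange are handled.

LAS_HEADER_SIZE <- 227L
LAS_POINT_SIZE <- 20L

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) {
    stop_pheno(sprintf("not a LAS file (bad signature): %s", path),
               "phenolidar_format_error")
  }
  seek(con, 24)
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", size = 4)
  seek(con, 104)
  pt_format <- readBin(con, "integer", size = 1, signed = FALSE)
  rec_len <- readBin(con, "integer", size = 2, signed = FALSE)
  n_points <- readBin(con, "integer", size = 4)
  if (pt_format != 0L) {
    stop_pheno(sprintf("unsupported LAS point format %d (only 0)", pt_format),
               "phenolidar_format_error")
  }
  seek(con, 131)
  scale <- readBin(con, "double", n = 3, size = 8)
  off <- readBin(con, "double", n = 3, size = 8)
  seek(con, offset_to_points)
  xyz <- matrix(NA_real_, nrow = n_points, ncol = 3)
  for (i in seq_len(n_points)) {
    rec <- readBin(con, "integer", n = 3, size = 4)
    xyz[i, ] <- rec * scale + off
    if (rec_len > 12L) readBin(con, "raw", n = rec_len - 12L)
  }
  point_cloud(xyz[, 1], xyz[, 2], xyz[, 3])
}

write_las <- function(cloud, path, scale = c(0.001, 0.001, 0.001)) {
  n <- nrow(cloud)
  off <- if (n > 0) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, nchars = 4, eos = NULL)
  writeBin(rep(as.raw(0), 20), con)                 # source id .. project id
  writeBin(as.raw(c(1, 2)), con)                    # version 1.2
  writeBin(rep(as.raw(0), 64), con)                 # system id + software
  writeBin(as.integer(c(1, 2026)), con, size = 2)   # day of year, year
  writeBin(as.integer(LAS_HEADER_SIZE), con, size = 2)
  writeBin(as.integer(LAS_HEADER_SIZE), con, size = 4)  # offset to points
  writeBin(0L, con, size = 4)                       # number of VLRs
  writeBin(as.raw(0), con)                          # point format 0
  writeBin(as.integer(LAS_POINT_SIZE), con, size = 2)
  writeBin(as.integer(n), con, size = 4)
  writeBin(as.integer(c(n, 0, 0, 0, 0)), con, size = 4)  # returns by number
  writeBin(as.numeric(scale), con, size = 8)
  writeBin(as.numeric(off), con, size = 8)
  rng <- function(v) if (n > 0) c(max(v), min(v)) else c(0, 0)
  writeBin(c(rng(cloud$x), rng(cloud$y), rng(cloud$z)), con, size = 8)
  tail_bytes <- as.raw(rep(0, LAS_POINT_SIZE - 12L))
  for (i in seq_len(n)) {
    rec <- as.integer(round((c(cloud$x[i], cloud$y[i], cloud$z[i]) - off) /
                              scale))
    writeBin(rec, con, size = 4)
    writeBin(tail_bytes, con)
  }
  invisible(path)
}

# --- Segmentation ---------------------------------------------------------

#' Extract the returns falling inside a plot rectangle
#'
#' Uses a half-open convention: points with `x_min <= x < x_max` and
#' `y_min <= y < y_max` are kept, so adjacent plots in a tiling never share
#' a point. The input cloud is never modified.
#'
#' @param cloud a [point_cloud].
#' @param rect a [plot_rect] (or any list with `x_min`, `x_max`, `y_min`,
#'   `y_max` in metres).
#' @return the subset [point_cloud]. When no point falls inside, an empty
#'   cloud is returned with a `phenolidar_empty_plot` warning so callers can
#'   distinguish a bare plot from an I/O failure.
#' @export
segment_plot <- function(cloud, rect) {
  stopifnot(inherits(cloud, "point_cloud"))
  validate_rect(rect)
  keep <- cloud$x >= rect$x_min & cloud$x < rect$x_max &
    cloud$y >= rect$y_min & cloud$y < rect$y_max
  out <- cloud[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("point_cloud", "data.frame")
  if (nrow(out) == 0) {
    warn_pheno(sprintf("no returns inside plot rectangle [%g,%g)x[%g,%g)",
                       rect$x_min, rect$x_max, rect$y_min, rect$y_max),
               "phenolidar_empty_plot")
  }
  out
}

#' Plot rectangle
#'
#' Describes the sampled section of an experimental plot: its rectangle in
#' field coordinates plus the row geometry that determines the ground area
#' sampled (`n_rows * row_spacing * sampled_length`).
#'
#' @param x_min,x_max,y_min,y_max rectangle bounds, metres.
#' @param n_rows number of crop rows in the section.
#' @param row_spacing spacing between rows, metres.
#' @param sampled_length length of the section along the rows, metres.
#' @return a list of class `plot_rect`.
#' @examples
#' # a 6-row, 0.18 m spacing, 1 m long section: 1.08 m2
#' r <- plot_rect(0, 1.08, 0, 1, n_rows = 6, row_spacing = 0.18,
#'                sampled_length = 1)
#' sampled_area(r)
#' @export
plot_rect <- function(x_min, x_max, y_min, y_max,
                      n_rows = 6L, row_spacing = 0.18, sampled_length = 1.0) {
  rect <- list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
               n_rows = as.integer(n_rows), row_spacing = row_spacing,
               sampled_length = sampled_length)
  class(rect) <- "plot_rect"
  validate_rect(rect)
  rect
}

validate_rect <- function(rect) {
  for (f in c("x_min", "x_max", "y_min", "y_max")) {
    assert_scalar_num(rect[[f]], f)
  }
  if (rect$x_min >= rect$x_max || rect$y_min >= rect$y_max) {
    stop_pheno("plot rectangle must have x_min < x_max and y_min < y_max",
               "phenolidar_validation_error")
  }
  if (!is.null(rect$n_rows)) {
    if (rect$n_rows < 1 || rect$row_spacing <= 0 || rect$sampled_length <= 0) {
      stop_pheno("plot geometry must give a positive sampled area",
                 "phenolidar_validation_error")
    }
  }
  invisible(rect)
}

#' Ground area sampled by a plot section
#'
#' @param rect a [plot_rect].
#' @return area in square metres (`n_rows * row_spacing * sampled_length`).
#' @export
sampled_area <- function(rect) {
  rect$n_rows * rect$row_spacing * rect$sampled_length
}

# --- Ground elevation -----------------------------------------------------

#' Estimate ground elevation from pooled point clouds
#'
#' Ground elevation is taken as the mode of the height distribution: z
#' values are binned at `bin_width`, the modal bin is located (ties broken
#' toward the lower bin), and the ground elevation is the mean z of the
#' returns in that bin — the average of the soil returns. Clouds from a
#' whole column of plots are normally pooled so the soil mode dominates.
#'
#' @param clouds a [point_cloud] or a list of them (typically all plots in
#'   one field column).
#' @param bin_width histogram bin width in metres (default 0.01).
#' @return a list of class `ground_model` with `ground_z`, `bin_width` and
#'   `n_ground_points`.
#' @export
estimate_ground <- function(clouds, bin_width = 0.01) {
  assert_scalar_num(bin_width, "bin_width", positive = TRUE)
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  z <- unlist(lapply(clouds, function(cl) cl$z), use.names = FALSE)
  if (length(z) < 1) {
    stop_pheno("cannot estimate ground from zero points",
               "phenolidar_validation_error")
  }
  z0 <- floor(min(z) / bin_width) * bin_width
  idx <- floor((z - z0) / bin_width)
  counts <- table(idx)
  best <- as.integer(names(counts)[which.max(counts)])  # table is sorted by
  # bin index, so which.max returns the lowest bin among ties
  in_mode <- idx == best
  structure(list(ground_z = mean(z[in_mode]),
                 bin_width = bin_width,
                 n_ground_points = sum(in_mode)),
            class = "ground_model")
}

#' @export
print.ground_model <- function(x, ...) {
  cat(sprintf("<ground_model: z = %.4f m (%d returns in modal %.0f mm bin)>\n",
              x$ground_z, x$n_ground_points, x$bin_width * 1000))
  invisible(x)
}

# --- Crop height ----------------------------------------------------------

#' Crop height of a plot
#'
#' Height is the mean of the returns at or above the 95th percentile of the
#' plot's height distribution, minus the ground elevation. The percentile is
#' computed by linear interpolation of order statistics
#' ([stats::quantile()] type 7). Returns within one ground bin of the
#' ground elevation are treated as soil and excluded before taking the
#' percentile (set `exclude_ground = FALSE` to keep them).
#'
#' Small negative heights (down to `-2 * noise_tol`), which arise from
#' measurement noise on bare plots, are clamped to zero; larger negatives
#' raise a data-quality warning.
#'
#' @param cloud a non-empty [point_cloud], already segmented to one plot.
#' @param ground a `ground_model` from [estimate_ground()].
#' @param percentile percentile defining the canopy top set (default 0.95).
#' @param exclude_ground drop returns within one bin of the ground first?
#' @param noise_tol per-return vertical noise scale in metres, used for the
#'   negative-height clamp (default 0.01).
#' @return crop height in metres, `>= 0`.
#' @export
crop_height <- function(cloud, ground, percentile = 0.95,
                        exclude_ground = TRUE, noise_tol = 0.01) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (nrow(cloud) == 0) {
    stop_pheno("cannot compute crop height of an empty cloud",
               "phenolidar_validation_error")
  }
  z <- cloud$z
  if (exclude_ground) {
    canopy <- z >= ground$ground_z + ground$bin_width
    if (any(canopy)) z <- z[canopy] else return(0)
  }
  p95 <- stats::quantile(z, percentile, type = 7, names = FALSE)
  h <- mean(z[z >= p95]) - ground$ground_z
  if (h < 0) {
    if (h >= -2 * noise_tol) {
      h <- 0
    } else {
      warn_pheno(sprintf(
        "crop height %.3f m is negative beyond noise tolerance; check ground model",
        h), "phenolidar_data_quality")
      h <- 0
    }
  }
  h
}
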