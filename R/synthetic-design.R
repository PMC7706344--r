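# Trial-design generator: randomized complete block and partial-replicate
# layouts on a field grid, with per-plot sampled rectangles.

#' Simulate a field trial design
#'
#' Generates a randomized layout of plots on a `rows x cols` field grid.
#' Two layouts are supported: a randomized complete block design (`rcbd`),
#' where every genotype appears once per replicate block, and a
#' partial-replicate design (`partial_rep`), where a fixed plot budget is
#' spread over the genotypes with replication bounded in a stated range —
#' the layout used for large germplasm panels (e.g. 98 genotypes in 240
#' plots with replication averaging 2.45, or 41 genotypes in 64 plots
#' averaging 1.6).
#'
#' @param n_genotypes number of genotypes (>= 2).
#' @param design_type `"rcbd"` or `"partial_rep"`.
#' @param replication for `rcbd`, `list(reps = <int>)`; for `partial_rep`,
#'   `list(n_plots = <int>, rep_range = c(min, max))`.
#' @param field_shape `c(rows, cols)` of the field grid; defaults to a
#'   near-square grid holding all plots.
#' @param plot_geometry list with `n_rows`, `row_spacing` (m),
#'   `sampled_length` (m), `plot_length` (m) and `path` (m between plots).
#' @param seed_density sowing density, seeds per square metre.
#' @param rng_seed integer seed; the same seed reproduces the same design.
#' @return a data frame of class `trial_design` with one row per plot:
#'   `plot_id`, `genotype`, `replicate`, `row`, `col`, the sampled
#'   rectangle (`x_min`, `x_max`, `y_min`, `y_max`), the plot geometry
#'   columns and `seed_density`.
#' @examples
#' d <- simulate_design(20, "rcbd", list(reps = 3), rng_seed = 1)
#' nrow(d)            # 60 plots
#' mean_replication(d)
#' @export
simulate_design <- function(n_genotypes,
                            design_type = c("rcbd", "partial_rep"),
                            replication = list(reps = 3),
                            field_shape = NULL,
                            plot_geometry = list(),
                            seed_density = 250,
                            rng_seed = NULL) {
  design_type <- match.arg(design_type)
  if (!is.numeric(n_genotypes) || n_genotypes < 2) {
    stop_pheno("need at least 2 genotypes for a trial design",
               "phenolidar_sizing_error")
  }
  n_genotypes <- as.integer(n_genotypes)
  geom <- utils::modifyList(
    list(n_rows = 6L, row_spacing = 0.18, sampled_length = 1.0,
         plot_length = 6.0, path = 0.4),
    plot_geometry)

  with_seed_(rng_seed, {
    genotypes <- sprintf("g%03d", seq_len(n_genotypes))
    if (design_type == "rcbd") {
      reps <- as.integer(replication$reps)
      if (is.na(reps) || reps < 1) {
        stop_pheno("rcbd replication needs list(reps = <positive int>)",
                   "phenolidar_validation_error")
      }
      n_plots <- n_genotypes * reps
      # block = replicate; genotype order randomized within each block
      geno_idx <- unlist(lapply(seq_len(reps),
                                function(b) sample.int(n_genotypes)))
      rep_no <- rep(seq_len(reps), each = n_genotypes)
    } else {
      n_plots <- as.integer(replication$n_plots)
      rr <- replication$rep_range
      if (is.null(rr)) rr <- c(1L, 4L)
      rmin <- as.integer(rr[1]); rmax <- as.integer(rr[2])
      if (is.na(n_plots) || n_plots < n_genotypes * rmin ||
          n_plots > n_genotypes * rmax) {
        stop_pheno(sprintf(
          "partial_rep budget %d incompatible with %d genotypes at replication [%d, %d]",
          n_plots, n_genotypes, rmin, rmax), "phenolidar_sizing_error")
      }
      reps_per_geno <- rep(rmin, n_genotypes)
      extra <- n_plots - n_genotypes * rmin
      if (extra > 0) {
        # spread the surplus plots uniformly at random, respecting rmax
        pool <- sample(rep(seq_len(n_genotypes), times = rmax - rmin))
        add <- pool[seq_len(extra)]
        tab <- tabulate(add, nbins = n_genotypes)
        reps_per_geno <- reps_per_geno + tab
      }
      geno_idx <- sample(rep(seq_len(n_genotypes), times = reps_per_geno))
      rep_no <- stats::ave(geno_idx, geno_idx, FUN = seq_along)
    }

    if (is.null(field_shape)) {
      n_cols <- ceiling(sqrt(n_plots))
      n_rows_field <- ceiling(n_plots / n_cols)
      field_shape <- c(n_rows_field, n_cols)
    }
    if (prod(field_shape) < n_plots) {
      stop_pheno(sprintf("field of %d x %d plots cannot hold %d plots",
                         field_shape[1], field_shape[2], n_plots),
                 "phenolidar_sizing_error")
    }
    cell <- seq_len(n_plots)                   # row-major grid fill
    row <- (cell - 1L) %/% field_shape[2] + 1L
    col <- (cell - 1L) %% field_shape[2] + 1L

    plot_w <- geom$n_rows * geom$row_spacing
    x0 <- (col - 1L) * (plot_w + geom$path)
    y0 <- (row - 1L) * (geom$plot_length + geom$path) +
      (geom$plot_length - geom$sampled_length) / 2

    design <- data.frame(
      plot_id = sprintf("p%03d", cell),
      genotype = genotypes[geno_idx],
      replicate = as.integer(rep_no),
      row = row, col = col,
      x_min = x0, x_max = x0 + plot_w,
      y_min = y0, y_max = y0 + geom$sampled_length,
      n_rows = geom$n_rows, row_spacing = geom$row_spacing,
      sampled_length = geom$sampled_length,
      seed_density = seed_density,
      stringsAsFactors = FALSE)
    attr(design, "design_type") <- design_type
    attr(design, "field_shape") <- field_shape
    attr(design, "geometry") <- geom
    class(design) <- c("trial_design", "data.frame")
    design
  })
}

#' Sampled rectangle of one plot in a design
#'
#' @param design a `trial_design`.
#' @param plot_id the plot identifier (or a row index).
#' @return a [plot_rect].
#' @export
design_rect <- function(design, plot_id) {
  i <- if (is.character(plot_id)) match(plot_id, design$plot_id) else plot_id
  if (is.na(i)) {
    stop_pheno(sprintf("unknown plot_id: %s", plot_id),
               "phenolidar_validation_error")
  }
  plot_rect(design$x_min[i], design$x_max[i], design$y_min[i], design$y_max[i],
            n_rows = design$n_rows[i], row_spacing = design$row_spacing[i],
            sampled_length = design$sampled_length[i])
}

#' Mean genotype replication of a design
#'
#' Arithmetic mean of the per-genotype plot counts: the `nrep` entering the
#' repeatability formula. A harmonic-mean option is provided for unbalanced
#' designs.
#'
#' @param design a `trial_design` (or any data frame with a `genotype`
#'   column).
#' @param method `"arithmetic"` (default) or `"harmonic"`.
#' @return mean replicates per genotype.
#' @export
mean_replication <- function(design, method = c("arithmetic", "harmonic")) {
  method <- match.arg(method)
  counts <- as.numeric(table(design$genotype))
  if (method == "arithmetic") mean(counts) else length(counts) / sum(1 / counts)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design: %s, %d plots, %d genotypes, mean rep %.2f>\n",
              attr(x, "design_type"), nrow(x),
              length(unique(x$genotype)), mean_replication(x)))
  invisible(x)
}
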