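# Ground-truth generator: genotype effects, phenology, spatial field
# structure and the variance settings behind every simulated observation.

#' Default variance and mean settings for the simulated trial
#'
#' Groups the constants that define the simulated growing conditions:
#'
#' * `genotype`: between-genotype standard deviations of the physiological
#'   parameters (maximum height in m, canopy density on the log scale,
#'   logistic growth rate per day, phenology dates in days).
#' * `means`: population means of the same parameters; `gs31_days` and
#'   `gs65_days` are days from sowing to stem elongation and anthesis.
#' * `spatial`: standard deviations (log scale) of the smooth second-order
#'   field trend and of the independent row and column effects.
#' * `observation`: destructive-sampling and NDVI noise. The AGB noise
#'   standard deviation is `agb_noise_coef * sqrt(AGB) / sqrt(quadrat m2)`,
#'   so small quadrats and big crops are noisier, and the stated
#'   1/sqrt(area) scaling holds exactly.
#' * `traits`: named list of plain observed traits for recovery studies,
#'   each with `sigma2_g` (genotypic variance) and `sigma2_e` (residual
#'   variance) in trait units squared.
#'
#' @return a nested list, suitable for the `variance_spec` argument of
#'   [simulate_truth()] (override any element before passing it in).
#' @export
default_variance_spec <- function() {
  list(
    genotype = list(height_sd = 0.10, density_sdlog = 0.12,
                    growth_rate_sd = 0.006, phenology_sd = 2),
    means = list(height_max = 0.95, density = 1.0, growth_rate = 0.062,
                 gs31_days = 75, gs65_days = 108, gai_max = 6.0,
                 agb_coef = 1.65),
    spatial = list(trend_sd = 0.04, row_sd = 0.03, col_sd = 0.03),
    observation = list(agb_noise_coef = 0.27, ndvi_noise_sd = 0.02),
    traits = list(generic = list(sigma2_g = 1, sigma2_e = 1))
  )
}

validate_variance_spec <- function(vs) {
  num_fields <- c(vs$genotype, vs$spatial, vs$observation,
                  unlist(vs$traits, recursive = FALSE))
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop_pheno(sprintf("variance setting `%s` must be a finite nonnegative number",
                         nm), "phenolidar_validation_error")
    }
  }
  for (tn in names(vs$traits)) {
    if (vs$traits[[tn]]$sigma2_e <= 0) {
      stop_pheno(sprintf("trait `%s` needs sigma2_e > 0", tn),
                 "phenolidar_validation_error")
    }
  }
  invisible(vs)
}

#' Simulate the ground truth of a field trial
#'
#' Draws per-genotype physiological parameters (maximum height, canopy
#' density, logistic growth rate, GS31/GS65 phenology dates), plain trait
#' effects with the requested genotypic variances, and the spatial field
#' structure (a smooth second-order polynomial trend over the plot grid
#' plus independent row and column effects, all on the log scale), together
#' with a gently sloping terrain. The returned object is the single source
#' every `simulate_*` observation function reads from, so downstream
#' recovery tests can compare estimates against known truth.
#'
#' The `water_limited` scenario scales every genotype's growth rate by 0.6
#' and doubles observation noise, reproducing the qualitative contrast of a
#' droughted trial.
#'
#' @param design a `trial_design` from [simulate_design()].
#' @param variance_spec settings from [default_variance_spec()], possibly
#'   modified. All variances must be nonnegative.
#' @param scenario `"well_watered"` or `"water_limited"`.
#' @param sowing_date a `Date`; phenology dates are drawn relative to it.
#' @param rng_seed integer seed.
#' @return a list of class `sim_truth`: `genotypes` (per-genotype
#'   parameters, phenology dates and trait effects), `plots` (per-plot
#'   log-scale spatial multiplier and terrain elevation), plus the
#'   variance settings, scenario, noise multiplier and sowing date.
#' @export
simulate_truth <- function(design,
                           variance_spec = default_variance_spec(),
                           scenario = c("well_watered", "water_limited"),
                           sowing_date = as.Date("2016-05-23"),
                           rng_seed = NULL) {
  scenario <- match.arg(scenario)
  if (!inherits(design, "trial_design") || nrow(design) == 0) {
    stop_pheno("`design` must be a non-empty trial_design",
               "phenolidar_validation_error")
  }
  vs <- utils::modifyList(default_variance_spec(), variance_spec)
  validate_variance_spec(vs)

  with_seed_(rng_seed, {
    genos <- sort(unique(design$genotype))
    G <- length(genos)
    gp <- vs$genotype
    mu <- vs$means
    rate_mult <- if (scenario == "water_limited") 0.6 else 1.0
    noise_mult <- if (scenario == "water_limited") 2.0 else 1.0

    gs31 <- sowing_date + round(stats::rnorm(G, mu$gs31_days, gp$phenology_sd))
    gs65 <- sowing_date + round(stats::rnorm(G, mu$gs65_days, gp$phenology_sd))
    gs65 <- pmax(gs65, gs31 + 7)              # GS31 < GS65 always

    genotypes <- data.frame(
      genotype = genos,
      height_max = pmax(0.3, stats::rnorm(G, mu$height_max, gp$height_sd)),
      density = mu$density * stats::rlnorm(G, 0, gp$density_sdlog),
      growth_rate = rate_mult *
        pmax(0.02, stats::rnorm(G, mu$growth_rate, gp$growth_rate_sd)),
      gs31 = gs31, gs65 = gs65,
      stringsAsFactors = FALSE)
    for (tn in names(vs$traits)) {
      s2g <- vs$traits[[tn]]$sigma2_g
      genotypes[[paste0(tn, "_effect")]] <-
        if (s2g > 0) stats::rnorm(G, 0, sqrt(s2g)) else rep(0, G)
    }

    # spatial structure on the log scale: smooth quadratic trend + row/col
    sp <- vs$spatial
    rc <- scale(design$row)[, 1]
    cc <- scale(design$col)[, 1]
    rc[is.nan(rc)] <- 0; cc[is.nan(cc)] <- 0
    beta <- stats::rnorm(5, 0, sp$trend_sd)
    trend <- beta[1] * rc + beta[2] * cc + beta[3] * rc^2 + beta[4] * cc^2 +
      beta[5] * rc * cc
    row_eff <- stats::rnorm(max(design$row), 0, sp$row_sd)
    col_eff <- stats::rnorm(max(design$col), 0, sp$col_sd)
    # terrain: graded field, level along each plot column (constant y),
    # gentle slope across columns only — the geometry that makes pooling
    # ground returns per column sound
    slope <- stats::runif(1, -0.002, 0.002)
    plots <- data.frame(
      plot_id = design$plot_id,
      genotype = design$genotype,
      log_mult = trend + row_eff[design$row] + col_eff[design$col],
      terrain_z = slope * (design$x_min + design$x_max) / 2,
      stringsAsFactors = FALSE)

    structure(list(genotypes = genotypes, plots = plots,
                   variance_spec = vs, scenario = scenario,
                   noise_mult = noise_mult, sowing_date = sowing_date,
                   trend_beta = beta),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth: %d genotypes, %d plots, scenario %s>\n",
              nrow(x$genotypes), nrow(x$plots), x$scenario))
  invisible(x)
}

#' True repeatability implied by the generator settings
#'
#' For a plain simulated trait, the repeatability that an ideal analysis
#' would recover: `sigma2_g / (sigma2_g + sigma2_e / nrep)` with the
#' generator's true variances.
#'
#' @param truth a `sim_truth`.
#' @param trait name of a trait in the variance spec (default `"generic"`).
#' @param nrep mean genotype replication of the design analysed.
#' @return the true repeatability, in `[0, 1]`.
#' @export
true_repeatability <- function(truth, trait = "generic", nrep) {
  tv <- truth$variance_spec$traits[[trait]]
  if (is.null(tv)) {
    stop_pheno(sprintf("no variance settings for trait `%s`", trait),
               "phenolidar_validation_error")
  }
  repeatability(tv$sigma2_g, tv$sigma2_e, nrep)
}

#' Simulate a plain observed trait
#'
#' Draws one observation per plot as genotype effect plus independent
#' residual noise, using the variances stored in the truth object. This is
#' the generator's recovery hook: the analysis modules should recover
#' [true_repeatability()] from these observations.
#'
#' @param design a `trial_design`.
#' @param truth a `sim_truth` for that design.
#' @param trait trait name in the truth's variance spec.
#' @param date observation date attached to the rows.
#' @param rng_seed integer seed for the residual draw.
#' @return a [trait_table] data frame.
#' @export
simulate_trait <- function(design, truth, trait = "generic",
                           date = truth$sowing_date, rng_seed = NULL) {
  tv <- truth$variance_spec$traits[[trait]]
  if (is.null(tv)) {
    stop_pheno(sprintf("no variance settings for trait `%s`", trait),
               "phenolidar_validation_error")
  }
  eff <- truth$genotypes[[paste0(trait, "_effect")]]
  names(eff) <- truth$genotypes$genotype
  with_seed_(rng_seed, {
    value <- eff[design$genotype] +
      stats::rnorm(nrow(design), 0, sqrt(tv$sigma2_e))
    trait_table(data.frame(plot_id = design$plot_id,
                           genotype = design$genotype,
                           date = rep(as.Date(date), nrow(design)),
                           trait = trait, value = as.numeric(value),
                           stringsAsFactors = FALSE))
  })
}

# --- Canopy state at a date ----------------------------------------------

# Logistic canopy trajectories. Height rises toward height_max with
# midpoint 40% of the way from GS31 to GS65; green-area index follows with
# a 5-day lag. Returns per-genotype vectors aligned with `genotype`.
canopy_state <- function(truth, genotype, date) {
  g <- truth$genotypes[match(genotype, truth$genotypes$genotype), ]
  if (anyNA(g$genotype)) {
    stop_pheno("genotype absent from truth", "phenolidar_validation_error")
  }
  t <- as.numeric(as.Date(date) - truth$sowing_date)
  t31 <- as.numeric(g$gs31 - truth$sowing_date)
  t65 <- as.numeric(g$gs65 - truth$sowing_date)
  t_mid <- t31 + 0.4 * (t65 - t31)
  height <- g$height_max / (1 + exp(-g$growth_rate * (t - t_mid)))
  gai_max <- truth$variance_spec$means$gai_max * g$density
  gai <- gai_max / (1 + exp(-g$growth_rate * (t - (t_mid + 5))))
  list(height = height, gai = gai)
}
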