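# Destructive AGB sampling and the NDVI surrogate.

# Deterministic expectation of plot AGB (t/ha) at a date: proportional to
# canopy height x green-area index, times the plot's spatial multiplier.
expected_agb <- function(design, truth, date) {
  date <- as.Date(date)
  if (length(date) == 1L) date <- rep(date, nrow(design))
  if (length(date) != nrow(design)) {
    stop_pheno("`date` must be scalar or one per plot",
               "phenolidar_validation_error")
  }
  state <- canopy_state(truth, design$genotype, date)
  log_mult <- truth$plots$log_mult[match(design$plot_id, truth$plots$plot_id)]
  truth$variance_spec$means$agb_coef * state$height * state$gai *
    exp(log_mult)
}

#' Simulate destructive above-ground biomass sampling
#'
#' Each plot's expected AGB (t/ha) is proportional to its integrated canopy
#' volume times density (height x green-area index, with the plot's
#' spatial multiplier). Observed AGB adds quadrat sampling noise with
#' standard deviation `agb_noise_coef * sqrt(AGB) / sqrt(quadrat_area)`:
#' halving the quadrat area inflates the noise standard deviation by
#' `sqrt(2)`, which is what makes small-quadrat destructive sampling less
#' repeatable than the LiDAR indices. Under the water-limited scenario the
#' noise is doubled.
#'
#' @param design a `trial_design`.
#' @param truth a `sim_truth`.
#' @param date sampling date, a scalar or one date per plot (per-genotype
#'   anthesis sampling).
#' @param quadrat_area harvested ground area per plot, square metres.
#' @param noise_coef overrides the truth's `agb_noise_coef` (t/ha per
#'   sqrt(t/ha) per sqrt(m2)); set 0 for noiseless sampling.
#' @param rng_seed integer seed.
#' @return a [trait_table] with trait `"agb"` in t/ha.
#' @export
simulate_agb <- function(design, truth, date, quadrat_area,
                         noise_coef = NULL, rng_seed = NULL) {
  assert_scalar_num(quadrat_area, "quadrat_area", positive = TRUE)
  if (is.null(noise_coef)) {
    noise_coef <- truth$variance_spec$observation$agb_noise_coef
  }
  assert_scalar_num(noise_coef, "noise_coef", nonneg = TRUE)
  mu <- expected_agb(design, truth, date)
  sd <- truth$noise_mult * noise_coef * sqrt(pmax(mu, 0.05)) /
    sqrt(quadrat_area)
  date <- as.Date(date)
  if (length(date) == 1L) date <- rep(date, nrow(design))
  with_seed_(rng_seed, {
    value <- pmax(mu + stats::rnorm(nrow(design), 0, sd), 0)
    trait_table(data.frame(plot_id = design$plot_id,
                           genotype = design$genotype,
                           date = date, trait = "agb",
                           value = as.numeric(value),
                           stringsAsFactors = FALSE))
  })
}

#' Simulate the NDVI surrogate
#'
#' A saturating logistic-style function of the plot's green-area index:
#' `ndvi = ndvi_max - (ndvi_max - ndvi_soil) * exp(-k * GAI)` plus additive
#' noise. Reproduces NDVI's saturation with canopy closure qualitatively;
#' no radiometric model is attempted.
#'
#' @param design a `trial_design`.
#' @param truth a `sim_truth`.
#' @param date measurement date.
#' @param rng_seed integer seed.
#' @return a [trait_table] with trait `"ndvi"`, values in `[0, 1]`.
#' @export
simulate_ndvi <- function(design, truth, date, rng_seed = NULL) {
  state <- canopy_state(truth, design$genotype, as.Date(date))
  log_mult <- truth$plots$log_mult[match(design$plot_id, truth$plots$plot_id)]
  gai <- state$gai * exp(log_mult)
  sd <- truth$noise_mult * truth$variance_spec$observation$ndvi_noise_sd
  with_seed_(rng_seed, {
    ndvi <- 0.9 - (0.9 - 0.15) * exp(-0.65 * gai) +
      stats::rnorm(nrow(design), 0, sd)
    trait_table(data.frame(plot_id = design$plot_id,
                           genotype = design$genotype,
                           date = rep(as.Date(date), nrow(design)),
                           trait = "ndvi",
                           value = pmin(pmax(as.numeric(ndvi), 0), 1),
                           stringsAsFactors = FALSE))
  })
}
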