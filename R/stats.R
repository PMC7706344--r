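# Event-wise random-effects analysis: variance components by REML,
# repeatability, BLUPs, BLUP correlations and raw-data regression.

#' Fit the event-wise random-effects model
#'
#' For one trait at one sampling event, fits (by REML) the mixed model with
#' independent random effects for genotype, field row and field column,
#' and extracts the genotypic and residual variance components, genotype
#' BLUPs and the repeatability `sigma2_g / (sigma2_g + sigma2_e / nrep)`.
#' Row and column random effects (optionally with a fixed second-order
#' polynomial surface, `trend = TRUE`) absorb spatial field variation.
#' Variance estimates are bounded below at zero by the REML optimizer, so
#' a trait with no genotypic signal yields `sigma2_g = 0` and repeatability
#' 0 exactly.
#'
#' Degenerate inputs (a single genotype, constant observations, or a fit
#' failure) return a zero-variance decomposition flagged in `$convergence`
#' instead of raising.
#'
#' @param traits a [trait_table] (or data frame with `plot_id` and `value`)
#'   already filtered to one event and one trait.
#' @param design the `trial_design`, supplying genotype, row and column for
#'   each plot.
#' @param spatial `"rowcol"` (default) for row + column random effects, or
#'   `"none"` for a genotype-only model.
#' @param trend add a fixed second-order polynomial in (row, col)?
#' @param nrep_method `"arithmetic"` (default) or `"harmonic"` mean
#'   genotype replication.
#' @return a list of class `variance_decomposition`: `sigma2_g`,
#'   `sigma2_row`, `sigma2_col`, `sigma2_e`, `nrep`, `rho`, `blups` (named
#'   vector), `residuals`, `n_obs`, `convergence`.
#' @export
fit_random_effects <- function(traits, design,
                               spatial = c("rowcol", "none"),
                               trend = FALSE,
                               nrep_method = c("arithmetic", "harmonic")) {
  spatial <- match.arg(spatial)
  nrep_method <- match.arg(nrep_method)
  tr <- as.data.frame(traits)
  if ((("date" %in% names(tr)) && length(unique(tr$date)) > 1) ||
      (("trait" %in% names(tr)) && length(unique(tr$trait)) > 1)) {
    stop_pheno("filter the trait table to a single event and trait first",
               "phenolidar_validation_error")
  }
  dat <- merge(tr[, c("plot_id", "value")],
               as.data.frame(design)[, c("plot_id", "genotype", "row", "col")],
               by = "plot_id")
  dat <- dat[is.finite(dat$value), , drop = FALSE]
  if (nrow(dat) == 0) {
    stop_pheno("no observations to fit", "phenolidar_validation_error")
  }
  nrep <- mean_replication(dat, nrep_method)
  degenerate <- function(note) {
    blups <- rep(0, length(unique(dat$genotype)))
    names(blups) <- sort(unique(dat$genotype))
    structure(list(sigma2_g = 0, sigma2_row = 0, sigma2_col = 0,
                   sigma2_e = 0, nrep = nrep, rho = 0, blups = blups,
                   residuals = rep(0, nrow(dat)), n_obs = nrow(dat),
                   convergence = note),
              class = "variance_decomposition")
  }
  if (length(unique(dat$genotype)) < 2) {
    return(degenerate("degenerate: fewer than 2 genotypes"))
  }
  if (stats::var(dat$value) == 0) {
    return(degenerate("degenerate: constant observations"))
  }

  dat$genotype <- factor(dat$genotype)
  dat$frow <- factor(dat$row)
  dat$fcol <- factor(dat$col)
  terms <- "value ~ 1 + (1 | genotype)"
  if (spatial == "rowcol") {
    if (nlevels(dat$frow) > 1) terms <- paste(terms, "+ (1 | frow)")
    if (nlevels(dat$fcol) > 1) terms <- paste(terms, "+ (1 | fcol)")
  }
  if (isTRUE(trend)) {
    dat$rc <- as.numeric(scale(dat$row))
    dat$cc <- as.numeric(scale(dat$col))
    dat$rc[is.nan(dat$rc)] <- 0
    dat$cc[is.nan(dat$cc)] <- 0
    terms <- paste(terms, "+ rc + cc + I(rc^2) + I(cc^2) + rc:cc")
  }

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(terms), data = dat, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(degenerate("degenerate: REML fit failed"))
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 1) v else 0
  }
  sigma2_g <- get_vc("genotype")
  sigma2_e <- get_vc("Residual")
  re <- lme4::ranef(fit)$genotype
  blups <- re[["(Intercept)"]]
  names(blups) <- rownames(re)
  structure(list(sigma2_g = sigma2_g,
                 sigma2_row = get_vc("frow"),
                 sigma2_col = get_vc("fcol"),
                 sigma2_e = sigma2_e,
                 nrep = nrep,
                 rho = repeatability(sigma2_g, sigma2_e, nrep),
                 blups = blups,
                 residuals = stats::residuals(fit),
                 n_obs = nrow(dat),
                 convergence = "converged"),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<variance_decomposition: sigma2_g = %.4g, ",
                     "sigma2_e = %.4g, nrep = %.2f, rho = %.3f>\n"),
              x$sigma2_g, x$sigma2_e, x$nrep, x$rho))
  invisible(x)
}

#' Repeatability (broad-sense heritability) from variance components
#'
#' `rho = sigma2_g / (sigma2_g + sigma2_e / nrep)`: the proportion of the
#' variance among genotype means attributable to genotype, given the mean
#' replication `nrep`. Exactly 0 when `sigma2_g` is 0 and exactly 1 when
#' the residual variance vanishes with genotypic signal present.
#'
#' @param sigma2_g genotypic variance (>= 0), or a `variance_decomposition`.
#' @param sigma2_e residual variance (>= 0).
#' @param nrep mean genotype replication (> 0).
#' @return repeatability in `[0, 1]`.
#' @examples
#' repeatability(1, 1, 2)  # 2/3
#' @export
repeatability <- function(sigma2_g, sigma2_e, nrep) {
  if (inherits(sigma2_g, "variance_decomposition")) {
    vc <- sigma2_g
    return(repeatability(vc$sigma2_g, vc$sigma2_e, vc$nrep))
  }
  assert_scalar_num(sigma2_g, "sigma2_g", nonneg = TRUE)
  assert_scalar_num(sigma2_e, "sigma2_e", nonneg = TRUE)
  assert_scalar_num(nrep, "nrep", positive = TRUE)
  if (sigma2_g == 0) return(0)
  rho <- sigma2_g / (sigma2_g + sigma2_e / nrep)
  min(max(rho, 0), 1)
}

#' Significance stars for p-values
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"****"` for p < 0.0001, `"***"` < 0.001,
#'   `"**"` < 0.01, `"*"` < 0.05, `""` otherwise.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Pearson correlation between two sets of genotype BLUPs
#'
#' Correlates the BLUPs over the genotypes present in both sets (pairwise
#' intersection), with a two-sided p-value from the t distribution on
#' `n - 2` degrees of freedom and the usual significance stars.
#'
#' @param blups_a,blups_b named numeric vectors of genotype BLUPs (or
#'   `variance_decomposition` objects).
#' @return a list of class `correlation_result`: `r`, `p_value`, `n`,
#'   `stars`.
#' @export
correlate_blups <- function(blups_a, blups_b) {
  if (inherits(blups_a, "variance_decomposition")) blups_a <- blups_a$blups
  if (inherits(blups_b, "variance_decomposition")) blups_b <- blups_b$blups
  common <- intersect(names(blups_a), names(blups_b))
  n <- length(common)
  if (n < 3) {
    stop_pheno(sprintf("need >= 3 shared genotypes to correlate (got %d)", n),
               "phenolidar_sample_size_error")
  }
  a <- blups_a[common]; b <- blups_b[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_pheno("BLUPs are constant; correlation undefined",
               "phenolidar_validation_error")
  }
  r <- stats::cor(a, b)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n, stars = p_stars(p)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation: r = %.3f%s (p = %.3g, n = %d)>\n",
              x$r, x$stars, x$p_value, x$n))
  invisible(x)
}

#' Intraclass correlation of a trait between two sampling events
#'
#' Defined as the Pearson correlation between the genotype BLUPs of the
#' same trait at two events: high when genotype ranking is stable over
#' time.
#'
#' @param traits a [trait_table] holding the trait at both events.
#' @param design the `trial_design`.
#' @param trait trait name.
#' @param event_a,event_b the two event dates.
#' @param ... passed to [fit_random_effects()].
#' @return a `correlation_result`.
#' @export
icc_between_events <- function(traits, design, trait, event_a, event_b, ...) {
  event_a <- as.Date(event_a); event_b <- as.Date(event_b)
  fits <- lapply(c(event_a, event_b), function(ev) {
    sub <- traits[traits$trait == trait & traits$date == ev, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop_pheno(sprintf(
        "no `%s` observations at event %s (available events: %s)",
        trait, ev,
        paste(sort(unique(traits$date[traits$trait == trait])),
              collapse = ", ")),
        "phenolidar_missing_event")
    }
    fit_random_effects(sub, design, ...)
  })
  correlate_blups(fits[[1]], fits[[2]])
}

#' Raw-data least-squares regression of AGB on a LiDAR index
#'
#' Ordinary least squares on nonspatially corrected plot-level values.
#'
#' @param agb per-plot AGB values (response).
#' @param index per-plot index values (predictor), same order.
#' @return a list of class `raw_regression`: `slope`, `intercept`, `r`
#'   (Pearson), `n`.
#' @export
regress_raw <- function(agb, index) {
  ok <- is.finite(agb) & is.finite(index)
  agb <- agb[ok]; index <- index[ok]
  if (length(agb) < 3) {
    stop_pheno("need >= 3 paired plots for regression",
               "phenolidar_sample_size_error")
  }
  if (stats::var(index) == 0) {
    stop_pheno("index has zero variance; regression undefined",
               "phenolidar_validation_error")
  }
  fit <- stats::lm(agb ~ index)
  r <- if (stats::sd(agb) == 0) NA_real_ else stats::cor(agb, index)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r,
                 n = length(agb)),
            class = "raw_regression")
}

#' @export
print.raw_regression <- function(x, ...) {
  cat(sprintf("<raw_regression: slope = %.3g, intercept = %.3g, r = %.3f, n = %d>\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}
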