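# End-to-end orchestration: simulate -> extract -> growth rate -> stats,
# reproducible under a single seed, with a machine-readable report.

#' Assemble and validate a run configuration
#'
#' Collects every parameter of a pipeline run: the simulated trial (design
#' type, genotypes, variance settings, scenario), the scanner, the sampling
#' events, and the extraction and estimation options. The resolved
#' configuration is serialized verbatim into the output directory of a run
#' and fingerprinted into every output file, so a run is fully described by
#' its config and seed.
#'
#' @param scenario `"well_watered"` or `"water_limited"`.
#' @param n_genotypes number of genotypes in the simulated trial.
#' @param design_type `"rcbd"` or `"partial_rep"`.
#' @param replication replication spec, see [simulate_design()].
#' @param events sampling events, days after sowing; the first is the
#'   common stem-elongation (GS31) sampling, the last must cover the
#'   latest genotype's anthesis so index series can be interpolated.
#' @param sowing_date sowing date (ISO string or `Date`).
#' @param quadrat_area destructive AGB quadrat, square metres.
#' @param variance_spec overrides merged onto [default_variance_spec()].
#' @param scan named list of [scan_config()] arguments.
#' @param voxel_size 3DVI voxel edge, metres.
#' @param layer 3DPI layer thickness, metres.
#' @param dpi_variant 3DPI variant, see [compute_3dpi()].
#' @param ground_bin ground-mode histogram bin, metres.
#' @param spatial,trend model options, see [fit_random_effects()].
#' @param seed integer master seed; every stage derives its own stream.
#' @param out_dir optional output directory; `NULL` keeps results in
#'   memory only.
#' @return a list of class `run_config`.
#' @export
run_config <- function(scenario = "well_watered",
                       n_genotypes = 25,
                       design_type = "rcbd",
                       replication = list(reps = 2),
                       events = c(75, 92, 108, 122),
                       sowing_date = "2016-05-23",
                       quadrat_area = 0.3,
                       variance_spec = list(),
                       scan = list(),
                       voxel_size = 0.05,
                       layer = 0.01,
                       dpi_variant = "interception",
                       ground_bin = 0.01,
                       spatial = "rowcol",
                       trend = TRUE,
                       seed = 1,
                       out_dir = NULL) {
  cfg <- list(scenario = scenario, n_genotypes = n_genotypes,
              design_type = design_type, replication = replication,
              events = as.numeric(events),
              sowing_date = as.character(as.Date(sowing_date)),
              quadrat_area = quadrat_area,
              variance_spec = utils::modifyList(default_variance_spec(),
                                                variance_spec),
              scan = utils::modifyList(
                list(beam_spacing = 0.02, layer = 0.01, extinction = 0.55,
                     ground_fraction = 0.10, z_noise_sd = 0.003), scan),
              voxel_size = voxel_size, layer = layer,
              dpi_variant = dpi_variant, ground_bin = ground_bin,
              spatial = spatial, trend = trend,
              seed = as.integer(seed), out_dir = out_dir)
  scenario <- match.arg(cfg$scenario, c("well_watered", "water_limited"))
  assert_scalar_num(cfg$quadrat_area, "quadrat_area", positive = TRUE)
  assert_scalar_num(cfg$voxel_size, "voxel_size", positive = TRUE)
  assert_scalar_num(cfg$layer, "layer", positive = TRUE)
  if (length(cfg$events) < 2) {
    stop_pheno("need at least two sampling events",
               "phenolidar_validation_error")
  }
  validate_variance_spec(cfg$variance_spec)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML document
#'
#' @param path path to a YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0) {
    stop_pheno(sprintf("unknown config keys: %s",
                       paste(unknown, collapse = ", ")),
               "phenolidar_validation_error")
  }
  do.call(run_config, doc)
}

config_hash <- function(config) {
  fnv1a_hash(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA,
                                           null = "null")))
}

# --- Trait extraction from clouds ----------------------------------------

#' Extract LiDAR traits from one scan of a trial
#'
#' Runs the point-cloud module over every plot of a scan: ground elevation
#' is estimated per field column from the pooled clouds of that column,
#' then crop height, 3DVI and 3DPI are computed per plot.
#'
#' @param clouds named list of [point_cloud]s, one per plot (as produced by
#'   [simulate_scan()], or read from disk).
#' @param design the `trial_design`.
#' @param date the scan date.
#' @param voxel_size,layer,dpi_variant,ground_bin extraction parameters,
#'   see [compute_3dvi()] and [compute_3dpi()].
#' @return a [trait_table] with traits `height`, `dvi` (3DVI) and `dpi`
#'   (3DPI) for every plot.
#' @export
extract_traits <- function(clouds, design, date,
                           voxel_size = 0.05, layer = 0.01,
                           dpi_variant = "interception",
                           ground_bin = 0.01) {
  date <- as.Date(date)
  missing_clouds <- setdiff(design$plot_id, names(clouds))
  if (length(missing_clouds) > 0) {
    stop_pheno(sprintf("no cloud for plot(s): %s",
                       paste(missing_clouds, collapse = ", ")),
               "phenolidar_validation_error")
  }
  grounds <- list()
  for (cl in sort(unique(design$col))) {
    ids <- design$plot_id[design$col == cl]
    grounds[[as.character(cl)]] <- estimate_ground(clouds[ids],
                                                   bin_width = ground_bin)
  }
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    pid <- design$plot_id[i]
    cloud <- clouds[[pid]]
    ground <- grounds[[as.character(design$col[i])]]
    rect <- design_rect(design, i)
    h <- crop_height(cloud, ground)
    dvi <- suppressWarnings(compute_3dvi(cloud, rect, ground,
                                         voxel_size = voxel_size))
    dpi <- compute_3dpi(cloud, ground, layer = layer, variant = dpi_variant)
    rows[[i]] <- data.frame(plot_id = pid, genotype = design$genotype[i],
                            date = date,
                            trait = c("height", "dvi", "dpi"),
                            value = c(h, dvi, dpi),
                            stringsAsFactors = FALSE)
  }
  trait_table(do.call(rbind, rows))
}

# --- Event-wise analysis --------------------------------------------------

# Rethrow any stage failure with the stage name and context attached.
stage_ <- function(name, context, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("stage `%s` failed (%s): %s", name, context,
              conditionMessage(e)),
      class = c("phenolidar_stage_error", class(e)[class(e) != "condition"])))
  })
}

simulate_run_inputs <- function(config) {
  seed <- config$seed
  design <- simulate_design(config$n_genotypes, config$design_type,
                            config$replication,
                            rng_seed = derive_seed(seed, 1))
  truth <- simulate_truth(design, config$variance_spec,
                          scenario = config$scenario,
                          sowing_date = as.Date(config$sowing_date),
                          rng_seed = derive_seed(seed, 2))
  list(design = design, truth = truth)
}

# Simulate scans and observations at every event and extract traits.
build_event_traits <- function(config, design, truth) {
  scfg <- do.call(scan_config, config$scan)
  seed <- config$seed
  event_dates <- as.Date(config$sowing_date) + config$events
  tabs <- list()
  for (e in seq_along(event_dates)) {
    ev <- event_dates[e]
    clouds <- stage_("scan", sprintf("event %s", ev),
                     simulate_scan(design, truth, ev, scfg,
                                   rng_seed = derive_seed(seed, 10 + e)))
    tabs[[length(tabs) + 1L]] <- stage_(
      "extract", sprintf("event %s", ev),
      extract_traits(clouds, design, ev,
                     voxel_size = config$voxel_size, layer = config$layer,
                     dpi_variant = config$dpi_variant,
                     ground_bin = config$ground_bin))
    tabs[[length(tabs) + 1L]] <- stage_(
      "agb_sampling", sprintf("event %s", ev),
      simulate_agb(design, truth, ev, config$quadrat_area,
                   rng_seed = derive_seed(seed, 100 + e)))
    tabs[[length(tabs) + 1L]] <- stage_(
      "ndvi", sprintf("event %s", ev),
      simulate_ndvi(design, truth, ev, rng_seed = derive_seed(seed, 200 + e)))
  }
  do.call(bind_traits, tabs)
}

fit_one <- function(traits, design, trait, event, config) {
  sub <- traits[traits$trait == trait & traits$date == event, , drop = FALSE]
  fit_random_effects(sub, design, spatial = config$spatial,
                     trend = config$trend)
}

residual_diagnostics <- function(vc) {
  res <- vc$residuals
  sw <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0) {
    unname(stats::shapiro.test(res)$statistic)
  } else NA_real_
  # homogeneity: variance ratio between the two halves of the residuals
  half <- res[seq_len(floor(length(res) / 2))]
  other <- res[-seq_len(floor(length(res) / 2))]
  ratio <- if (stats::var(other) > 0) stats::var(half) / stats::var(other)
           else NA_real_
  list(shapiro_w = sw, var_ratio = ratio)
}

#' Event-wise repeatability analysis of a simulated trial
#'
#' Simulates the trial defined by the config, extracts the LiDAR traits at
#' every event, and fits the random-effects model per trait and event,
#' reporting repeatabilities, BLUP correlations of each LiDAR trait with
#' AGB, intraclass correlations between consecutive events, and advisory
#' residual diagnostics (Shapiro-Wilk statistic, residual variance ratio).
#' Deterministic given the config's seed.
#'
#' @param config a [run_config()].
#' @return a list of class `event_report`: `config_hash`, `repeatability`
#'   (data frame: event, trait, variance components, nrep, rho,
#'   diagnostics), `correlations` (per event, trait vs AGB: r, p, n,
#'   stars), `iccs` (consecutive-event ICCs per trait), `traits` (the full
#'   trait table), `design`, `truth`.
#' @export
run_event_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- simulate_run_inputs(config)
  design <- inputs$design; truth <- inputs$truth
  traits <- build_event_traits(config, design, truth)
  event_dates <- as.Date(config$sowing_date) + config$events
  trait_names <- c("agb", "dvi", "dpi", "height", "ndvi")

  fits <- list()
  rep_rows <- list(); cor_rows <- list(); icc_rows <- list()
  for (ev in as.list(event_dates)) {
    key <- as.character(ev)
    fits[[key]] <- lapply(stats::setNames(trait_names, trait_names),
                          function(tn) {
                            stage_("stats", sprintf("trait %s, event %s", tn, ev),
                                   fit_one(traits, design, tn, ev, config))
                          })
    for (tn in trait_names) {
      vc <- fits[[key]][[tn]]
      di <- residual_diagnostics(vc)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        event = ev, trait = tn, sigma2_g = vc$sigma2_g,
        sigma2_row = vc$sigma2_row, sigma2_col = vc$sigma2_col,
        sigma2_e = vc$sigma2_e, nrep = vc$nrep, rho = vc$rho,
        shapiro_w = di$shapiro_w, var_ratio = di$var_ratio,
        stringsAsFactors = FALSE)
    }
    for (tn in setdiff(trait_names, "agb")) {
      cr <- tryCatch(correlate_blups(fits[[key]][["agb"]], fits[[key]][[tn]]),
                     error = function(e) NULL)
      if (!is.null(cr)) {
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          event = ev, trait_a = "agb", trait_b = tn, r = cr$r,
          p_value = cr$p_value, n = cr$n, stars = cr$stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (tn in trait_names) {
    for (e in seq_len(length(event_dates) - 1)) {
      k1 <- as.character(event_dates[e]); k2 <- as.character(event_dates[e + 1])
      cr <- tryCatch(correlate_blups(fits[[k1]][[tn]], fits[[k2]][[tn]]),
                     error = function(e) NULL)
      if (!is.null(cr)) {
        icc_rows[[length(icc_rows) + 1L]] <- data.frame(
          trait = tn, event_a = event_dates[e], event_b = event_dates[e + 1],
          r = cr$r, p_value = cr$p_value, n = cr$n, stars = cr$stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- structure(
    list(config_hash = config_hash(config),
         repeatability = do.call(rbind, rep_rows),
         correlations = do.call(rbind, cor_rows),
         iccs = do.call(rbind, icc_rows),
         traits = traits, design = design, truth = truth),
    class = "event_report")
  if (!is.null(config$out_dir)) write_report(report, config, "events")
  report
}

#' Crop-growth-rate analysis of a simulated trial
#'
#' Mirrors the anthesis-window workflow: AGB is destructively sampled at
#' the common stem-elongation event and again at each genotype's own
#' anthesis (GS65) date, while the LiDAR index series are linearly
#' interpolated to each genotype's GS65 date. Per-plot growth rates are
#' then analysed with the same random-effects model, giving CGR
#' repeatabilities and the BLUP correlations between AGB-derived and
#' index-derived CGR.
#'
#' @param config a [run_config()].
#' @param events_report optionally, the result of [run_event_analysis()]
#'   for the same config, to reuse its simulated traits.
#' @return a list of class `cgr_report`: `config_hash`, `repeatability`,
#'   `correlations`, `cgr` (per-plot CGR trait table).
#' @export
run_cgr_analysis <- function(config, events_report = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(events_report)) {
    inputs <- simulate_run_inputs(config)
    design <- inputs$design; truth <- inputs$truth
    traits <- build_event_traits(config, design, truth)
  } else {
    design <- events_report$design; truth <- events_report$truth
    traits <- events_report$traits
  }
  event_dates <- as.Date(config$sowing_date) + config$events
  gs31_common <- event_dates[1]

  # destructive AGB: common GS31 event + per-genotype anthesis sampling
  ph_true <- truth_phenology(truth)
  gs65_plot <- ph_true$gs65_date[match(design$genotype, ph_true$genotype)]
  agb31 <- traits[traits$trait == "agb" & traits$date == gs31_common, ]
  agb65 <- simulate_agb(design, truth, gs65_plot, config$quadrat_area,
                        rng_seed = derive_seed(config$seed, 300))
  # CGR window: common GS31 sampling -> genotype GS65 (paperless plots drop)
  ph_window <- phenology_table(ph_true$genotype,
                               rep(gs31_common, nrow(ph_true)),
                               pmax(ph_true$gs65_date, gs31_common + 1))
  agb_series <- bind_traits(agb31, agb65)
  cgr_tabs <- list(agb = cgr_table(agb_series, ph_window, "agb"))
  for (tn in c("dvi", "dpi")) {
    cgr_tabs[[tn]] <- suppressMessages(
      cgr_table(traits[traits$trait == tn, ], ph_window, tn))
  }

  rep_rows <- list(); cor_rows <- list(); fits <- list()
  for (tn in names(cgr_tabs)) {
    tab <- as.data.frame(cgr_tabs[[tn]])
    tab$date <- as.Date(config$sowing_date)     # collapse to one pseudo-event
    tab$trait <- paste0("cgr_", tn)
    fits[[tn]] <- fit_random_effects(tab, design, spatial = config$spatial,
                                     trend = config$trend)
    vc <- fits[[tn]]
    rep_rows[[tn]] <- data.frame(trait = paste0("cgr_", tn),
                                 sigma2_g = vc$sigma2_g,
                                 sigma2_e = vc$sigma2_e, nrep = vc$nrep,
                                 rho = vc$rho, n_plots = vc$n_obs,
                                 stringsAsFactors = FALSE)
  }
  for (tn in c("dvi", "dpi")) {
    cr <- tryCatch(correlate_blups(fits[["agb"]], fits[[tn]]),
                   error = function(e) NULL)
    if (!is.null(cr)) {
      cor_rows[[tn]] <- data.frame(trait_a = "cgr_agb",
                                   trait_b = paste0("cgr_", tn),
                                   r = cr$r, p_value = cr$p_value, n = cr$n,
                                   stars = cr$stars, stringsAsFactors = FALSE)
    }
  }
  report <- structure(
    list(config_hash = config_hash(config),
         repeatability = do.call(rbind, c(rep_rows, make.row.names = FALSE)),
         correlations = do.call(rbind, c(cor_rows, make.row.names = FALSE)),
         cgr = do.call(bind_traits, cgr_tabs)),
    class = "cgr_report")
  if (!is.null(config$out_dir)) write_report(report, config, "cgr")
  report
}

#' Run the full pipeline
#'
#' Event-wise analysis followed by the crop-growth-rate analysis, sharing
#' one simulated trial. With `out_dir` set in the config, writes
#' `config.json`, per-table CSVs under `tables/` and a combined
#' `report.json`; two runs with the same config and seed produce
#' byte-identical reports.
#'
#' @param config a [run_config()].
#' @return a list with elements `events` and `cgr`.
#' @export
run_all <- function(config) {
  cfg_mem <- config
  cfg_mem$out_dir <- NULL
  events <- run_event_analysis(cfg_mem)
  cgr <- run_cgr_analysis(cfg_mem, events_report = events)
  result <- list(events = events, cgr = cgr)
  if (!is.null(config$out_dir)) {
    write_report(events, config, "events")
    write_report(cgr, config, "cgr")
    write_combined_report(result, config)
  }
  result
}

# --- Output writing -------------------------------------------------------

report_tables <- function(report) {
  is_tab <- vapply(report, is.data.frame, logical(1))
  report[is_tab]
}

serialize_report <- function(report) {
  keep <- setdiff(names(report), c("design", "truth", "traits"))
  jsonlite::toJSON(lapply(report[keep], function(x) {
    if (is.data.frame(x)) {
      x <- as.data.frame(x)
      for (cn in names(x)) if (inherits(x[[cn]], "Date")) {
        x[[cn]] <- as.character(x[[cn]])
      }
      x
    } else x
  }), dataframe = "rows", auto_unbox = TRUE, digits = 10, pretty = TRUE,
  null = "null")
}

write_table_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

write_report <- function(report, config, stem) {
  out <- config$out_dir
  dir.create(file.path(out, "tables"), recursive = TRUE, showWarnings = FALSE)
  hash <- report$config_hash
  writeLines(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE,
                                           null = "null")),
             file.path(out, "config.json"))
  for (tn in names(report_tables(report))) {
    write_table_csv(report[[tn]],
                    file.path(out, "tables", sprintf("%s_%s.csv", stem, tn)),
                    hash)
  }
  writeLines(as.character(serialize_report(report)),
             file.path(out, sprintf("report_%s.json", stem)))
  invisible(out)
}

write_combined_report <- function(result, config) {
  out <- config$out_dir
  combined <- jsonlite::toJSON(
    list(config_hash = result$events$config_hash,
         events = jsonlite::fromJSON(serialize_report(result$events),
                                     simplifyVector = FALSE),
         cgr = jsonlite::fromJSON(serialize_report(result$cgr),
                                  simplifyVector = FALSE)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  writeLines(as.character(combined), file.path(out, "report.json"))
  invisible(out)
}
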