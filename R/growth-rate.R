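# Long-format trait tables, phenology, and crop growth rate between stem
# elongation (GS31) and anthesis (GS65).

#' Construct a long-format trait table
#'
#' The common currency of the pipeline: one row per plot x date x trait
#' observation. `(plot_id, date, trait)` must be unique, dates must be
#' `Date`s and values finite.
#'
#' @param df a data frame with columns `plot_id`, `genotype`, `date`,
#'   `trait`, `value`.
#' @return the validated data frame with class `trait_table` prepended.
#' @export
trait_table <- function(df) {
  need <- c("plot_id", "genotype", "date", "trait", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_pheno(sprintf("trait table missing columns: %s",
                       paste(missing_cols, collapse = ", ")),
               "phenolidar_validation_error")
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) {
    stop_pheno("trait table dates must be valid calendar dates",
               "phenolidar_validation_error")
  }
  if (!all(is.finite(df$value))) {
    stop_pheno("trait table values must be finite",
               "phenolidar_validation_error")
  }
  key <- paste(df$plot_id, df$date, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    stop_pheno("duplicate (plot_id, date, trait) rows in trait table",
               "phenolidar_validation_error")
  }
  if (!inherits(df, "trait_table")) class(df) <- c("trait_table", class(df))
  df
}

#' Combine trait tables
#'
#' @param ... trait tables (or compatible data frames).
#' @return one validated [trait_table].
#' @export
bind_traits <- function(...) {
  trait_table(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Construct a phenology table
#'
#' @param genotype character vector of genotype names (unique).
#' @param gs31_date stem-elongation (GS31) dates.
#' @param gs65_date anthesis (GS65) dates; must be after GS31 per genotype.
#' @return a data frame of class `phenology_table`.
#' @export
phenology_table <- function(genotype, gs31_date, gs65_date) {
  gs31_date <- as.Date(gs31_date)
  gs65_date <- as.Date(gs65_date)
  if (anyDuplicated(genotype)) {
    stop_pheno("phenology genotypes must be unique",
               "phenolidar_validation_error")
  }
  if (any(gs65_date <= gs31_date)) {
    bad <- genotype[gs65_date <= gs31_date]
    stop_pheno(sprintf("GS31 must precede GS65; violated for: %s",
                       paste(bad, collapse = ", ")),
               "phenolidar_validation_error")
  }
  ph <- data.frame(genotype = genotype, gs31_date = gs31_date,
                   gs65_date = gs65_date, stringsAsFactors = FALSE)
  class(ph) <- c("phenology_table", "data.frame")
  ph
}

#' Phenology of a simulated trial
#'
#' @param truth a `sim_truth`.
#' @return a [phenology_table] with the generator's true GS31/GS65 dates.
#' @export
truth_phenology <- function(truth) {
  phenology_table(truth$genotypes$genotype, truth$genotypes$gs31,
                  truth$genotypes$gs65)
}

#' Linearly interpolate a trait series to a target date
#'
#' Piecewise-linear interpolation between sampling events; when the target
#' date is itself an event, that event's value is returned exactly. No
#' extrapolation: a target outside the sampled window is an error.
#'
#' @param dates event dates (`Date` or coercible), at least two.
#' @param values trait values at those events.
#' @param target_date the date to interpolate to.
#' @return the interpolated value.
#' @export
interpolate_trait <- function(dates, values, target_date) {
  dates <- as.Date(dates)
  target_date <- as.Date(target_date)
  if (length(dates) != length(values) || length(dates) < 2) {
    stop_pheno("need at least two (date, value) events to interpolate",
               "phenolidar_validation_error")
  }
  o <- order(dates)
  dates <- dates[o]; values <- values[o]
  if (target_date < dates[1] || target_date > dates[length(dates)]) {
    stop_pheno(sprintf(
      "target date %s outside the sampled window [%s, %s]; no extrapolation",
      target_date, dates[1], dates[length(dates)]),
      "phenolidar_range_error")
  }
  stats::approx(as.numeric(dates), values, xout = as.numeric(target_date),
                method = "linear", ties = "ordered")$y
}

#' Crop growth rate between two dates
#'
#' @param value_start,value_end trait values at the window ends.
#' @param date_start,date_end window dates; `date_end` must be later.
#' @return rate per day, `(value_end - value_start) / days`.
#' @examples
#' compute_cgr(0.9, 2.4, as.Date("2016-08-08"), as.Date("2016-08-23"))  # 0.1
#' @export
compute_cgr <- function(value_start, value_end, date_start, date_end) {
  days <- as.numeric(as.Date(date_end) - as.Date(date_start))
  if (!is.finite(days) || days <= 0) {
    stop_pheno("CGR window must have positive duration",
               "phenolidar_validation_error")
  }
  (value_end - value_start) / days
}

#' Per-plot crop growth rate table
#'
#' For each plot carrying the requested trait, computes the growth rate
#' over its genotype's GS31 to GS65 window. Values at the window ends are
#' taken from an exactly matching sampling event when one exists and are
#' otherwise linearly interpolated between the bracketing events (the
#' per-genotype anthesis-date interpolation used when all plots are scanned
#' on common dates but genotypes flower on different days). Plots whose
#' sampled window does not bracket the phenology dates are excluded, with
#' the reasons attached.
#'
#' @param traits a [trait_table].
#' @param phenology a [phenology_table] covering every genotype present.
#' @param trait the trait to differentiate.
#' @return a data frame (class `trait_table`) with one row per retained
#'   plot: trait `"cgr_<trait>"`, `value` in trait units per day, `date` =
#'   the GS65 window end; window start in column `date_start`. Excluded
#'   plots are recorded in `attr(, "excluded")`.
#' @export
cgr_table <- function(traits, phenology, trait) {
  tr <- traits[traits$trait == trait, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop_pheno(sprintf("trait `%s` not present in trait table", trait),
               "phenolidar_validation_error")
  }
  genos <- unique(tr$genotype)
  missing_ph <- setdiff(genos, phenology$genotype)
  if (length(missing_ph) > 0) {
    stop_pheno(sprintf("phenology missing for genotypes: %s",
                       paste(sort(missing_ph), collapse = ", ")),
               "phenolidar_missing_phenology")
  }
  out <- list()
  excluded <- list()
  for (pid in unique(tr$plot_id)) {
    rows <- tr[tr$plot_id == pid, , drop = FALSE]
    rows <- rows[order(rows$date), , drop = FALSE]
    geno <- rows$genotype[1]
    ph <- phenology[phenology$genotype == geno, ]
    value_at <- function(target) {
      hit <- which(rows$date == target)
      if (length(hit) == 1) return(rows$value[hit])
      if (nrow(rows) < 2 || target < min(rows$date) || target > max(rows$date)) {
        return(NULL)
      }
      interpolate_trait(rows$date, rows$value, target)
    }
    v31 <- value_at(ph$gs31_date)
    v65 <- value_at(ph$gs65_date)
    if (is.null(v31) || is.null(v65)) {
      stage <- if (is.null(v31)) "GS31" else "GS65"
      excluded[[pid]] <- sprintf(
        "%s date outside sampled window [%s, %s]",
        stage, min(rows$date), max(rows$date))
      next
    }
    out[[pid]] <- data.frame(
      plot_id = pid, genotype = geno, date = ph$gs65_date,
      date_start = ph$gs31_date,
      trait = paste0("cgr_", trait),
      value = compute_cgr(v31, v65, ph$gs31_date, ph$gs65_date),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    stop_pheno("no plot has events bracketing its genotype's GS31-GS65 window",
               "phenolidar_validation_error")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(excluded) > 0) {
    message(sprintf("cgr_table: excluded %d plot(s): %s",
                    length(excluded),
                    paste(sprintf("%s (%s)", names(excluded),
                                  unlist(excluded)), collapse = "; ")))
  }
  res <- trait_table(res)
  attr(res, "excluded") <- if (length(excluded) > 0) {
    data.frame(plot_id = names(excluded),
               reason = unlist(excluded, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(plot_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  res
}
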