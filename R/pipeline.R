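# End-to-end orchestration: read -> assemble -> filter -> classify ->
# tabulate -> interrupted time series, with report-shaped CSV outputs and a
# run log.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_abx("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' Run the full evaluation pipeline
#'
#' Validates the run configuration, reads and assembles the event tables,
#' applies the institution inclusion rule, classifies antibiotics and
#' diagnoses, and writes the report bundle:
#' `table1_characteristics.csv`, `fig1_rates_by_category.csv`,
#' `table2_appropriateness.csv` (with odds ratios when `fit_or` is set),
#' `pattern_aware_spectrum.csv`, `its_results.csv`, and `run_log.txt`.
#' Any stage failure aborts with the stage name and cause.
#'
#' @param config A named list (or path to a JSON file) with elements:
#'   `prescriptions`, `diagnoses` (paths, required), `patients`,
#'   `physicians`, `institutions` (paths, optional), `tier_map`, `catalog`
#'   (paths, optional — package defaults used when absent), `study_window`
#'   (length-2 dates), `tcm_mode`, `interruption` (e.g. `"2020-03"`),
#'   `min_months`, `seasonal_adjust` (logical), `fit_or` (logical),
#'   `or_covariates` (character), `out_dir` (required), `seed`.
#' @return The output bundle (named list of tibbles plus the `its_fit`
#'   objects), invisibly; the CSVs are written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- with_stage("validate_config", {
    stopifnot(is.list(config), !is.null(config$out_dir))
    for (f in c("prescriptions", "diagnoses", "patients", "physicians",
                "institutions", "tier_map", "catalog")) {
      if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
        abort_abx("configured file for '", f, "' does not exist: ",
                  config[[f]])
      }
    }
    if (is.null(config$prescriptions) || is.null(config$diagnoses)) {
      abort_abx("config must name 'prescriptions' and 'diagnoses' files")
    }
    config
  })
  window <- as.Date(cfg$study_window %||% default_study_window())
  tcm_mode <- cfg$tcm_mode %||% "expert"
  interruption <- cfg$interruption %||% "2020-03"
  min_months <- cfg$min_months %||% 10
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  tier_map <- with_stage("load_tier_map", load_tier_map(cfg$tier_map))
  catalog <- with_stage("load_catalog", load_antibiotic_catalog(cfg$catalog))
  read_tbl <- function(path) {
    if (is.null(path)) NULL else
      readr::read_csv(path, col_types = readr::cols(
        .default = readr::col_character()), progress = FALSE)
  }
  rx <- with_stage("read_prescriptions",
                   read_events(cfg$prescriptions, "prescription", window))
  dx <- with_stage("read_diagnoses",
                   read_events(cfg$diagnoses, "diagnosis", window))
  vs <- with_stage("assemble_visits", assemble_visits(
    rx, dx, patients = read_tbl(cfg$patients),
    physicians = read_tbl(cfg$physicians),
    institutions = read_tbl(cfg$institutions)
  ))
  flt <- with_stage("filter_institutions",
                    filter_institutions(vs, min_months = min_months))
  vs <- flt$kept

  classified <- with_stage("classify_diagnoses",
                           classify_diagnosis(vs$diagnoses, tier_map,
                                              tcm_mode = tcm_mode))
  records <- with_stage("assign_appropriateness",
                        assign_visit_appropriateness(
                          vs, tier_map, catalog, tcm_mode = tcm_mode,
                          classified = classified))
  items <- with_stage("classify_antibiotics",
                      classify_antibiotics(vs$prescriptions, catalog))

  table1 <- with_stage("table1", characteristics_table(vs))
  fig1 <- with_stage("fig1_rates", prescription_rates_by_category(
    vs, tier_map, catalog, tcm_mode = tcm_mode, classified = classified))
  strata_cols <- intersect(
    c("institution_area_type", "institution_level", "patient_age_group",
      "patient_gender", "patient_payment", "year", "physician_age_group",
      "physician_gender", "physician_education"),
    names(records)
  )
  table2 <- with_stage("table2", dplyr::bind_rows(
    dplyr::mutate(tabulate_appropriateness(records),
                  stratifier = "overall", stratum = "overall"),
    dplyr::bind_rows(lapply(strata_cols, function(sc) {
      tb <- tabulate_appropriateness(records, strata = sc)
      tb$stratifier <- sc
      names(tb)[names(tb) == sc] <- "stratum"
      tb
    }))
  ))
  or_model <- NULL
  if (isTRUE(cfg$fit_or)) {
    or_model <- with_stage("fit_or_model", fit_inappropriate_or_model(
      records,
      covariates = cfg$or_covariates %||% DEFAULT_OR_COVARIATES))
  }
  pattern <- with_stage("patterns", dplyr::bind_rows(
    tabulate_antibiotic_pattern(items, by = "spectrum"),
    tabulate_antibiotic_pattern(items, by = "aware"),
    tabulate_antibiotic_pattern(items, by = "atc4")
  ))

  its_results <- with_stage("its", {
    fits <- list()
    for (oc in c("rx_rate", "inappropriate_prop")) {
      series <- aggregate_monthly(
        vs = vs, records = records, outcome = oc, catalog = catalog)
      if (anyNA(series$value)) {
        message("outcome ", oc, ": months flagged missing dropped before ",
                "seasonal adjustment")
        series <- series[!is.na(series$value), , drop = FALSE]
      }
      use <- series
      if (isTRUE(cfg$seasonal_adjust %||% TRUE) && nrow(series) >= 24) {
        use <- seasonal_adjust(series)$adjusted
      }
      fits[[oc]] <- fit_segmented(use, interruption = interruption)
    }
    fits
  })
  its_tbl <- dplyr::bind_rows(lapply(names(its_results), function(oc) {
    co <- its_results[[oc]]$coefficients
    co$outcome <- oc
    co
  }))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) readr::write_csv(x, file.path(cfg$out_dir, f))
  wr(table1, "table1_characteristics.csv")
  wr(fig1, "fig1_rates_by_category.csv")
  tbl2_out <- table2
  if (!is.null(or_model)) {
    wr(or_model$or_table, "table2_odds_ratios.csv")
  }
  wr(tbl2_out, "table2_appropriateness.csv")
  wr(pattern, "pattern_aware_spectrum.csv")
  wr(its_tbl, "its_results.csv")
  log_lines <- c(
    paste0("abxeval ", as.character(utils::packageVersion("abxeval")),
           " / R ", getRversion()),
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", cfg$seed %||% "unset"),
    paste0("study window: ", paste(window, collapse = " .. ")),
    paste0("tcm_mode: ", tcm_mode, "; interruption: ", interruption,
           "; min_months: ", min_months),
    paste0("prescription events: ", nrow(rx), "; diagnosis events: ",
           nrow(dx)),
    paste0("visits kept: ", nrow(vs$visits), "; institutions excluded: ",
           nrow(flt$excluded)),
    paste0("antibiotic-prescribing visits: ", nrow(records),
           "; antibiotic items: ", nrow(items))
  )
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  bundle <- list(
    table1 = table1, fig1_rates = fig1, table2 = table2,
    or_model = or_model, pattern = pattern, its = its_results,
    its_table = its_tbl, records = records, excluded = flt$excluded,
    config = cfg
  )
  invisible(bundle)
}

# visit counts and column percentages by area type for each attribute
characteristics_table <- function(vs) {
  attrs <- c("institution_level", "patient_age_group", "patient_gender",
             "patient_payment", "physician_age_group", "physician_gender",
             "physician_education")
  attrs <- intersect(attrs, names(vs$visits))
  v <- vs$visits
  v$year <- format(v$visit_date, "%Y")
  attrs <- c(attrs, "year")
  dplyr::bind_rows(lapply(attrs, function(a) {
    out <- dplyr::count(v, .data$institution_area_type, .data[[a]],
                        name = "n")
    names(out)[2] <- "level"
    out <- tidyr::pivot_wider(out, names_from = "institution_area_type",
                              values_from = "n", values_fill = 0L)
    out$attribute <- a
    out$all <- rowSums(out[setdiff(names(out), c("level", "attribute"))])
    out$pct_all <- 100 * out$all / sum(out$all)
    out
  }))
}

#' Render a human-readable summary of a pipeline bundle
#'
#' One markdown report with the headline numbers — overall prescription
#' rate, appropriateness mix, AWaRe/spectrum mix, and the segmented
#' regression coefficients — each formatted at one decimal (half away from
#' zero); empty strata render as an em dash.
#'
#' @param bundle Output of [run_pipeline()].
#' @return A character scalar of markdown.
#' @export
render_summary <- function(bundle) {
  t2 <- bundle$table2[bundle$table2$stratifier == "overall", ]
  line_for <- function(lvl) {
    r <- t2[t2$appropriateness == lvl, ]
    if (nrow(r) == 0 || r$denominator == 0) return("—")
    paste0(format_pct(r$proportion), "% (", r$n, "/", r$denominator, ")")
  }
  pat <- bundle$pattern
  pct_of <- function(classifier, lvl) {
    r <- pat[pat$classifier == classifier & pat$level == lvl, ]
    if (nrow(r) == 0) "—" else paste0(format_pct(sum(r$proportion)), "%")
  }
  its_line <- function(oc) {
    f <- bundle$its[[oc]]
    if (is.null(f)) return("—")
    co <- f$coefficients
    g <- function(term) {
      r <- co[co$term == term, ]
      paste0(format_pct(r$estimate), " (", format_pct(r$ci_low), " to ",
             format_pct(r$ci_high), ")")
    }
    paste0("trend before ", g("trend_before"), "; level change ",
           g("level_change"), "; slope change ", g("slope_change"),
           "; trend after ", g("trend_after"))
  }
  fig1 <- bundle$fig1_rates
  overall_rate <- paste0(
    format_pct(100 * sum(fig1$x) / sum(fig1$n)), "% (",
    sum(fig1$x), "/", sum(fig1$n), ")"
  )
  paste(c(
    "# Antibiotic prescribing evaluation summary",
    "",
    paste0("- Overall antibiotic prescription rate: ", overall_rate),
    paste0("- Appropriate: ", line_for("appropriate")),
    paste0("- Potentially appropriate: ",
           line_for("potentially_appropriate")),
    paste0("- Inappropriate: ", line_for("inappropriate")),
    paste0("- Not linked to any diagnosis: ", line_for("not_linked")),
    paste0("- Broad-spectrum share of items: ", pct_of("spectrum", "broad")),
    paste0("- Watch share of items: ", pct_of("aware", "Watch")),
    "",
    "## Interrupted time series",
    paste0("- Prescription rate: ", its_line("rx_rate")),
    paste0("- Inappropriate proportion: ", its_line("inappropriate_prop"))
  ), collapse = "\n")
}
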