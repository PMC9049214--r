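# Synthetic visit-level prescribing records with ground-truth bookkeeping.
#
# The generator emulates the statistical structure the analysis assumes:
# four institution types (urban/rural x center/station), ~50 monthly visit
# streams, patient/physician attribute margins, a 30-category + TCM
# diagnostic spectrum in three tiers, tier-dependent prescribing
# probabilities with institution random intercepts and covariate effects on
# the logit scale, 12-month seasonality, and a step + slope change at the
# pandemic month. Monthly volumes default to a deliberate scale-down of the
# source setting so the full pipeline runs at desk scale.

#' Build and validate a simulation configuration
#'
#' Defaults encode the emulated study setting: 155 institutions (51
#' centers/township hospitals, 104 stations/village clinics, with the urban
#' share of visits near 61%), the June 2017 - July 2021 window (50 months),
#' a 13% TCM fraction, tier-wise baseline prescribing probabilities
#' 0.6/0.5/0.2, institution random-intercept SD 0.3 on the logit scale, a
#' 2-percentage-point winter-peaking seasonal term, and a COVID-19
#' interruption at March 2020 with a -2.8 pp level change and +0.3 pp/month
#' slope change applied to the prescribing probability. Seasonal, trend and
#' COVID terms act additively on the probability scale (in percentage
#' points) so the segmented-regression parameters are recovered in the same
#' units they are specified in.
#'
#' @param seed Integer seed used by [simulate_dataset()].
#' @param n_institutions Named counts per (area x level) cell.
#' @param window_start First month of the window (Date or string).
#' @param n_months Number of calendar months (>= 24).
#' @param mean_monthly_visits Poisson mean visits per institution-month.
#' @param tier_prob Baseline prescribing probability per tier (length 3).
#' @param tcm_fraction Fraction of diagnoses carrying TCM codes.
#' @param sigma_u SD of the institution random intercept (logit scale).
#' @param covariate_effects Named list of named numeric vectors: additive
#'   logit effects per attribute level (reference levels 0).
#' @param seasonal_amplitude_pp Amplitude (pp) of the cosine month effect
#'   peaking in January.
#' @param baseline_trend_pp Secular trend in pp per month.
#' @param covid List: `month`, `level_pp`, `slope_pp`.
#' @param multi_dx_prob Probability of a secondary diagnosis from a
#'   different tier (exercises the priority rule).
#' @param not_linked_prob Probability a prescribing visit loses its
#'   diagnosis record (yields "not linked" visits).
#' @param nonabx_rx_prob Probability a visit carries a non-antibiotic drug
#'   row (exercises catalogue filtering).
#' @param second_item_prob Probability a prescribing visit receives a second
#'   antibiotic item.
#' @param spectrum Optional tibble `category, tier, weight` overriding the
#'   default diagnostic spectrum.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_institutions = c(urban_CHSC_TH = 26,
                                                 urban_CHSS_VC = 78,
                                                 rural_CHSC_TH = 25,
                                                 rural_CHSS_VC = 26),
                              window_start = "2017-06-01",
                              n_months = 50,
                              mean_monthly_visits = 60,
                              tier_prob = c(0.6, 0.5, 0.2),
                              tcm_fraction = 0.13,
                              sigma_u = 0.3,
                              covariate_effects = default_covariate_effects(),
                              seasonal_amplitude_pp = 2,
                              baseline_trend_pp = -0.05,
                              covid = list(month = "2020-03",
                                           level_pp = -2.8, slope_pp = 0.3),
                              multi_dx_prob = 0.1,
                              not_linked_prob = 2e-4,
                              nonabx_rx_prob = 0.3,
                              second_item_prob = 0.1,
                              spectrum = NULL) {
  cfg <- list(seed = as.integer(seed), n_institutions = n_institutions,
              window_start = as.Date(window_start), n_months = n_months,
              mean_monthly_visits = mean_monthly_visits,
              tier_prob = tier_prob, tcm_fraction = tcm_fraction,
              sigma_u = sigma_u, covariate_effects = covariate_effects,
              seasonal_amplitude_pp = seasonal_amplitude_pp,
              baseline_trend_pp = baseline_trend_pp, covid = covid,
              multi_dx_prob = multi_dx_prob,
              not_linked_prob = not_linked_prob,
              nonabx_rx_prob = nonabx_rx_prob,
              second_item_prob = second_item_prob,
              spectrum = spectrum %||% default_spectrum())
  if (cfg$n_months < 24) abort_abx("n_months must be >= 24")
  if (any(cfg$tier_prob <= 0 | cfg$tier_prob >= 1)) {
    abort_abx("tier probabilities must be in (0, 1)")
  }
  if (abs(sum(cfg$spectrum$weight) - 1) > 1e-8) {
    abort_abx("spectrum weights must sum to 1")
  }
  if (cfg$sigma_u < 0) abort_abx("sigma_u must be nonnegative")
  if (cfg$tcm_fraction < 0 || cfg$tcm_fraction > 1) {
    abort_abx("tcm_fraction must be in [0, 1]")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Default diagnostic spectrum of the generator
#'
#' Category weights over the 30 ICD-10 categories of the shipped tier map,
#' dominated by tier-3 chronic and viral conditions as in routine primary
#' care, with small tier-1/tier-2 infection shares.
#'
#' @return Tibble `category, tier, weight` with weights summing to 1.
#' @export
default_spectrum <- function() {
  w <- c(
    urinary_tract_infection = 0.013, pneumonia = 0.004,
    skin_soft_tissue_infection = 0.006,
    sexually_transmitted_infection = 0.001,
    other_tier1_bacterial_infection = 0.002,
    acute_otitis_media = 0.002, acute_sinusitis = 0.002,
    acute_pharyngitis = 0.010, acute_tonsillitis = 0.010,
    infectious_gastroenteritis = 0.012,
    chronic_obstructive_pulmonary_disease = 0.030,
    otitis_externa = 0.003, acne = 0.003, chronic_sinusitis = 0.003,
    eye_infection = 0.008, pelvic_inflammatory_disease = 0.004,
    dental_infection = 0.008, other_respiratory_infection = 0.005,
    other_tier2_diagnosis = 0.004,
    acute_bronchitis = 0.030, viral_upper_respiratory_infection = 0.120,
    influenza = 0.003, unspecific_fever = 0.004, asthma = 0.015,
    allergy = 0.020, non_infectious_gastroenteritis = 0.020,
    gastritis = 0.070, cardiovascular_disease = 0.350, diabetes = 0.130,
    non_specific_digestive_symptoms = 0.108
  )
  map <- load_tier_map()
  icd <- dplyr::distinct(map[map$code_system == "ICD10", ],
                         .data$category, .data$tier)
  out <- tibble::tibble(category = names(w), weight = unname(w))
  out <- dplyr::left_join(out, icd, by = "category")
  if (anyNA(out$tier)) abort_abx("spectrum category missing from tier map")
  out$weight <- out$weight / sum(out$weight)
  out[c("category", "tier", "weight")]
}

#' Default covariate effects on the prescribing logit
#'
#' Small additive logit effects per attribute level (reference levels carry
#' 0), of magnitudes in line with the subgroup contrasts of the emulated
#' setting.
#'
#' @return Named list of named numeric vectors.
#' @export
default_covariate_effects <- function() {
  list(
    patient_age_group = c("<6" = 0.45, "6-17" = 0.30, "18-44" = 0,
                          "45-64" = -0.05, ">=65" = -0.10),
    patient_gender = c(male = 0, female = -0.10),
    patient_payment = c(insurance = 0, out_of_pocket = -0.07),
    physician_age_group = c("<30" = 0, "30-39" = -0.07, "40-49" = 0.03,
                            "50-59" = 0.08, ">=60" = -0.06),
    physician_gender = c(male = 0, female = -0.14),
    physician_education = c(high_school_or_below = 0,
                            bachelor_or_above = 0.02),
    institution_area_type = c(rural = 0, urban = -0.36),
    institution_level = c(CHSS_VC = 0, CHSC_TH = -0.43)
  )
}

# attribute margins of the emulated setting (visit-level proportions)
PATIENT_AGE_MARGIN <- c("<6" = 0.071, "6-17" = 0.063, "18-44" = 0.226,
                        "45-64" = 0.366, ">=65" = 0.275)
PATIENT_GENDER_MARGIN <- c(male = 0.460, female = 0.540)
PAYMENT_MARGIN <- c(insurance = 0.791, out_of_pocket = 0.209)
PHYSICIAN_AGE_MARGIN <- c("<30" = 0.061, "30-39" = 0.373, "40-49" = 0.290,
                          "50-59" = 0.187, ">=60" = 0.089)
PHYSICIAN_GENDER_MARGIN <- c(male = 0.440, female = 0.560)
PHYSICIAN_EDU_MARGIN <- c(bachelor_or_above = 0.245,
                          high_school_or_below = 0.755)

NON_ANTIBIOTICS <- tibble::tibble(
  drug_code = c("C09AA01", "A02BC01", "M01AE01", "R05CB01", "N02BE01"),
  drug_name = c("enalapril", "omeprazole", "ibuprofen", "bromhexine",
                "paracetamol")
)

TCM_PREFIXES <- tibble::tibble(
  prefix = c("BNL", "BNF", "BWG", "BNG", "BNX"),
  weight = c(0.05, 0.30, 0.15, 0.30, 0.20)
)

# per-entry sampling weights reproducing the emulated ATC level-4 mixture
default_antibiotic_mixture <- function(catalog) {
  atc4_w <- c(J01DC = 0.181, J01MA = 0.170, J01CA = 0.155, J01DD = 0.147,
              J01DB = 0.143, J01FA = 0.060, J01CR = 0.030, J01XD = 0.020,
              P01AB = 0.020, J01GB = 0.020)
  w <- atc4_w[catalog$atc4]
  w[is.na(w)] <- (1 - sum(atc4_w)) / sum(is.na(w))
  # rare agents: keep Reserve and Unclassified entries genuinely rare
  w[catalog$aware %in% c("Reserve", "Unclassified")] <-
    w[catalog$aware %in% c("Reserve", "Unclassified")] / 200
  cnt <- table(catalog$atc4)[catalog$atc4]
  w <- w / as.numeric(cnt)
  w / sum(w)
}

#' Simulate a visit-level prescribing dataset
#'
#' Draws, for every visit: a diagnosis from the configured spectrum (TCM
#' with the configured fraction), a prescribing decision from
#' `logit(p) = tier base + covariate effects + institution intercept`
#' shifted additively (probability scale, percentage points) by the
#' seasonal, secular-trend and COVID step/slope terms, and, when an
#' antibiotic is prescribed, one or two items from the catalogue mixture.
#' Full ground truth (per-visit tier, probability and drawn outcome) is
#' recorded so every downstream quantity can be computed without re-running
#' the generator. Output tables are loadable by [validate_events()] /
#' [assemble_visits()].
#'
#' @param config A [simulation_config()].
#' @param catalog Antibiotic catalogue used for item sampling.
#' @return An `abx_simulation`: list of tibbles `prescriptions, diagnoses,
#'   patients, physicians, institutions` and a `ground_truth` list
#'   (`config`, per-visit `truth` tibble, tier-wise summary, institution
#'   intercepts).
#' @export
simulate_dataset <- function(config = simulation_config(),
                             catalog = load_antibiotic_catalog()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cells <- config$n_institutions
  inst <- tibble::tibble(
    institution_id = sprintf("I%03d", seq_len(sum(cells))),
    cell = rep(names(cells), cells)
  )
  inst$area_type <- ifelse(startsWith(inst$cell, "urban"), "urban", "rural")
  inst$level <- ifelse(grepl("CHSC_TH", inst$cell), "CHSC_TH", "CHSS_VC")
  inst$u <- stats::rnorm(nrow(inst), 0, config$sigma_u)

  physicians <- tidyr::expand_grid(institution_id = inst$institution_id,
                                   k = 1:4)
  physicians$physician_id <- paste0(physicians$institution_id, "-D",
                                    physicians$k)
  np <- nrow(physicians)
  physicians <- tibble::tibble(
    physician_id = physicians$physician_id,
    institution_id = physicians$institution_id,
    age_group = sample(names(PHYSICIAN_AGE_MARGIN), np, TRUE,
                       PHYSICIAN_AGE_MARGIN),
    gender = sample(names(PHYSICIAN_GENDER_MARGIN), np, TRUE,
                    PHYSICIAN_GENDER_MARGIN),
    education = sample(names(PHYSICIAN_EDU_MARGIN), np, TRUE,
                       PHYSICIAN_EDU_MARGIN)
  )

  months <- seq(config$window_start, by = "month",
                length.out = config$n_months)
  grid <- tidyr::expand_grid(institution_id = inst$institution_id,
                             month = months)
  grid$n <- stats::rpois(nrow(grid), config$mean_monthly_visits)
  v <- grid[rep(seq_len(nrow(grid)), grid$n), c("institution_id", "month")]
  N <- nrow(v)
  dim_tab <- vapply(months, function(m) {
    as.integer(format(seq(m, by = "month", length.out = 2)[2] - 1, "%d"))
  }, integer(1))
  names(dim_tab) <- format(months, "%Y-%m")
  v$visit_date <- v$month +
    (sample.int(31L, N, replace = TRUE) - 1L) %%
      dim_tab[format(v$month, "%Y-%m")]
  v$patient_id <- sprintf("P%07d", seq_len(N))
  v$physician_id <- paste0(v$institution_id, "-D",
                           sample.int(4L, N, replace = TRUE))

  patients <- tibble::tibble(
    patient_id = v$patient_id,
    age_group = sample(names(PATIENT_AGE_MARGIN), N, TRUE,
                       PATIENT_AGE_MARGIN),
    gender = sample(names(PATIENT_GENDER_MARGIN), N, TRUE,
                    PATIENT_GENDER_MARGIN),
    payment = sample(names(PAYMENT_MARGIN), N, TRUE, PAYMENT_MARGIN)
  )

  # diagnosis draw
  spec <- config$spectrum
  is_tcm <- stats::runif(N) < config$tcm_fraction
  cat_idx <- sample.int(nrow(spec), N, replace = TRUE, prob = spec$weight)
  v$category <- ifelse(is_tcm, "tcm", spec$category[cat_idx])
  tmap <- load_tier_map()
  tcm_rows <- tmap[tmap$code_system == "TCM" &
                     tmap$code_prefix %in% TCM_PREFIXES$prefix, ]
  tcm_pick <- sample.int(nrow(TCM_PREFIXES), N, replace = TRUE,
                         prob = TCM_PREFIXES$weight)
  v$tier <- ifelse(is_tcm,
                   tcm_rows$tier[match(TCM_PREFIXES$prefix[tcm_pick],
                                       tcm_rows$code_prefix)],
                   spec$tier[cat_idx])
  # a concrete code for the drawn category: random prefix of the category
  icd_rows <- tmap[tmap$code_system == "ICD10", ]
  prefixes_by_cat <- split(icd_rows$code_prefix, icd_rows$category)
  pick_code <- function(cats) {
    out <- character(length(cats))
    for (cc in unique(cats)) {
      idx <- which(cats == cc)
      px <- prefixes_by_cat[[cc]]
      out[idx] <- paste0(px[sample.int(length(px), length(idx),
                                       replace = TRUE)],
                         ".", sample(0:9, length(idx), replace = TRUE))
    }
    out
  }
  v$diagnosis_code <- NA_character_
  v$diagnosis_code[!is_tcm] <- pick_code(v$category[!is_tcm])
  v$diagnosis_code[is_tcm] <- paste0(
    TCM_PREFIXES$prefix[tcm_pick[is_tcm]],
    sprintf("%02d", sample(0:99, sum(is_tcm), replace = TRUE))
  )
  v$code_system <- ifelse(is_tcm, "TCM", "ICD10")

  # prescribing probability
  eff <- config$covariate_effects
  logit <- stats::qlogis(config$tier_prob[v$tier]) +
    eff$patient_age_group[patients$age_group] +
    eff$patient_gender[patients$gender] +
    eff$patient_payment[patients$payment] +
    eff$physician_age_group[
      physicians$age_group[match(v$physician_id, physicians$physician_id)]] +
    eff$physician_gender[
      physicians$gender[match(v$physician_id, physicians$physician_id)]] +
    eff$physician_education[
      physicians$education[match(v$physician_id, physicians$physician_id)]] +
    eff$institution_area_type[
      inst$area_type[match(v$institution_id, inst$institution_id)]] +
    eff$institution_level[
      inst$level[match(v$institution_id, inst$institution_id)]] +
    inst$u[match(v$institution_id, inst$institution_id)]
  t0 <- month_diff(v$month, months[1])
  covid_month <- first_of_month(paste0(config$covid$month, "-01"))
  rel <- month_diff(v$month, covid_month)
  moy <- as.integer(format(v$month, "%m"))
  seasonal <- config$seasonal_amplitude_pp * cos(2 * pi * (moy - 1) / 12)
  shift_pp <- seasonal + config$baseline_trend_pp * t0 +
    config$covid$level_pp * (rel >= 0) +
    config$covid$slope_pp * pmax(0, rel)
  p <- pmin(1 - 1e-4, pmax(1e-4, stats::plogis(unname(logit)) +
                             shift_pp / 100))
  v$p <- p
  v$prescribed <- stats::runif(N) < p

  # antibiotic items
  mix <- default_antibiotic_mixture(catalog)
  rx_idx <- which(v$prescribed)
  second <- rx_idx[stats::runif(length(rx_idx)) < config$second_item_prob]
  item_rows <- c(rx_idx, second)
  picked <- sample.int(nrow(catalog), length(item_rows), replace = TRUE,
                       prob = mix)
  abx <- tibble::tibble(
    institution_id = v$institution_id[item_rows],
    patient_id = v$patient_id[item_rows],
    visit_date = v$visit_date[item_rows],
    drug_code = catalog$atc_code[picked],
    drug_name = catalog$generic_name[picked],
    route = ifelse(startsWith(catalog$atc_code[picked], "P01AB"), "oral",
                   sample(c("oral", "parenteral"), length(item_rows), TRUE,
                          c(0.8, 0.2))),
    physician_id = v$physician_id[item_rows]
  )
  nonabx_rows <- which(stats::runif(N) < config$nonabx_rx_prob)
  na_pick <- sample.int(nrow(NON_ANTIBIOTICS), length(nonabx_rows),
                        replace = TRUE)
  nonabx <- tibble::tibble(
    institution_id = v$institution_id[nonabx_rows],
    patient_id = v$patient_id[nonabx_rows],
    visit_date = v$visit_date[nonabx_rows],
    drug_code = NON_ANTIBIOTICS$drug_code[na_pick],
    drug_name = NON_ANTIBIOTICS$drug_name[na_pick],
    route = "oral",
    physician_id = v$physician_id[nonabx_rows]
  )
  prescriptions <- dplyr::bind_rows(abx, nonabx)

  # diagnosis stream: primary diagnosis, optional secondary from another
  # tier, with a small fraction of prescribing visits losing their record
  lost <- v$prescribed & stats::runif(N) < config$not_linked_prob
  dx1 <- tibble::tibble(
    institution_id = v$institution_id, patient_id = v$patient_id,
    visit_date = v$visit_date, code_system = v$code_system,
    diagnosis_code = v$diagnosis_code
  )[!lost, ]
  sec_rows <- which(!lost & stats::runif(N) < config$multi_dx_prob)
  if (length(sec_rows) > 0) {
    other <- integer(length(sec_rows))
    for (tt in unique(v$tier[sec_rows])) {
      idx <- which(v$tier[sec_rows] == tt)
      cand <- which(spec$tier != tt)
      other[idx] <- cand[sample.int(length(cand), length(idx),
                                    replace = TRUE)]
    }
    dx2 <- tibble::tibble(
      institution_id = v$institution_id[sec_rows],
      patient_id = v$patient_id[sec_rows],
      visit_date = v$visit_date[sec_rows],
      code_system = "ICD10",
      diagnosis_code = pick_code(spec$category[other])
    )
    diagnoses <- dplyr::bind_rows(dx1, dx2)
  } else {
    diagnoses <- dx1
  }

  truth <- tibble::tibble(
    visit_id = paste(v$institution_id, v$patient_id,
                     format(v$visit_date, "%Y-%m-%d"), sep = "|"),
    month = v$month, tier = v$tier, category = v$category,
    is_tcm = is_tcm, p = v$p, prescribed = v$prescribed,
    not_linked = lost
  )
  tier_summary <- dplyr::summarise(
    dplyr::group_by(truth, .data$tier),
    n = dplyr::n(), target_p = mean(.data$p),
    empirical_rate = mean(.data$prescribed), .groups = "drop"
  )
  structure(
    list(
      prescriptions = prescriptions, diagnoses = diagnoses,
      patients = patients,
      physicians = physicians[c("physician_id", "age_group", "gender",
                                "education")],
      institutions = inst[c("institution_id", "area_type", "level")],
      ground_truth = list(config = config, truth = truth,
                          tier_summary = tier_summary,
                          institution_intercepts = inst[c("institution_id",
                                                          "u")])
    ),
    class = "abx_simulation"
  )
}

#' @export
print.abx_simulation <- function(x, ...) {
  cat("<abx_simulation> ", nrow(x$ground_truth$truth), " visits, ",
      nrow(x$prescriptions), " prescription rows, ",
      nrow(x$diagnoses), " diagnosis rows, ",
      nrow(x$institutions), " institutions\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to delimited files
#'
#' Emits `prescriptions.csv`, `diagnoses.csv`, `patients.csv`,
#' `physicians.csv`, `institutions.csv`, the per-visit `visit_truth.csv`,
#' and `ground_truth.json` (configuration echo and tier-wise summary).
#'
#' @param sim An `abx_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "abx_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$prescriptions, file.path(dir, "prescriptions.csv"))
  readr::write_csv(sim$diagnoses, file.path(dir, "diagnoses.csv"))
  readr::write_csv(sim$patients, file.path(dir, "patients.csv"))
  readr::write_csv(sim$physicians, file.path(dir, "physicians.csv"))
  readr::write_csv(sim$institutions, file.path(dir, "institutions.csv"))
  readr::write_csv(sim$ground_truth$truth, file.path(dir, "visit_truth.csv"))
  cfg <- unclass(sim$ground_truth$config)
  cfg$spectrum <- NULL
  cfg$window_start <- format(cfg$window_start, "%Y-%m-%d")
  jsonlite::write_json(
    list(config = cfg, tier_summary = sim$ground_truth$tier_summary),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Simulate monthly outcome series directly
#'
#' Bypasses the visit level for fast estimator testing: each replicate is
#' \deqn{Y_t = \beta_0 + \beta_1 t_0 + \beta_2 Intv_t + \beta_3 taft_t +
#'   s_{m(t)} + e_t}
#' with `Intv = 1` from the interruption month on, `taft` months elapsed
#' since it (0 at the interruption), a fixed calendar-month effect `s`, and
#' AR(1) noise `e_t = rho e_{t-1} + innov`, innovations N(0, sd), started
#' from the stationary distribution.
#'
#' @param n_months Series length (default 50, June 2017 - July 2021).
#' @param beta Numeric (level, trend, level change, slope change); the
#'   default emulates a prescribing-rate series with the study-magnitude
#'   pandemic effect.
#' @param interruption_month 1-based index of the interruption month
#'   (default 34 = March 2020 with the default start).
#' @param rho AR(1) coefficient of the noise.
#' @param sd Innovation SD.
#' @param seasonal Length-12 calendar-month effects (January first),
#'   default all zero.
#' @param replicates Number of replicate series.
#' @param start First month (Date or string).
#' @return A `monthly_series` when `replicates == 1`, otherwise a list of
#'   them. Each carries its generating parameters in attribute `"truth"`.
#' @export
simulate_monthly_series <- function(n_months = 50,
                                    beta = c(20, -0.2, -2.8, 0.3),
                                    interruption_month = 34,
                                    rho = 0.3, sd = 1,
                                    seasonal = rep(0, 12),
                                    replicates = 1,
                                    start = "2017-06-01") {
  stopifnot(length(beta) == 4, length(seasonal) == 12, replicates >= 1,
            interruption_month > 1, interruption_month <= n_months)
  months <- seq(as.Date(start), by = "month", length.out = n_months)
  t0 <- 0:(n_months - 1)
  m <- seq_len(n_months)
  intv <- as.integer(m >= interruption_month)
  taft <- pmax(0L, m - interruption_month)
  moy <- as.integer(format(months, "%m"))
  det <- beta[1] + beta[2] * t0 + beta[3] * intv + beta[4] * taft +
    seasonal[moy]
  one <- function() {
    if (sd == 0) {
      e <- rep(0, n_months)
    } else {
      innov <- stats::rnorm(n_months, 0, sd)
      e <- numeric(n_months)
      e[1] <- if (abs(rho) < 1) innov[1] / sqrt(1 - rho^2) else innov[1]
      for (t in 2:n_months) e[t] <- rho * e[t - 1] + innov[t]
    }
    out <- as_monthly_series(tibble::tibble(month = months, t0 = t0,
                                            value = det + e))
    attr(out, "truth") <- list(beta = beta,
                               interruption_month = interruption_month,
                               rho = rho, sd = sd, seasonal = seasonal)
    out
  }
  if (replicates == 1) one() else replicate(replicates, one(),
                                            simplify = FALSE)
}
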