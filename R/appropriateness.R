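# Diagnosis tier classification and visit-level appropriateness.
#
# Diagnoses are mapped to 30 diagnostic categories, each in one of three
# tiers: tier 1 almost always justifies antibiotics, tier 2 sometimes,
# tier 3 almost never. Traditional Chinese medicine (TCM) codes carry their
# own mapping (expert mode) or are forced wholesale to tier 2 / tier 3 in
# the two sensitivity modes, and all contribute to a single umbrella "tcm"
# category when tabulating rates by diagnostic category.

APPROPRIATENESS_LEVELS <- c("appropriate", "potentially_appropriate",
                            "inappropriate", "not_linked")

#' Load the diagnosis tier map
#'
#' Reads and validates the code-prefix to category/tier mapping. Prefixes must
#' be unique within a code system, tiers must be 1, 2 or 3, and every ICD-10
#' category must carry exactly one tier. TCM rows all map to the single
#' umbrella `tcm` category but may carry different tiers per code prefix
#' (the expert classification).
#'
#' @param path Mapping CSV with columns
#'   `code_system, code_prefix, category, tier`; default is the file shipped
#'   with the package.
#' @return A validated tibble; the file-order category index used for
#'   deterministic tie-breaking is attached as column `category_index`.
#' @export
load_tier_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tier_map.csv",
                                package = "abxeval", mustWork = TRUE)
  map <- readr::read_csv(path, col_types = readr::cols(
    code_system = readr::col_character(),
    code_prefix = readr::col_character(),
    category = readr::col_character(),
    tier = readr::col_integer()), progress = FALSE)
  required <- c("code_system", "code_prefix", "category", "tier")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0) {
    abort_abx("tier map is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  if (!all(map$code_system %in% c("ICD10", "TCM"))) {
    abort_abx("tier map code_system must be ICD10 or TCM")
  }
  if (!all(map$tier %in% 1:3)) abort_abx("tier map tiers must be in {1,2,3}")
  key <- paste(map$code_system, normalize_code(map$code_prefix))
  if (anyDuplicated(key)) {
    abort_abx("duplicate code prefix(es) in tier map: ",
              paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  icd <- map[map$code_system == "ICD10", ]
  multi <- tapply(icd$tier, icd$category, function(t) length(unique(t)))
  if (any(multi > 1)) {
    abort_abx("ICD-10 category mapped to more than one tier: ",
              paste(names(multi)[multi > 1], collapse = ", "))
  }
  map$category_index <- match(map$category, unique(map$category))
  map
}

# strip punctuation and upper-case, so "J18.9" matches prefix "J18"
normalize_code <- function(x) {
  toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))
}

#' Classify diagnoses into categories and tiers
#'
#' ICD-10 codes are matched by longest matching prefix after stripping
#' punctuation; TCM codes are matched against the TCM mapping in `expert`
#' mode, or forced to tier 2 (`all_tier2`) / tier 3 (`all_tier3`) in the two
#' sensitivity modes (always under the umbrella `tcm` category). Codes with
#' no matching prefix are returned unmatched (`tier` is `NA`) and counted;
#' they are excluded from tier assignment downstream.
#'
#' @param diagnoses Diagnosis events (tibble with `code_system`,
#'   `diagnosis_code`; other columns pass through).
#' @param tier_map Mapping from [load_tier_map()].
#' @param tcm_mode `"expert"`, `"all_tier2"` or `"all_tier3"`.
#' @return `diagnoses` with added `category`, `tier` (integer or `NA`),
#'   `category_index` columns.
#' @export
classify_diagnosis <- function(diagnoses, tier_map = load_tier_map(),
                               tcm_mode = c("expert", "all_tier2",
                                            "all_tier3")) {
  tcm_mode <- match.arg(tcm_mode)
  dx <- tibble::as_tibble(diagnoses)
  code <- normalize_code(dx$diagnosis_code)
  prefix <- normalize_code(tier_map$code_prefix)
  map_key <- paste(tier_map$code_system, prefix)

  hit <- rep(NA_integer_, nrow(dx))
  # longest-prefix-wins: try prefix lengths from longest to shortest
  for (len in sort(unique(nchar(prefix)), decreasing = TRUE)) {
    need <- is.na(hit) & nchar(code) >= len
    if (!any(need)) next
    cand <- match(paste(dx$code_system[need], substr(code[need], 1, len)),
                  map_key)
    ok <- !is.na(cand) & nchar(prefix)[cand] == len
    hit[which(need)[ok]] <- cand[ok]
  }
  dx$category <- tier_map$category[hit]
  dx$tier <- tier_map$tier[hit]
  dx$category_index <- tier_map$category_index[hit]

  if (tcm_mode != "expert") {
    is_tcm <- dx$code_system == "TCM"
    forced_tier <- if (tcm_mode == "all_tier2") 2L else 3L
    dx$tier[is_tcm] <- forced_tier
    dx$category[is_tcm] <- "tcm"
    tcm_idx <- tier_map$category_index[match("tcm", tier_map$category)]
    dx$category_index[is_tcm] <- tcm_idx %||% max(tier_map$category_index) + 1L
  }
  n_unmatched <- sum(is.na(dx$tier))
  if (n_unmatched > 0) {
    message(n_unmatched, " diagnosis code(s) with no prefix match; ",
            "excluded from tier assignment")
  }
  dx
}

# one (category, tier) per visit by the priority rules:
# best (lowest) tier wins; within the best tier allopathic (ICD10) beats TCM;
# remaining ties broken by the lowest category index in the tier map file.
assign_visit_diagnosis <- function(classified) {
  matched <- dplyr::filter(classified, !is.na(.data$tier))
  if (nrow(matched) == 0) {
    return(tibble::tibble(visit_id = character(),
                          assigned_category = character(),
                          assigned_tier = integer()))
  }
  matched <- dplyr::arrange(
    matched, .data$visit_id, .data$tier,
    .data$code_system == "TCM", .data$category_index
  )
  best <- dplyr::distinct(matched, .data$visit_id, .keep_all = TRUE)
  tibble::tibble(visit_id = best$visit_id,
                 assigned_category = best$category,
                 assigned_tier = best$tier)
}

#' Assign an appropriateness category to each antibiotic-prescribing visit
#'
#' For every visit with at least one antibiotic item, one diagnosis
#' (category, tier) is selected by priority — tier 1 beats tier 2 beats
#' tier 3; within the best tier allopathic (ICD-10) diagnoses beat TCM; any
#' remaining tie goes to the lowest category index in the tier map file —
#' and the appropriateness label follows: tier 1 is `appropriate`, tier 2
#' (with no tier 1) `potentially_appropriate`, only tier 3
#' `inappropriate`, and no matched diagnosis at all `not_linked`.
#'
#' @param vs A `visit_set` from [assemble_visits()].
#' @param tier_map Mapping from [load_tier_map()].
#' @param catalog Antibiotic catalogue from [load_antibiotic_catalog()].
#' @param tcm_mode TCM handling passed to [classify_diagnosis()].
#' @param classified Optional pre-classified diagnoses (output of
#'   [classify_diagnosis()] on `vs$diagnoses`); computed if `NULL`.
#' @return A tibble with one row per antibiotic-prescribing visit:
#'   the visit key and attributes, `assigned_category`, `assigned_tier`
#'   (`NA` for `not_linked`), `appropriateness` (factor with the four
#'   levels), and `year` of the visit.
#' @export
assign_visit_appropriateness <- function(vs, tier_map = load_tier_map(),
                                         catalog = load_antibiotic_catalog(),
                                         tcm_mode = "expert",
                                         classified = NULL) {
  stopifnot(inherits(vs, "visit_set"))
  items <- classify_antibiotics(vs$prescriptions, catalog)
  abx_ids <- unique(items$visit_id)
  if (is.null(classified)) {
    classified <- classify_diagnosis(vs$diagnoses, tier_map,
                                     tcm_mode = tcm_mode)
  }
  best <- assign_visit_diagnosis(
    dplyr::filter(classified, .data$visit_id %in% abx_ids)
  )
  rec <- dplyr::filter(vs$visits, .data$visit_id %in% abx_ids)
  rec <- dplyr::left_join(rec, best, by = "visit_id")
  rec$appropriateness <- factor(
    dplyr::case_when(
      is.na(rec$assigned_tier) ~ "not_linked",
      rec$assigned_tier == 1L ~ "appropriate",
      rec$assigned_tier == 2L ~ "potentially_appropriate",
      TRUE ~ "inappropriate"
    ),
    levels = APPROPRIATENESS_LEVELS
  )
  rec$year <- format(rec$visit_date, "%Y")
  rec
}

#' Tabulate appropriateness categories, optionally by subgroup
#'
#' Counts and proportions of the four appropriateness categories. The
#' denominator of every stratum is all its antibiotic-prescribing visits,
#' including those not linked to any diagnosis. Simultaneous 95% Goodman
#' bounds over the four categories are attached per stratum.
#'
#' @param records Output of [assign_visit_appropriateness()].
#' @param strata Optional character vector of stratifier columns in
#'   `records` (e.g. `"year"`, `"institution_area_type"`).
#' @param alpha Simultaneous error level for the Goodman bounds.
#' @return Tibble of `(strata..., appropriateness, n, denominator,
#'   proportion, ci_low, ci_high)` with proportions and bounds in percent.
#' @export
tabulate_appropriateness <- function(records, strata = NULL, alpha = 0.05) {
  grp <- c(strata, "appropriateness")
  out <- dplyr::count(records, dplyr::across(dplyr::all_of(grp)),
                      name = "n", .drop = FALSE)
  out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(strata)))
  out <- dplyr::mutate(
    out,
    denominator = sum(.data$n),
    proportion = 100 * .data$n / sum(.data$n)
  )
  out <- dplyr::mutate(
    out,
    ci_low = 100 * goodman_ci(.data$n, alpha = alpha)$ci_low,
    ci_high = 100 * goodman_ci(.data$n, alpha = alpha)$ci_high
  )
  dplyr::ungroup(out)
}

#' Antibiotic prescription rates by assigned diagnostic category
#'
#' Every visit (with or without antibiotics) receives one diagnostic category
#' by the same priority rules as the appropriateness assignment; the rate in
#' a category is the percentage of its visits that ended with at least one
#' antibiotic prescription, with Clopper-Pearson 95% intervals.
#'
#' @inheritParams assign_visit_appropriateness
#' @param strata Optional extra stratifier columns from `vs$visits`.
#' @param alpha Error level for the exact intervals.
#' @return Tibble of `(strata..., assigned_category, x, n, rate, ci_low,
#'   ci_high)` in percent. Visits whose codes are all unmatched appear under
#'   category `NA`.
#' @export
prescription_rates_by_category <- function(vs, tier_map = load_tier_map(),
                                           catalog = load_antibiotic_catalog(),
                                           tcm_mode = "expert",
                                           strata = NULL, alpha = 0.05,
                                           classified = NULL) {
  stopifnot(inherits(vs, "visit_set"))
  items <- classify_antibiotics(vs$prescriptions, catalog)
  if (is.null(classified)) {
    classified <- classify_diagnosis(vs$diagnoses, tier_map,
                                     tcm_mode = tcm_mode)
  }
  best <- assign_visit_diagnosis(classified)
  v <- dplyr::left_join(vs$visits, best, by = "visit_id")
  v$has_antibiotic <- v$visit_id %in% items$visit_id
  grp <- c(strata, "assigned_category")
  out <- dplyr::summarise(
    dplyr::group_by(v, dplyr::across(dplyr::all_of(grp))),
    x = sum(.data$has_antibiotic), n = dplyr::n(), .groups = "drop"
  )
  ci <- clopper_pearson_ci(out$x, out$n, alpha = alpha)
  out$rate <- ci$rate
  out$ci_low <- ci$ci_low
  out$ci_high <- ci$ci_high
  out
}
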