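# Antibiotic identification and labelling: systemic antibacterials (ATC J01)
# plus the three nitroimidazoles that are mainly used against anaerobic
# infections in Chinese outpatient care and may carry P01AB (oral) codes.

NITROIMIDAZOLES <- c("metronidazole", "tinidazole", "ornidazole")

# ATC level-4 classes counted as broad-spectrum: 2nd-4th generation
# cephalosporins, fluoroquinolones, macrolides, penicillin combinations,
# aminoglycosides.
BROAD_ATC4 <- c("J01DC", "J01DD", "J01DE", "J01MA", "J01FA",
                "J01CR", "J01GB", "J01GA")

#' Load the antibiotic catalogue
#'
#' The catalogue is an editable delimited file with columns
#' `atc_code, generic_name, atc4, spectrum, aware`; classification is fully
#' data-driven. The shipped default is a synthetic reconstruction of the
#' systemic-antibacterial list (J01 plus oral nitroimidazoles) labelled with
#' WHO AWaRe categories, with fosfomycin as the single Reserve agent and
#' cefathiamidine, cefoperazone/tazobactam, cefoperazone/sulbactam and
#' etimicin as the only Unclassified agents.
#'
#' @param path Catalogue CSV; default is the file shipped with the package.
#' @return A validated tibble with the five catalogue columns.
#' @export
load_antibiotic_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "antibiotic_catalog.csv",
                                package = "abxeval", mustWork = TRUE)
  cat_tbl <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  required <- c("atc_code", "generic_name", "atc4", "spectrum", "aware")
  missing_cols <- setdiff(required, names(cat_tbl))
  if (length(missing_cols) > 0) {
    abort_abx("catalogue is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  if (!all(cat_tbl$spectrum %in% c("broad", "narrow"))) {
    abort_abx("catalogue spectrum values must be 'broad' or 'narrow'")
  }
  if (!all(cat_tbl$aware %in% c("Access", "Watch", "Reserve", "Unclassified"))) {
    abort_abx("catalogue aware values must be Access/Watch/Reserve/Unclassified")
  }
  ok <- startsWith(cat_tbl$atc_code, "J01") |
    tolower(cat_tbl$generic_name) %in% NITROIMIDAZOLES
  if (!all(ok)) {
    abort_abx("catalogue entries must be J01 or a nitroimidazole: ",
              paste(cat_tbl$atc_code[!ok], collapse = ", "))
  }
  if (anyDuplicated(cat_tbl$atc_code)) {
    abort_abx("duplicate atc_code in catalogue: ",
              paste(unique(cat_tbl$atc_code[duplicated(cat_tbl$atc_code)]),
                    collapse = ", "))
  }
  cat_tbl
}

#' Is a prescribed drug an antibiotic?
#'
#' A drug counts as an antibiotic if its ATC code begins with `J01`
#' (systemic antibacterials) or its generic name is one of the three
#' nitroimidazoles (metronidazole, tinidazole, ornidazole — case-insensitive),
#' which may carry P01AB codes for the oral route.
#'
#' @param drug_code Character vector of ATC codes.
#' @param generic_name Character vector of generic names (recycled).
#' @return Logical vector.
#' @examples
#' is_antibiotic(c("J01DC02", "P01AB01", "C09AA01"),
#'               c("cefuroxime", "metronidazole", "enalapril"))
#' @export
is_antibiotic <- function(drug_code, generic_name = "") {
  startsWith(as.character(drug_code), "J01") |
    tolower(trimws(as.character(generic_name))) %in% NITROIMIDAZOLES
}

#' Classify antibiotic spectrum from the ATC level-4 class
#'
#' Broad-spectrum agents are the second- to fourth-generation cephalosporins
#' (J01DC, J01DD, J01DE), fluoroquinolones (J01MA), macrolides (J01FA),
#' penicillin combinations (J01CR), and aminoglycosides (J01GB, J01GA);
#' everything else (e.g. beta-lactamase-sensitive penicillins J01CE,
#' first-generation cephalosporins J01DB) is narrow-spectrum.
#'
#' @param atc4 Character vector of ATC level-4 classes (or full ATC codes,
#'   of which the first five characters are used).
#' @return Character vector `"broad"`/`"narrow"`.
#' @export
classify_spectrum <- function(atc4) {
  atc4 <- substr(as.character(atc4), 1, 5)
  unknown <- !(atc4 %in% BROAD_ATC4) & !startsWith(atc4, "J01") &
    !startsWith(atc4, "P01AB")
  if (any(unknown)) {
    warning("unknown ATC level-4 class(es) treated as narrow: ",
            paste(unique(atc4[unknown]), collapse = ", "), call. = FALSE)
  }
  ifelse(atc4 %in% BROAD_ATC4, "broad", "narrow")
}

#' Look up the WHO AWaRe category of an antibiotic
#'
#' Returns the catalogue's AWaRe label, matching first on the ATC code and
#' falling back to the lower-cased generic name. Antibiotics absent from the
#' catalogue are returned as `"Unclassified"` with a warning.
#'
#' @param drug_code Character vector of ATC codes.
#' @param generic_name Character vector of generic names.
#' @param catalog Catalogue tibble from [load_antibiotic_catalog()].
#' @return Character vector of AWaRe categories.
#' @export
classify_aware <- function(drug_code, generic_name = "",
                           catalog = load_antibiotic_catalog()) {
  idx <- match(as.character(drug_code), catalog$atc_code)
  by_name <- match(tolower(trimws(as.character(generic_name))),
                   tolower(catalog$generic_name))
  idx[is.na(idx)] <- by_name[is.na(idx)]
  out <- catalog$aware[idx]
  if (anyNA(out)) {
    warning(sum(is.na(out)),
            " antibiotic(s) absent from catalogue labelled Unclassified",
            call. = FALSE)
    out[is.na(out)] <- "Unclassified"
  }
  out
}

#' Label prescription events with catalogue classes
#'
#' Restricts a prescription-event table to antibiotic items and attaches
#' `atc4`, `spectrum` and `aware` columns. Items matching the J01 prefix but
#' missing from the catalogue get their ATC level-4 class from the code, a
#' spectrum from [classify_spectrum()], and AWaRe `"Unclassified"`.
#'
#' @param prescriptions Prescription events (validated tibble).
#' @param catalog Catalogue tibble from [load_antibiotic_catalog()].
#' @return The antibiotic subset of `prescriptions` with three extra columns.
#' @export
classify_antibiotics <- function(prescriptions,
                                 catalog = load_antibiotic_catalog()) {
  items <- dplyr::filter(
    tibble::as_tibble(prescriptions),
    is_antibiotic(.data$drug_code, .data$drug_name)
  )
  idx <- match(items$drug_code, catalog$atc_code)
  by_name <- match(tolower(trimws(items$drug_name)),
                   tolower(catalog$generic_name))
  idx[is.na(idx)] <- by_name[is.na(idx)]
  items$atc4 <- ifelse(is.na(idx), substr(items$drug_code, 1, 5),
                       catalog$atc4[idx])
  items$spectrum <- ifelse(is.na(idx), classify_spectrum(items$atc4),
                           catalog$spectrum[idx])
  items$aware <- ifelse(is.na(idx), "Unclassified", catalog$aware[idx])
  n_miss <- sum(is.na(idx))
  if (n_miss > 0) {
    message(n_miss, " antibiotic item(s) not in catalogue; ",
            "classified from the ATC code with AWaRe Unclassified")
  }
  items
}

#' Tabulate antibiotic prescribing patterns
#'
#' Counts and proportions at the individual-antibiotic level (one row of the
#' classified prescription table = one prescribed item, not one visit), by
#' any classification column, optionally within strata such as the assigned
#' diagnostic category.
#'
#' @param items Classified antibiotic items from [classify_antibiotics()].
#' @param by Column to tabulate: `"atc4"`, `"spectrum"` or `"aware"`.
#' @param strata Optional character vector of stratifier columns present in
#'   `items`.
#' @return Tibble of `(strata..., level, n, proportion)` with `proportion`
#'   in percent; proportions sum to 100 within each stratum.
#' @export
tabulate_antibiotic_pattern <- function(items,
                                        by = c("atc4", "spectrum", "aware"),
                                        strata = NULL) {
  by <- match.arg(by)
  grp <- c(strata, by)
  out <- dplyr::count(items, dplyr::across(dplyr::all_of(grp)), name = "n")
  out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(strata)))
  out <- dplyr::mutate(out, proportion = 100 * .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  names(out)[names(out) == by] <- "level"
  out$classifier <- by
  out
}
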