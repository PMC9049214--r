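#' Read prescription or diagnosis event tables
#'
#' Reads a delimited (UTF-8, comma-separated, header mandatory) event file and
#' validates it row by row. Rows failing validation are dropped and counted by
#' reason; the counts are attached as the `"rejected"` attribute and reported
#' with [message()].
#'
#' Required columns:
#' \describe{
#'   \item{prescription}{`institution_id, patient_id, visit_date, drug_code,
#'     drug_name, route, physician_id`}
#'   \item{diagnosis}{`institution_id, patient_id, visit_date, code_system,
#'     diagnosis_code`}
#' }
#'
#' @param path Path to a CSV file.
#' @param schema `"prescription"` or `"diagnosis"`.
#' @param study_window Length-2 date vector; rows dated outside it are
#'   rejected. Defaults to the June 2017 – July 2021 study window.
#' @return A tibble of validated events (`visit_date` as `Date`), with a
#'   `"rejected"` attribute: a tibble of `(reason, n)` for dropped rows.
#' @seealso [validate_events()] for in-memory tables, [assemble_visits()]
#' @export
read_events <- function(path,
                        schema = c("prescription", "diagnosis"),
                        study_window = default_study_window()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort_abx("event file does not exist: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_events(raw, schema, study_window = study_window)
}

#' Default study window
#'
#' @return Dates 2017-06-01 and 2021-07-31.
#' @export
default_study_window <- function() {
  as.Date(c("2017-06-01", "2021-07-31"))
}

#' Validate an in-memory event table
#'
#' The same validation [read_events()] applies after reading from disk:
#' missing required columns are a hard failure naming the column; rows with
#' unparseable dates, dates outside the study window, or empty codes are
#' dropped and counted by reason.
#'
#' @param events A data frame with the schema's columns.
#' @inheritParams read_events
#' @return A validated tibble with a `"rejected"` attribute.
#' @export
validate_events <- function(events,
                            schema = c("prescription", "diagnosis"),
                            study_window = default_study_window()) {
  schema <- match.arg(schema)
  required <- switch(schema,
    prescription = c("institution_id", "patient_id", "visit_date",
                     "drug_code", "drug_name", "route", "physician_id"),
    diagnosis = c("institution_id", "patient_id", "visit_date",
                  "code_system", "diagnosis_code")
  )
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort_abx("missing required column(s) in ", schema, " table: ",
              paste(missing_cols, collapse = ", "))
  }
  study_window <- as.Date(study_window)

  out <- tibble::as_tibble(events)[required]
  date_parsed <- as.Date(suppressWarnings(
    readr::parse_date(as.character(out$visit_date), format = "%Y-%m-%d")
  ))
  code_col <- if (schema == "prescription") out$drug_code else out$diagnosis_code

  reason <- rep(NA_character_, nrow(out))
  blank <- function(x) is.na(x) | trimws(as.character(x)) == ""
  reason[blank(code_col)] <- "empty_code"
  if (schema == "diagnosis") {
    bad_sys <- !out$code_system %in% c("ICD10", "TCM")
    reason[is.na(reason) & bad_sys] <- "unknown_code_system"
  }
  reason[is.na(reason) & is.na(date_parsed)] <- "unparseable_date"
  outside <- !is.na(date_parsed) &
    (date_parsed < study_window[1] | date_parsed > study_window[2])
  reason[is.na(reason) & outside] <- "date_outside_window"

  keep <- is.na(reason)
  rejected <- dplyr::count(
    tibble::tibble(reason = reason[!keep]), .data$reason, name = "n"
  )
  if (nrow(rejected) > 0) {
    message(sum(rejected$n), " ", schema, " row(s) rejected: ",
            paste(rejected$reason, rejected$n, sep = "=", collapse = ", "))
  }
  out <- out[keep, , drop = FALSE]
  out$visit_date <- date_parsed[keep]
  attr(out, "rejected") <- rejected
  out
}

#' Assemble events into visits
#'
#' All prescriptions and diagnoses sharing the composite key
#' (institution, patient, calendar date) are treated as one outpatient visit.
#' Matching is exact string equality on the identifier tokens — the key is the
#' linkage identifier of the source records, so no fuzzy matching is applied.
#' Patient, physician and institution attributes are joined from the lookup
#' tables; a lookup miss leaves the attribute `NA` (an explicit missing level)
#' and is counted. Physician attributes attach at the prescription level and
#' are lifted to the visit by majority physician, ties broken by first
#' occurrence in file order.
#'
#' @param prescriptions Validated prescription events (see [validate_events()]).
#' @param diagnoses Validated diagnosis events.
#' @param patients Optional lookup: `patient_id, age_group, gender, payment`.
#' @param physicians Optional lookup: `physician_id, age_group, gender,
#'   education`.
#' @param institutions Optional lookup: `institution_id, area_type, level`.
#' @return A `visit_set`: a list with tibbles `visits` (one row per key,
#'   carrying attributes and event counts), `prescriptions` and `diagnoses`
#'   (the input events with a `visit_id` column).
#' @examples
#' rx <- tibble::tibble(
#'   institution_id = "I1", patient_id = "P1",
#'   visit_date = as.Date("2019-03-04"),
#'   drug_code = c("J01CA04", "J01MA02"),
#'   drug_name = c("amoxicillin", "ciprofloxacin"),
#'   route = "oral", physician_id = "D1"
#' )
#' dx <- tibble::tibble(
#'   institution_id = "I1", patient_id = "P1",
#'   visit_date = as.Date("2019-03-04"),
#'   code_system = "ICD10", diagnosis_code = "N39.0"
#' )
#' assemble_visits(rx, dx)
#' @export
assemble_visits <- function(prescriptions, diagnoses,
                            patients = NULL, physicians = NULL,
                            institutions = NULL) {
  key_cols <- c("institution_id", "patient_id", "visit_date")
  prescriptions <- tibble::as_tibble(prescriptions)
  diagnoses <- tibble::as_tibble(diagnoses)
  add_id <- function(df) {
    df$visit_id <- paste(df$institution_id, df$patient_id,
                         format(df$visit_date, "%Y-%m-%d"), sep = "|")
    df
  }
  prescriptions <- add_id(prescriptions)
  diagnoses <- add_id(diagnoses)

  keys <- dplyr::distinct(
    dplyr::bind_rows(prescriptions[c("visit_id", key_cols)],
                     diagnoses[c("visit_id", key_cols)]),
    .data$visit_id, .keep_all = TRUE
  )
  visits <- dplyr::arrange(keys, .data$institution_id, .data$patient_id,
                           .data$visit_date)
  visits$n_prescriptions <-
    as.integer(table(factor(prescriptions$visit_id,
                            levels = visits$visit_id)))
  visits$n_diagnoses <-
    as.integer(table(factor(diagnoses$visit_id, levels = visits$visit_id)))

  # majority physician per visit, ties -> earliest row in file order
  if (nrow(prescriptions) > 0) {
    ph <- prescriptions
    ph$.row <- seq_len(nrow(ph))
    ph <- dplyr::summarise(
      dplyr::group_by(ph, .data$visit_id, .data$physician_id),
      n = dplyr::n(), first_row = min(.data$.row), .groups = "drop"
    )
    ph <- dplyr::arrange(ph, .data$visit_id, dplyr::desc(.data$n),
                         .data$first_row)
    ph <- dplyr::distinct(ph, .data$visit_id, .keep_all = TRUE)
    visits <- dplyr::left_join(visits, ph[c("visit_id", "physician_id")],
                               by = "visit_id")
  } else {
    visits$physician_id <- NA_character_
  }

  misses <- integer(0)
  join_attrs <- function(visits, lookup, by, prefix, cols) {
    if (is.null(lookup)) {
      for (cl in cols) visits[[paste0(prefix, cl)]] <- NA_character_
      return(visits)
    }
    lookup <- tibble::as_tibble(lookup)
    stopifnot(all(c(by, cols) %in% names(lookup)))
    lk <- lookup[c(by, cols)]
    names(lk) <- c(by, paste0(prefix, cols))
    out <- dplyr::left_join(visits, dplyr::distinct(lk, .data[[by]],
                                                    .keep_all = TRUE),
                            by = by)
    n_miss <- sum(!is.na(out[[by]]) &
                    is.na(out[[paste0(prefix, cols[1])]]))
    if (n_miss > 0) {
      message(n_miss, " visit(s) with no ", prefix,
              "attribute match; kept with missing attributes")
    }
    out
  }
  visits <- join_attrs(visits, patients, "patient_id", "patient_",
                       c("age_group", "gender", "payment"))
  visits <- join_attrs(visits, physicians, "physician_id", "physician_",
                       c("age_group", "gender", "education"))
  visits <- join_attrs(visits, institutions, "institution_id", "institution_",
                       c("area_type", "level"))

  structure(
    list(visits = visits, prescriptions = prescriptions,
         diagnoses = diagnoses),
    class = "visit_set"
  )
}

#' @export
print.visit_set <- function(x, ...) {
  cat("<visit_set> ", nrow(x$visits), " visits, ",
      nrow(x$prescriptions), " prescription events, ",
      nrow(x$diagnoses), " diagnosis events, ",
      dplyr::n_distinct(x$visits$institution_id), " institutions\n", sep = "")
  invisible(x)
}

#' Apply the minimum-months institution inclusion rule
#'
#' An institution is kept if and only if it has at least `min_months` distinct
#' calendar months containing one or more visits; institutions uploading fewer
#' months of data are excluded with a report. The boundary is inclusive:
#' exactly `min_months` months keeps the institution.
#'
#' @param vs A `visit_set` from [assemble_visits()].
#' @param min_months Minimum number of distinct calendar months (default 10).
#' @return A list: `kept` (a filtered `visit_set`) and `excluded` (tibble of
#'   `institution_id, n_months, n_visits` for every excluded institution).
#' @export
filter_institutions <- function(vs, min_months = 10) {
  stopifnot(inherits(vs, "visit_set"), min_months >= 1)
  cover <- dplyr::summarise(
    dplyr::group_by(vs$visits, .data$institution_id),
    n_months = dplyr::n_distinct(format(.data$visit_date, "%Y-%m")),
    n_visits = dplyr::n(), .groups = "drop"
  )
  excluded <- dplyr::filter(cover, .data$n_months < min_months)
  keep_ids <- setdiff(cover$institution_id, excluded$institution_id)
  kept <- structure(
    list(
      visits = dplyr::filter(vs$visits, .data$institution_id %in% keep_ids),
      prescriptions = dplyr::filter(vs$prescriptions,
                                    .data$institution_id %in% keep_ids),
      diagnoses = dplyr::filter(vs$diagnoses,
                                .data$institution_id %in% keep_ids)
    ),
    class = "visit_set"
  )
  list(kept = kept, excluded = excluded)
}
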