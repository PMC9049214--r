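# Builders and independent oracles shared across the test files. Oracles are
# deliberately written as plain loops, independent of the vectorized package
# code paths they check.

make_rx <- function(inst = "I1", pat = "P1", date = "2019-03-04",
                    code = "J01CA04", name = "amoxicillin",
                    route = "oral", doc = "D1") {
  tibble::tibble(
    institution_id = inst, patient_id = pat, visit_date = as.Date(date),
    drug_code = code, drug_name = name, route = route, physician_id = doc
  )
}

make_dx <- function(inst = "I1", pat = "P1", date = "2019-03-04",
                    system = "ICD10", code = "J18.9") {
  tibble::tibble(
    institution_id = inst, patient_id = pat, visit_date = as.Date(date),
    code_system = system, diagnosis_code = code
  )
}

small_sim_config <- function(seed = 7, mean_monthly_visits = 20, ...) {
  simulation_config(
    seed = seed,
    n_institutions = c(urban_CHSC_TH = 3, urban_CHSS_VC = 4,
                       rural_CHSC_TH = 3, rural_CHSS_VC = 4),
    mean_monthly_visits = mean_monthly_visits, ...
  )
}

# brute-force longest-prefix classifier: scan every mapping row and keep
# the longest prefix that matches (no join/truncation tricks)
oracle_classify_one <- function(code_system, code, tier_map) {
  norm <- toupper(gsub("[^A-Za-z0-9]", "", code))
  px <- toupper(gsub("[^A-Za-z0-9]", "", tier_map$code_prefix))
  ok <- tier_map$code_system == code_system & startsWith(norm, px)
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[which.max(nchar(px[cand]))]
  list(len = nchar(px[best]), tier = tier_map$tier[best],
       category = tier_map$category[best],
       index = tier_map$category_index[best])
}

# brute-force appropriateness rule: best tier wins, ICD10 beats TCM within
# the best tier, then lowest category index
oracle_visit_label <- function(dx_rows, tier_map) {
  matches <- list()
  for (i in seq_len(nrow(dx_rows))) {
    m <- oracle_classify_one(dx_rows$code_system[i],
                             dx_rows$diagnosis_code[i], tier_map)
    if (!is.null(m)) {
      m$is_tcm <- dx_rows$code_system[i] == "TCM"
      matches[[length(matches) + 1]] <- m
    }
  }
  if (length(matches) == 0) {
    return(list(label = "not_linked", category = NA_character_))
  }
  tiers <- vapply(matches, `[[`, integer(1), "tier")
  best_tier <- min(tiers)
  cand <- matches[tiers == best_tier]
  tcm <- vapply(cand, `[[`, logical(1), "is_tcm")
  if (any(!tcm)) cand <- cand[!tcm]
  idx <- vapply(cand, `[[`, integer(1), "index")
  chosen <- cand[[which.min(idx)]]
  label <- c("appropriate", "potentially_appropriate",
             "inappropriate")[best_tier]
  list(label = label, category = chosen$category)
}

# random visit fixtures drawing real and junk codes against the shipped map
random_visit_diagnoses <- function(n_visits, tier_map, seed) {
  set.seed(seed)
  icd <- tier_map[tier_map$code_system == "ICD10", ]
  tcm <- tier_map[tier_map$code_system == "TCM" &
                    tier_map$code_prefix != "B", ]
  out <- vector("list", n_visits)
  for (v in seq_len(n_visits)) {
    k <- sample(0:3, 1)
    if (k == 0) {
      out[[v]] <- tibble::tibble(code_system = character(),
                                 diagnosis_code = character())
      next
    }
    sys <- sample(c("ICD10", "TCM", "junk"), k, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
    code <- character(k)
    for (j in seq_len(k)) {
      if (sys[j] == "ICD10") {
        code[j] <- paste0(sample(icd$code_prefix, 1), ".",
                          sample(0:9, 1))
      } else if (sys[j] == "TCM") {
        code[j] <- paste0(sample(tcm$code_prefix, 1),
                          sprintf("%02d", sample(0:99, 1)))
        sys[j] <- "TCM"
      } else {
        code[j] <- paste0("Z", sample(10:99, 1), ".", sample(0:9, 1))
        sys[j] <- "ICD10"   # valid system, unmatched prefix
      }
    }
    out[[v]] <- tibble::tibble(code_system = sys, diagnosis_code = code)
  }
  out
}

# visit_set carrying one antibiotic per visit and the given diagnosis sets
visit_set_from_diagnoses <- function(dx_sets) {
  n <- length(dx_sets)
  dates <- as.Date("2019-01-01") + (seq_len(n) %% 600)
  rx <- make_rx(inst = "I1", pat = sprintf("P%05d", seq_len(n)),
                date = dates)
  dx <- dplyr::bind_rows(lapply(seq_len(n), function(v) {
    d <- dx_sets[[v]]
    if (nrow(d) == 0) return(NULL)
    tibble::tibble(institution_id = "I1",
                   patient_id = sprintf("P%05d", v),
                   visit_date = dates[v],
                   code_system = d$code_system,
                   diagnosis_code = d$diagnosis_code)
  }))
  if (is.null(dx) || nrow(dx) == 0) {
    dx <- make_dx()[0, ]
  }
  assemble_visits(rx, dx)
}
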