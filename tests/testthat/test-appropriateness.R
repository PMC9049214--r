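test_that("tier map fixture partitions 30 ICD categories into three tiers", {
  map <- load_tier_map()
  icd <- dplyr::distinct(map[map$code_system == "ICD10", ],
                         category, tier)
  expect_equal(nrow(icd), 30)
  expect_setequal(unique(icd$tier), 1:3)
  # accepted example row: pneumonia is a tier-1 condition under J18
  expect_equal(map$tier[map$code_prefix == "J18"], 1L)
  # every ICD category carries exactly one tier
  expect_equal(anyDuplicated(icd$category), 0L)
})

test_that("tier map validation rejects duplicates and bad tiers", {
  map <- load_tier_map()[, 1:4]
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_rows(map, map[3, ]), f)
  expect_error(load_tier_map(f), map$code_prefix[3])
  bad <- map
  bad$tier[1] <- 4L
  readr::write_csv(bad, f)
  expect_error(load_tier_map(f), "tier")
})

test_that("diagnosis codes match by longest prefix, punctuation stripped", {
  map <- load_tier_map()
  out <- classify_diagnosis(make_dx(code = "J18.9"), map)
  expect_equal(out$tier, 1L)
  expect_equal(out$category, "pneumonia")
  # longer prefix beats shorter when both match
  two <- tibble::tibble(code_system = "ICD10",
                        code_prefix = c("J1", "J18"),
                        category = c("short", "long"), tier = c(3L, 1L))
  two$category_index <- 1:2
  dx <- make_dx(code = c("J18.9", "J15.0", "J2"))
  got <- classify_diagnosis(dx, structure(two, class = class(map)))
  expect_equal(got$category, c("long", "short", NA))
  # agreement with the exhaustive prefix-scan oracle on random codes
  set.seed(3)
  codes <- paste0(sample(c("J", "N", "K", "R", "Z"), 50, TRUE),
                  sample(0:99, 50, TRUE), ".", sample(0:9, 50, TRUE))
  dx <- make_dx(code = codes)
  got <- suppressMessages(classify_diagnosis(dx, map))
  for (i in seq_len(50)) {
    o <- oracle_classify_one("ICD10", codes[i], map)
    if (is.null(o)) {
      expect_true(is.na(got$tier[i]))
    } else {
      expect_equal(got$tier[i], o$tier)
      expect_equal(got$category[i], o$category)
    }
  }
})

test_that("TCM sensitivity modes override the expert tiers", {
  dx <- make_dx(system = "TCM", code = c("BNL01", "BNG55", "XX99"))
  map <- load_tier_map()
  expert <- classify_diagnosis(dx, map, tcm_mode = "expert")
  expect_equal(expert$tier[1:2], c(1L, 3L))
  t2 <- classify_diagnosis(dx, map, tcm_mode = "all_tier2")
  expect_equal(t2$tier, rep(2L, 3))
  expect_equal(unique(t2$category), "tcm")
  t3 <- classify_diagnosis(dx, map, tcm_mode = "all_tier3")
  expect_equal(t3$tier, rep(3L, 3))
})

test_that("visit appropriateness follows the tier/system priority rules", {
  # tier-1 pneumonia beats tier-3 viral URI -> appropriate
  vs <- assemble_visits(make_rx(),
                        make_dx(code = c("J18.9", "J06.9")))
  rec <- assign_visit_appropriateness(vs)
  expect_equal(as.character(rec$appropriateness), "appropriate")
  expect_equal(rec$assigned_category, "pneumonia")
  # allopathic priority within the same tier: ICD-10 sinusitis over TCM
  dx <- dplyr::bind_rows(make_dx(system = "TCM", code = "BNF10"),
                         make_dx(code = "J01.0"))
  rec <- assign_visit_appropriateness(assemble_visits(make_rx(), dx))
  expect_equal(as.character(rec$appropriateness), "potentially_appropriate")
  expect_equal(rec$assigned_category, "acute_sinusitis")
  # no diagnosis rows -> not linked
  rec <- assign_visit_appropriateness(assemble_visits(make_rx(),
                                                      make_dx()[0, ]))
  expect_equal(as.character(rec$appropriateness), "not_linked")
  # adding a tier-3 diagnosis never changes an appropriate assignment
  vs3 <- assemble_visits(make_rx(),
                         make_dx(code = c("J18.9", "J06.9", "I10.0")))
  expect_equal(as.character(
    assign_visit_appropriateness(vs3)$appropriateness), "appropriate")
})

test_that("appropriateness agrees with the brute-force oracle on random visits", {
  map <- load_tier_map()
  dx_sets <- random_visit_diagnoses(400, map, seed = 17)
  vs <- visit_set_from_diagnoses(dx_sets)
  rec <- suppressMessages(assign_visit_appropriateness(vs))
  rec <- rec[order(rec$patient_id), ]
  for (v in seq_along(dx_sets)) {
    o <- oracle_visit_label(dx_sets[[v]], map)
    expect_equal(as.character(rec$appropriateness[v]), o$label)
    if (o$label != "not_linked") {
      expect_equal(rec$assigned_category[v], o$category)
    }
  }
})

test_that("four appropriateness counts sum to the antibiotic visits per stratum", {
  sim <- simulate_dataset(small_sim_config(seed = 9))
  vs <- assemble_visits(sim$prescriptions, sim$diagnoses, sim$patients,
                        sim$physicians, sim$institutions)
  rec <- assign_visit_appropriateness(vs)
  tab <- tabulate_appropriateness(rec, strata = "institution_area_type")
  sums <- tapply(tab$n, tab$institution_area_type, sum)
  expect_equal(sum(tab$n), nrow(rec))
  for (s in names(sums)) {
    expect_equal(unname(sums[s]),
                 sum(rec$institution_area_type == s))
  }
  # stratum sums equal overall totals
  overall <- tabulate_appropriateness(rec)
  by_cat <- tapply(tab$n, tab$appropriateness, sum)
  expect_equal(as.vector(by_cat[as.character(overall$appropriateness)]),
               overall$n)
})

test_that("TCM sensitivity modes move labels monotonically", {
  sim <- simulate_dataset(small_sim_config(seed = 13, tcm_fraction = 0.4))
  vs <- assemble_visits(sim$prescriptions, sim$diagnoses)
  rank <- function(x) match(as.character(x),
                            c("appropriate", "potentially_appropriate",
                              "inappropriate", "not_linked"))
  expert <- assign_visit_appropriateness(vs, tcm_mode = "expert")
  t3 <- assign_visit_appropriateness(vs, tcm_mode = "all_tier3")
  t2 <- assign_visit_appropriateness(vs, tcm_mode = "all_tier2")
  ord <- order(expert$visit_id)
  expert <- expert[ord, ]; t3 <- t3[order(t3$visit_id), ]
  t2 <- t2[order(t2$visit_id), ]
  # forcing TCM to tier 3 never moves any visit toward a better label
  expect_true(all(rank(t3$appropriateness) >= rank(expert$appropriateness)))
  # forcing TCM to tier 2 never moves a visit into inappropriate
  was_not_inappropriate <- expert$appropriateness != "inappropriate"
  expect_true(all(t2$appropriateness[was_not_inappropriate] !=
                    "inappropriate"))
})
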