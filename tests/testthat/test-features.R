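test_that("TTI is a whole-day difference with boundary exactness", {
  expect_equal(compute_tti(as.Date("2005-01-01"), as.Date("2005-01-01")), 0L)
  expect_equal(compute_tti(as.Date("2005-01-01"), as.Date("2005-01-31")), 30L)
  expect_equal(compute_tti(as.Date("2005-01-01"), as.Date("2006-01-01")), 365L)
  expect_error(compute_tti(as.Date("2005-01-02"), as.Date("2005-01-01")),
               "precedes")
})

test_that("delay flag is exact at the 30/31-day boundary", {
  expect_identical(delay_flag(c(0L, 29L, 30L, 31L, 365L)),
                   c(0L, 0L, 0L, 1L, 1L))
  expect_error(delay_flag(366L), "\\[0, 365\\]")
  expect_error(delay_flag(-1L), "\\[0, 365\\]")
})

test_that("comorbidity counts distinct conditions, not codes", {
  idx <- tibble::tibble(patient_id = c("P1", "P2", "P3", "P4"),
                        dx_date = as.Date("2006-06-01"))
  enc <- dplyr::bind_rows(
    # P1: two codes, same condition (myocardial infarction)
    make_claim("P1", "D", "2006-01-01", "diagnosis", code = "410.71"),
    make_claim("P1", "D", "2006-02-01", "diagnosis", code = "412"),
    # P2: two distinct conditions
    make_claim("P2", "D", "2006-01-01", "diagnosis", code = "428.0"),
    make_claim("P2", "D", "2006-02-01", "diagnosis", code = "250.00"),
    # P3: unmapped code only
    make_claim("P3", "D", "2006-01-01", "diagnosis", code = "999.9"),
    # P4: mapped condition but AFTER diagnosis -> ignored
    make_claim("P4", "D", "2006-07-01", "diagnosis", code = "428.0")
  )
  got <- charlson_category(enc, idx)
  expect_equal(as.character(got$cmi), c("one", "two_plus", "none", "none"))
  expect_equal(got$n_conditions, c(1L, 2L, 0L, 0L))
})

test_that("the cancer diagnosis code never scores as a comorbidity", {
  idx <- tibble::tibble(patient_id = "P1", dx_date = as.Date("2006-06-01"))
  enc <- make_claim("P1", "D", "2006-01-01", "diagnosis", code = "153.9")
  expect_equal(charlson_category(enc, idx)$n_conditions, 0L)
})

test_that("comorbidity lookback window can be restricted", {
  idx <- tibble::tibble(patient_id = "P1", dx_date = as.Date("2006-06-01"))
  enc <- make_claim("P1", "D", "2004-01-01", "diagnosis", code = "428.0")
  expect_equal(charlson_category(enc, idx)$n_conditions, 1L)
  expect_equal(charlson_category(enc, idx, lookback_days = 365)$n_conditions,
               0L)
})

test_that("dyad gender pairs are ordered diagnosing-first", {
  got <- dyad_gender_category(c("M", "M", "F", "F", NA),
                              c("M", "F", "M", "F", "M"))
  expect_equal(as.character(got), c("MM", "MF", "FM", "FF", NA))
  expect_equal(levels(got)[1], "MM")  # reference
  expect_error(dyad_gender_category("X", "M"), "'M' or 'F'")
})

test_that("colocation flag is 0 for shared facilities, NA when undefined", {
  expect_identical(colocation_flag(c("F1", "F1", NA), c("F1", "F2", "F1")),
                   c(0L, 1L, NA))
})

test_that("age bands split at completed years with 85 in the 81-85 band", {
  got <- psndelay:::age_band_of(c(66, 70, 71, 80, 81, 85, 86, 95, 65))
  expect_equal(as.character(got),
               c("66-70", "66-70", "71-75", "76-80", "81-85", "81-85",
                 "85+", "85+", NA))
})

# A fully hand-checked five-patient dataset exercising the analytic build:
# dyad structure of the worked example, one boundary delay, mixed provider
# genders, one non-colocated dyad, one comorbid patient.
analytic_fixture <- function() {
  patients <- dplyr::bind_rows(
    make_patient("P1", "2006-01-10", age = 67, gender = "M", stage = 1),
    make_patient("P2", "2006-02-10", age = 72, gender = "F", stage = 2,
                 race = "Black"),
    make_patient("P3", "2006-03-10", age = 78, stage = 3),
    make_patient("P4", "2006-04-10", age = 85, stage = 4, marital = "Single"),
    make_patient("P5", "2006-05-10", age = 90, stage = 2, poverty = 4)
  )
  providers <- tibble::tibble(
    provider_id = c("A", "B", "C", "1", "2"),
    gender = c("M", "F", "M", "M", "F"),
    specialty = c("Internal Medicine", "Gastroenterology", "General Surgery",
                  "General Surgery", "Medical Oncology"),
    facility_id = c("FA", "FB", "FX", "FA", "FB")
  )
  encounters <- dplyr::bind_rows(
    standard_claims("P1", "A", "1", "2006-01-10", tti = 30L),   # boundary: no delay
    standard_claims("P2", "A", "1", "2006-02-10", tti = 31L),   # boundary: delay
    standard_claims("P3", "B", "1", "2006-03-10", tti = 10L),
    standard_claims("P4", "B", "2", "2006-04-10", tti = 45L,
                    treatment_type = "chemo"),
    standard_claims("P5", "C", "2", "2006-05-10", tti = 100L,
                    treatment_type = "radio"),
    make_claim("P4", "B", "2006-01-05", "diagnosis", code = "428.0"),
    make_claim("P4", "B", "2006-02-05", "diagnosis", code = "496")
  )
  list(patients = patients, providers = providers, encounters = encounters)
}

test_that("the analytic table matches hand-computed codings row by row", {
  fx <- analytic_fixture()
  res <- apply_eligibility(fx$patients, fx$encounters, fx$providers)
  expect_equal(nrow(res$cohort), 5)
  dyads <- build_dyads(res$cohort, threshold = 2)
  tbl <- build_analytic_table(res$cohort, dyads, fx$providers, fx$encounters,
                              psn_threshold = 2)
  tbl <- tbl[match(sprintf("P%d", 1:5), tbl$patient_id), ]

  expect_equal(tbl$delay, c(0L, 1L, 0L, 1L, 1L))
  expect_equal(as.character(tbl$psn),
               c("psn", "psn", "no_psn", "no_psn", "no_psn"))
  expect_equal(as.character(tbl$age_band),
               c("66-70", "71-75", "76-80", "81-85", "85+"))
  expect_equal(as.character(tbl$stage_group), c("1", "2", "3_4", "3_4", "2"))
  expect_equal(as.character(tbl$cmi),
               c("none", "none", "none", "two_plus", "none"))
  # dyad gender: dx gender first (A=M, B=F, C=M; 1=M, 2=F)
  expect_equal(as.character(tbl$dyad_gender), c("MM", "MM", "FM", "FF", "MF"))
  # facilities: A/1 share FA, B/1 differ, B/2 share FB, C/2 differ
  expect_equal(as.character(tbl$colocation),
               c("colocated", "colocated", "not_colocated", "colocated",
                 "not_colocated"))
  expect_equal(as.character(tbl$dx_specialty),
               c("primary_care", "primary_care", "non_oncology",
                 "non_oncology", "non_oncology"))
  expect_equal(as.character(tbl$tx_specialty),
               c("non_oncology", "non_oncology", "non_oncology", "oncology",
                 "oncology"))
  expect_true(all(tbl$is_complete))
  expect_equal(nrow(attr(tbl, "rejects")), 0)
})

test_that("all-male providers give all-MM dyads", {
  fx <- analytic_fixture()
  fx$providers$gender <- "M"
  res <- apply_eligibility(fx$patients, fx$encounters, fx$providers)
  dyads <- build_dyads(res$cohort)
  tbl <- build_analytic_table(res$cohort, dyads, fx$providers, fx$encounters)
  expect_true(all(tbl$dyad_gender == "MM"))
})

test_that("collapsing stages 3 and 4 never changes the row count", {
  ds <- generate_cohort(small_config(n = 400, seed = 19))
  res <- apply_eligibility(ds$patients, ds$encounters, ds$providers)
  other <- setdiff(eligibility_rule_names(), "demographic_complete")
  pass <- Reduce(`&`, res$flags[other], rep(TRUE, nrow(res$flags)))
  pre <- res$linked[pass, ]
  dyads <- build_dyads(pre)
  tbl <- build_analytic_table(pre, dyads, ds$providers, ds$encounters)
  expect_equal(nrow(tbl), nrow(pre))
  expect_true(all(levels(tbl$stage_group) == c("1", "2", "3_4")))
  # collapsed groups partition the raw stages
  raw <- ds$patients$stage[match(tbl$patient_id, ds$patients$patient_id)]
  obs <- as.character(tbl$stage_group)
  expect_identical(obs[!is.na(raw)],
                   ifelse(raw[!is.na(raw)] >= 3, "3_4",
                          as.character(raw[!is.na(raw)])))
})

test_that("analytic categorical marginals agree with the generator's truth", {
  ds <- generate_cohort(small_config(n = 2500, seed = 23,
                                     missingness_rates = numeric(0)))
  res <- run_delay_pipeline(ds)
  tbl <- res$analytic
  tr <- ds$truth[match(tbl$patient_id, ds$truth$patient_id), ]
  for (v in c("stage_group", "cmi", "gender", "age_band", "race", "marital",
              "poverty", "dyad_gender", "colocation", "dx_specialty",
              "tx_specialty", "psn")) {
    expect_equal(as.character(tbl[[v]]), as.character(tr[[v]]),
                 label = sprintf("pipeline-recovered %s", v))
  }
  expect_identical(tbl$delay, tr$delay)
  expect_identical(tbl$tti_days, tr$tti_days)
})
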