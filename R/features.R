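#' Deyo-adapted Charlson condition map
#'
#' Named list mapping each Charlson-Deyo comorbidity (cancer conditions
#' excluded, since the index disease is a malignancy) to the ICD-9 code
#' prefixes that identify it in diagnosis claims.  Ships as an editable JSON
#' resource; supply your own file to change code lists.  Matching is
#' dot-insensitive prefix matching ("410.71" matches prefix "410").
#'
#' @param path Optional path to a JSON file with the same structure.
#' @return Named list of character prefix vectors.
#' @export
default_condition_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "deyo_condition_map.json",
                                package = "psndelay")
  if (!nzchar(path) || !file.exists(path)) {
    abort("Condition map file not found.")
  }
  map <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(map) == 0 || is.null(names(map)) || any(names(map) == "") ||
      !all(vapply(map, is.character, logical(1)))) {
    abort("Condition map must be a named list of character code-prefix vectors.")
  }
  map
}

strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

#' Charlson-Deyo comorbidity category from diagnosis claims
#'
#' Counts the *distinct* mapped conditions present in each patient's
#' diagnosis-class claims on or before the diagnosis date (several codes for
#' the same condition count once), and bins the count as `none` / `one` /
#' `two_plus`.
#'
#' @param encounters Claims tibble (`patient_id`, `service_date`, `code`,
#'   `code_class`).
#' @param index_dates Tibble with `patient_id` and `dx_date`; one row per
#'   patient to score (patients without qualifying claims score `none`).
#' @param condition_map As [default_condition_map()].
#' @param lookback_days Claims earlier than `dx_date - lookback_days` are
#'   ignored (default `Inf`: all claims up to diagnosis).
#' @return Tibble: `patient_id`, `n_conditions`, `cmi` (factor
#'   none/one/two_plus).
#' @export
charlson_category <- function(encounters, index_dates,
                              condition_map = default_condition_map(),
                              lookback_days = Inf) {
  if (!all(vapply(condition_map, is.character, logical(1))) ||
      is.null(names(condition_map))) {
    abort("`condition_map` must be a named list of character prefix vectors.")
  }
  claims <- dplyr::inner_join(
    dplyr::filter(encounters, .data$code_class == "diagnosis"),
    dplyr::select(index_dates, "patient_id", "dx_date"),
    by = "patient_id"
  )
  claims <- dplyr::filter(
    claims,
    .data$service_date <= .data$dx_date,
    is.infinite(lookback_days) |
      .data$service_date >= .data$dx_date - lookback_days
  )

  code_norm <- strip_dots(claims$code)
  condition <- rep(NA_character_, nrow(claims))
  for (cond in names(condition_map)) {
    for (pref in strip_dots(condition_map[[cond]])) {
      condition[is.na(condition) & startsWith(code_norm, pref)] <- cond
    }
  }
  hits <- dplyr::distinct(
    tibble::tibble(patient_id = claims$patient_id, condition = condition)
  )
  hits <- dplyr::count(dplyr::filter(hits, !is.na(.data$condition)),
                       .data$patient_id, name = "n_conditions")

  out <- dplyr::left_join(dplyr::select(index_dates, "patient_id"), hits,
                          by = "patient_id")
  out$n_conditions <- dplyr::coalesce(out$n_conditions, 0L)
  out$cmi <- factor(
    dplyr::case_when(out$n_conditions == 0 ~ "none",
                     out$n_conditions == 1 ~ "one",
                     TRUE ~ "two_plus"),
    levels = CMI_LEVELS
  )
  out
}

#' Time to treatment initiation in whole days
#'
#' @param dx_date,first_treatment_date Date vectors (same day gives 0).
#' @return Integer days.
#' @export
compute_tti <- function(dx_date, first_treatment_date) {
  tti <- days_between(dx_date, first_treatment_date)
  if (any(tti < 0, na.rm = TRUE)) {
    abort("Treatment date precedes diagnosis date for some patients.")
  }
  tti
}

#' 30-day care-delay indicator
#'
#' Codes a treatment delay as 1 when TTI exceeds 30 days and 0 when treatment
#' started within 30 days (inclusive).
#'
#' @param tti_days Integer days in `[0, 365]`.
#' @return Integer 0/1 vector (`NA` preserved).
#' @export
delay_flag <- function(tti_days) {
  bad <- !is.na(tti_days) & (tti_days < 0 | tti_days > 365)
  if (any(bad)) {
    abort("`tti_days` outside [0, 365]; eligibility should have excluded these.")
  }
  as.integer(tti_days > 30)
}

#' Dyad gender category
#'
#' Ordered pair of provider genders, diagnosing provider first: `"MF"` means
#' male diagnosing, female treating.  Male-male is the modelling reference.
#'
#' @param dx_gender,tx_gender Character vectors of `"M"`/`"F"`.
#' @return Factor with levels MM, FF, FM, MF; `NA` when either gender is
#'   missing.
#' @export
dyad_gender_category <- function(dx_gender, tx_gender) {
  ok <- function(g) is.na(g) | g %in% c("M", "F")
  if (!all(ok(dx_gender)) || !all(ok(tx_gender))) {
    abort("Provider genders must be 'M' or 'F' (or NA).")
  }
  out <- ifelse(is.na(dx_gender) | is.na(tx_gender), NA_character_,
                paste0(dx_gender, tx_gender))
  factor(out, levels = DYAD_GENDER_LEVELS)
}

#' Dyad colocation indicator
#'
#' 0 when both providers share the same facility code (reference), 1 when
#' they do not; `NA` when either facility id is missing.
#'
#' @param dx_facility,tx_facility Character facility ids.
#' @return Integer 0/1 vector with `NA` for undefined comparisons.
#' @export
colocation_flag <- function(dx_facility, tx_facility) {
  ifelse(is.na(dx_facility) | is.na(tx_facility), NA_integer_,
         as.integer(dx_facility != tx_facility))
}

age_band_of <- function(age) {
  factor(
    dplyr::case_when(
      age >= 66 & age <= 70 ~ "66-70",
      age >= 71 & age <= 75 ~ "71-75",
      age >= 76 & age <= 80 ~ "76-80",
      age >= 81 & age <= 85 ~ "81-85",
      age >= 86 ~ "85+",
      TRUE ~ NA_character_
    ),
    levels = AGE_BANDS
  )
}

#' Build the analytic table
#'
#' Derives one row per cohort patient with the delay outcome and every model
#' covariate: 30-day delay flag and TTI, PSN membership (via the dyad table),
#' age band, collapsed stage group (3 and 4 merged), Charlson-Deyo category
#' from pre-diagnosis claims, and the dyad homophily variables (gender pair,
#' colocation, specialty categories) from the provider table.  Categorical
#' variables are coded with the modelling reference levels (PSN, male, White,
#' stage 1, no comorbidity, male-male dyad, colocated, non-oncology diagnosing
#' / oncology treating specialty).
#'
#' Rows whose provider-derived covariates cannot be resolved are kept but
#' listed in the `"rejects"` attribute; rows with missing demographics carry
#' `is_complete = FALSE` (they enter the completeness-propensity stage, not
#' the final model).
#'
#' @param cohort Eligible cohort with linked providers: `patient_id`,
#'   `dx_date`, `age_at_dx`, demographics, `dx_provider_id`,
#'   `tx_provider_id`, `tti_days`.
#' @param dyads Dyad table from [build_dyads()].
#' @param providers Provider tibble (`provider_id`, `gender`, `specialty`,
#'   `facility_id`).
#' @param encounters Claims tibble (for the comorbidity score).
#' @param psn_threshold Shared-count cut for PSN membership.
#' @param condition_map,specialty_map Code resources; see
#'   [default_condition_map()] and [default_specialty_map()].
#' @return Tibble of analytic rows (`ipw_weight` initialised to `NA`), with a
#'   `"rejects"` attribute.
#' @export
build_analytic_table <- function(cohort, dyads, providers, encounters,
                                 psn_threshold = 3L,
                                 condition_map = default_condition_map(),
                                 specialty_map = default_specialty_map()) {
  needed <- c("patient_id", "dx_date", "age_at_dx", "gender",
              "race_ethnicity", "marital", "poverty_stratum", "stage",
              "dx_provider_id", "tx_provider_id", "tti_days")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("`cohort` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }

  cohort <- classify_psn(cohort, dyads, threshold = psn_threshold)

  prov <- function(prefix) {
    out <- dplyr::select(providers, "provider_id", "gender", "specialty",
                         "facility_id")
    out$specialty_category <- unname(specialty_map[out$specialty])
    names(out) <- c(paste0(prefix, "_provider_id"), paste0(prefix, "_pgender"),
                    paste0(prefix, "_raw_specialty"),
                    paste0(prefix, "_facility"), paste0(prefix, "_spec_cat"))
    out
  }
  tbl <- dplyr::left_join(cohort, prov("dx"), by = "dx_provider_id")
  tbl <- dplyr::left_join(tbl, prov("tx"), by = "tx_provider_id")

  cmi <- charlson_category(encounters,
                           dplyr::select(tbl, "patient_id", "dx_date"),
                           condition_map = condition_map)
  tbl <- dplyr::left_join(tbl, dplyr::select(cmi, "patient_id", "cmi"),
                          by = "patient_id")

  out <- tibble::tibble(
    patient_id = tbl$patient_id,
    delay = delay_flag(tbl$tti_days),
    tti_days = tbl$tti_days,
    psn = tbl$psn,
    shared_count = tbl$shared_count,
    age_band = age_band_of(tbl$age_at_dx),
    gender = tbl$gender,
    race = tbl$race_ethnicity,
    stage_group = ifelse(tbl$stage >= 3, "3_4", as.character(tbl$stage)),
    cmi = tbl$cmi,
    marital = tbl$marital,
    poverty = as.character(tbl$poverty_stratum),
    dyad_gender = dyad_gender_category(tbl$dx_pgender, tbl$tx_pgender),
    colocation = ifelse(
      colocation_flag(tbl$dx_facility, tbl$tx_facility) == 1L,
      "not_colocated", "colocated"
    ),
    dx_specialty = tbl$dx_spec_cat,
    tx_specialty = tbl$tx_spec_cat,
    ipw_weight = NA_real_
  )
  out <- coerce_model_factors(out)

  provider_vars <- c("psn", "dyad_gender", "colocation", "dx_specialty",
                     "tx_specialty", "age_band")
  unresolved <- !stats::complete.cases(out[provider_vars])
  rejects <- tibble::tibble(
    patient_id = out$patient_id[unresolved],
    reason = "unresolved provider-derived or age covariate"
  )

  demo_vars <- c("race", "stage_group", "marital", "poverty", "gender")
  out$is_complete <- stats::complete.cases(out[c(demo_vars, provider_vars)])

  attr(out, "rejects") <- rejects
  out
}
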