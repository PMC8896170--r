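#' Attach diagnosing and treating providers to a patient table
#'
#' Resolves each patient's diagnosing provider (diagnosis claim anchored to
#' pathology confirmation, see [identify_dx_provider()]) and treating
#' provider (earliest treatment claim on or after diagnosis, see
#' [identify_tx_provider()]), and computes the whole-day time to treatment
#' initiation.  Patients with an unresolvable provider carry `NA` and are
#' flagged for exclusion downstream.
#'
#' @param patients Patient tibble with `patient_id` and `dx_date`.
#' @param encounters Claims tibble.
#' @param providers Optional provider tibble; when given, encounters that
#'   reference an unknown provider id raise a referential-integrity error.
#' @return `patients` plus `dx_provider_id`, `tx_provider_id`,
#'   `first_treatment_date`, `treatment_type`, `tti_days`.
#' @export
link_providers <- function(patients, encounters, providers = NULL) {
  if (!is.null(providers)) {
    unknown <- setdiff(unique(encounters$provider_id), providers$provider_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "Encounters reference provider id(s) absent from the provider table: %s%s.",
        paste(head(unknown, 5), collapse = ", "),
        if (length(unknown) > 5) sprintf(" (and %d more)", length(unknown) - 5) else ""
      ))
    }
  }
  out <- dplyr::left_join(patients, identify_dx_provider(encounters),
                          by = "patient_id")
  out <- dplyr::left_join(
    out,
    identify_tx_provider(encounters,
                         dplyr::select(patients, "patient_id", "dx_date")),
    by = "patient_id"
  )
  resolved <- !is.na(out$first_treatment_date)
  out$tti_days <- NA_integer_
  out$tti_days[resolved] <- compute_tti(out$dx_date[resolved],
                                        out$first_treatment_date[resolved])
  out
}

eligibility_rule_names <- function() {
  c("age_66", "first_primary", "histology_confirmed", "dx_source_clinical",
    "stage_ge_1", "demographic_complete", "provider_resolved",
    "tti_within_365")
}

#' Apply the eligibility cascade
#'
#' Evaluates every eligibility rule for every patient and reports exclusions
#' sequentially in `rule_order` (the default is the selection narrative of
#' the source cohort: clinical/tumor criteria, demographic completeness,
#' provider completeness, then treatment within 365 days).  Per-rule excluded
#' counts depend on the order; the final cohort and the total excluded do
#' not.
#'
#' Rules: age at diagnosis `>= 66` completed years; first primary tumor;
#' histologic confirmation; diagnosis source not autopsy or death
#' certificate; stage recorded as 1 or greater (in-situ/stage-0 excluded;
#' a *missing* stage fails the completeness rule instead); complete
#' demographics (stage, poverty stratum, race/ethnicity, marital status,
#' gender); both providers resolvable and distinct (a provider cannot
#' self-share a patient); and TTI within 365 days.
#'
#' @param patients Patient tibble (schema of `patients.csv`).
#' @param encounters Claims tibble.
#' @param providers Optional provider tibble for referential checks.
#' @param rule_order Character permutation (or subset) of the rule names.
#' @return Object of class `eligibility_result`: `cohort` (eligible patients
#'   with linked providers, `age_at_dx` and `tti_days`), `report` (tibble
#'   `rule`, `n_excluded`, `n_remaining`), `flags` (per-patient rule
#'   outcomes), and `linked` (all patients with linked providers).
#' @export
apply_eligibility <- function(patients, encounters, providers = NULL,
                              rule_order = eligibility_rule_names()) {
  unknown <- setdiff(rule_order, eligibility_rule_names())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown eligibility rule(s): %s.",
                  paste(unknown, collapse = ", ")))
  }

  bad_dates <- which(is.na(patients$dx_date) | is.na(patients$birth_date))
  if (length(bad_dates) > 0) {
    abort(sprintf("Unparseable dates in patient row(s): %s.",
                  paste(head(bad_dates, 5), collapse = ", ")))
  }

  linked <- link_providers(patients, encounters, providers)
  linked$age_at_dx <- age_at(linked$birth_date, linked$dx_date)

  flags <- tibble::tibble(
    patient_id = linked$patient_id,
    age_66 = linked$age_at_dx >= 66,
    first_primary = linked$first_primary == 1L,
    histology_confirmed = linked$histology_confirmed == 1L,
    dx_source_clinical = !linked$dx_source %in% c("autopsy", "death_cert"),
    stage_ge_1 = is.na(linked$stage) | linked$stage >= 1L,
    demographic_complete = !is.na(linked$stage) &
      !is.na(linked$poverty_stratum) & !is.na(linked$race_ethnicity) &
      !is.na(linked$marital) & !is.na(linked$gender),
    provider_resolved = !is.na(linked$dx_provider_id) &
      !is.na(linked$tx_provider_id) &
      (is.na(linked$dx_provider_id) | is.na(linked$tx_provider_id) |
         linked$dx_provider_id != linked$tx_provider_id),
    tti_within_365 = !is.na(linked$tti_days) & linked$tti_days >= 0L &
      linked$tti_days <= 365L
  )

  remaining <- rep(TRUE, nrow(linked))
  report <- purrr::map_dfr(rule_order, function(rule) {
    fails <- remaining & !flags[[rule]]
    remaining <<- remaining & flags[[rule]]
    tibble::tibble(rule = rule, n_excluded = sum(fails),
                   n_remaining = sum(remaining))
  })

  eligible <- Reduce(`&`, flags[rule_order], rep(TRUE, nrow(linked)))
  structure(
    list(cohort = linked[eligible, , drop = FALSE],
         report = report, flags = flags, linked = linked),
    class = "eligibility_result"
  )
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat("Eligibility cascade\n")
  cat(sprintf("  %d patients in, %d eligible\n",
              nrow(x$flags), nrow(x$cohort)))
  print(x$report, n = Inf)
  invisible(x)
}
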