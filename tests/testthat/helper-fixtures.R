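# Small, fast configuration for unit tests.
small_config <- function(n = 500, seed = 1, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

# The worked five-patient example: diagnosing providers A, B, C and treating
# providers 1, 2; pairs (A,1) x2, (B,1), (B,2), (C,2).
fig1_cohort <- function() {
  tibble::tibble(
    patient_id = sprintf("P%d", 1:5),
    dx_provider_id = c("A", "A", "B", "B", "C"),
    tx_provider_id = c("1", "1", "1", "2", "2"),
    dx_date = as.Date("2006-01-01") + c(0, 30, 60, 90, 120)
  )
}

# Build one patient row in the raw patients.csv schema.
make_patient <- function(id, dx_date, birth_date = NULL, age = 70,
                         gender = "M", race = "White", marital = "Married",
                         poverty = 1L, stage = 2L, histology = 1L,
                         first_primary = 1L, dx_source = "clinical") {
  dx_date <- as.Date(dx_date)
  if (is.null(birth_date)) {
    birth_date <- dx_date - as.integer(round(age * 365.25)) - 10L
  }
  tibble::tibble(
    patient_id = id, birth_date = as.Date(birth_date), gender = gender,
    race_ethnicity = race, marital = marital,
    poverty_stratum = as.integer(poverty), stage = as.integer(stage),
    dx_date = dx_date, histology_confirmed = as.integer(histology),
    first_primary = as.integer(first_primary), dx_source = dx_source
  )
}

make_claim <- function(patient_id, provider_id, service_date, code_class,
                       code = "000", treatment_type = NA_character_) {
  tibble::tibble(
    patient_id = patient_id, provider_id = provider_id,
    service_date = as.Date(service_date), code = code,
    code_class = code_class, treatment_type = treatment_type
  )
}

# Standard claim triplet (diagnosis + pathology + treatment) for one patient.
standard_claims <- function(patient_id, dx_provider, tx_provider, dx_date,
                            tti = 10L, treatment_type = "surgery",
                            path_lag = 3L) {
  dx_date <- as.Date(dx_date)
  dplyr::bind_rows(
    make_claim(patient_id, dx_provider, dx_date, "diagnosis", "153.9"),
    make_claim(patient_id, dx_provider, dx_date + path_lag, "pathology",
               "88305"),
    make_claim(patient_id, tx_provider, dx_date + tti, "treatment", "45.73",
               treatment_type)
  )
}

# Minimal analytic-style tibble at the reference level of every model
# variable except those supplied.
reference_analytic <- function(n, ...) {
  vars <- psndelay:::delay_model_variables()
  out <- tibble::as_tibble(purrr::map(vars, ~rep(.x[1], n)))
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  psndelay:::coerce_model_factors(out)
}

# Draw an analytic covariate table directly from configured marginals
# (bypasses claims generation; used for calibration studies of the model
# stage).
sample_covariates <- function(n, config = sim_config(n_patients = 10)) {
  marg <- config$covariate_marginals
  draw <- function(m) names(m)[sample.int(length(m), n, replace = TRUE,
                                          prob = m)]
  stage_raw <- as.integer(draw(marg$stage))
  psn <- sample(c("psn", "no_psn"), n, replace = TRUE,
                prob = c(config$psn_target_prevalence,
                         1 - config$psn_target_prevalence))
  tbl <- tibble::tibble(
    psn = psn,
    stage_group = ifelse(stage_raw >= 3, "3_4", as.character(stage_raw)),
    cmi = draw(marg$cmi), gender = draw(marg$gender),
    age_band = draw(marg$age_band), race = draw(marg$race),
    marital = draw(marg$marital), poverty = draw(marg$poverty),
    dyad_gender = draw(marg$dyad_gender), colocation = draw(marg$colocation),
    dx_specialty = draw(marg$dx_specialty),
    tx_specialty = draw(marg$tx_specialty)
  )
  psndelay:::coerce_model_factors(tbl)
}
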