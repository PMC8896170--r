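#' Default raw-specialty to category map
#'
#' Maps free-text primary specialty strings (as carried by a provider
#' masterfile) to the three analysis categories `primary_care`,
#' `non_oncology` and `oncology`.
#'
#' @return Named character vector: raw specialty -> category.
#' @export
default_specialty_map <- function() {
  c(
    "Family Medicine" = "primary_care",
    "Internal Medicine" = "primary_care",
    "General Practice" = "primary_care",
    "General Surgery" = "non_oncology",
    "Colon & Rectal Surgery" = "non_oncology",
    "Gastroenterology" = "non_oncology",
    "Cardiovascular Disease" = "non_oncology",
    "Diagnostic Radiology" = "non_oncology",
    "Medical Oncology" = "oncology",
    "Radiation Oncology" = "oncology",
    "Surgical Oncology" = "oncology",
    "Hematology/Oncology" = "oncology"
  )
}

# Claim codes emitted by the generator for the index cancer pathway.
CANCER_DX_CODE <- "153.9"       # colon malignancy
PATHOLOGY_CODE <- "88305"       # surgical pathology, level IV
TREATMENT_CODES <- c(surgery = "45.73", radio = "V58.0", chemo = "V58.11")

sample_levels <- function(n, marginal) {
  names(marginal)[sample.int(length(marginal), n, replace = TRUE,
                             prob = marginal)]
}

# Ages drawn uniformly within each band; "85+" covers 86-95 (85 itself
# belongs to the 81-85 band).
AGE_BAND_RANGES <- list(
  "66-70" = 66:70, "71-75" = 71:75, "76-80" = 76:80,
  "81-85" = 81:85, "85+" = 86:95
)

# Calibrate an intercept so that mean(plogis(b0 + lp)) hits `target`.
calibrate_intercept <- function(lp, target) {
  uniroot(function(b0) mean(plogis(b0 + lp)) - target,
          interval = c(-30, 30), tol = 1e-10)$root
}

# Draw `k[i]` distinct condition indices out of `n_cond` for each row i
# (k <= 3 in practice): rank a uniform key matrix per row.
draw_distinct <- function(k, n_cond) {
  stopifnot(all(k <= n_cond))
  keys <- matrix(runif(length(k) * n_cond), nrow = length(k))
  picks <- t(apply(keys, 1, order))
  lapply(seq_along(k), function(i) picks[i, seq_len(k[i])])
}

#' Generate a synthetic claims dataset
#'
#' Simulates patients, providers and claim lines whose statistical structure
#' matches the calibration targets in a [sim_config()]: dyad shared-patient
#' counts from the calibrated zero-truncated mixture, covariates from the
#' configured marginals, a 30-day delay outcome drawn from a logistic model
#' whose coefficients are the logs of `true_effects` (intercept calibrated to
#' the overall delay target on the realized covariates), TTI drawn from the
#' calibrated day-level distribution conditional on the delay indicator, and
#' MAR missingness applied after outcome generation.
#'
#' Each patient receives one diagnosing and one treating provider (never the
#' same person) and four kinds of claim lines: the index diagnosis claim, a
#' pathology-confirmation claim shortly after, comorbidity diagnosis claims
#' before diagnosis (driving the Charlson-Deyo category), and the first
#' treatment claim at `dx_date + TTI`.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_claims`: tibbles `patients`,
#'   `providers`, `encounters`, the latent `truth` table (true dyad
#'   assignment, covariates, delay probability, delay, TTI, missingness), the
#'   calibrated `intercept`, and the `config`.
#' @examples
#' ds <- generate_cohort(sim_config(n_patients = 200, seed = 42))
#' ds
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_patients
  marg <- config$covariate_marginals

  ## -- dyads ---------------------------------------------------------------
  sizes <- integer(0)
  while (sum(sizes) < n) {
    need <- n - sum(sizes)
    sizes <- c(sizes, rsharing(max(ceiling(need / config$sharing$mean), 32L),
                               config$sharing))
  }
  cum <- cumsum(sizes)
  k <- which(cum >= n)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n)
  if (sizes[k] == 0L) sizes <- sizes[-k]
  n_dyads <- length(sizes)

  dyad_gender <- sample_levels(n_dyads, marg$dyad_gender)
  colocation <- sample_levels(n_dyads, marg$colocation)
  spec_map <- default_specialty_map()
  pick_raw_specialty <- function(categories) {
    vapply(categories, function(cat) {
      pool <- names(spec_map)[spec_map == cat]
      pool[sample.int(length(pool), 1)]
    }, character(1), USE.NAMES = FALSE)
  }
  dx_specialty <- sample_levels(n_dyads, marg$dx_specialty)
  tx_specialty <- sample_levels(n_dyads, marg$tx_specialty)

  # Dyad activity anchored inside the window, leaving a full lookback year
  # before and a full treatment year after any diagnosis date.
  first_anchor <- config$study_start + 366L
  last_anchor <- config$study_end - (365L + 364L)
  anchor_span <- as.integer(last_anchor - first_anchor)
  if (anchor_span < 1) abort("Study window too short for dyad anchors.")
  dyads <- tibble::tibble(
    dyad_id = seq_len(n_dyads),
    shared_count = as.integer(sizes),
    dx_provider_id = sprintf("DX%06d", seq_len(n_dyads)),
    tx_provider_id = sprintf("TX%06d", seq_len(n_dyads)),
    dyad_gender = dyad_gender,
    dx_gender = substr(dyad_gender, 1, 1),
    tx_gender = substr(dyad_gender, 2, 2),
    colocation = colocation,
    dx_facility = sprintf("F%06d", seq_len(n_dyads)),
    tx_facility = ifelse(colocation == "colocated",
                         sprintf("F%06d", seq_len(n_dyads)),
                         sprintf("G%06d", seq_len(n_dyads))),
    dx_specialty = dx_specialty,
    tx_specialty = tx_specialty,
    dx_raw_specialty = pick_raw_specialty(dx_specialty),
    tx_raw_specialty = pick_raw_specialty(tx_specialty),
    anchor = first_anchor + sample.int(anchor_span, n_dyads, replace = TRUE)
  )

  ## -- patients and covariates --------------------------------------------
  dyad_ix <- rep(seq_len(n_dyads), sizes)
  covs <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    dyad_id = dyad_ix,
    psn = ifelse(sizes[dyad_ix] >= config$psn_threshold, "psn", "no_psn"),
    stage_raw = as.integer(sample_levels(n, marg$stage)),
    cmi = sample_levels(n, marg$cmi),
    gender = sample_levels(n, marg$gender),
    age_band = sample_levels(n, marg$age_band),
    race = sample_levels(n, marg$race),
    marital = sample_levels(n, marg$marital),
    poverty = sample_levels(n, marg$poverty),
    treatment_type = sample_levels(n, marg$treatment_type)
  )
  covs$stage_group <- ifelse(covs$stage_raw >= 3, "3_4",
                             as.character(covs$stage_raw))
  covs <- dplyr::left_join(
    covs,
    dplyr::select(dyads, "dyad_id", "dyad_gender", "colocation",
                  "dx_specialty", "tx_specialty", "anchor"),
    by = "dyad_id"
  )
  # All patients of a dyad are diagnosed inside the dyad's one-year activity
  # window, so dyad tie spans are about a year (tie strength ~ shared count).
  covs$dx_date <- covs$anchor + sample.int(365L, n, replace = TRUE) - 1L
  age <- vapply(covs$age_band,
                function(b) AGE_BAND_RANGES[[b]][sample.int(length(AGE_BAND_RANGES[[b]]), 1)],
                integer(1), USE.NAMES = FALSE)
  covs$age_at_dx <- age
  covs$birth_date <- lubridate::`%m-%`(covs$dx_date, lubridate::years(age)) -
    sample.int(360L, n, replace = TRUE) + 1L

  ## -- delay outcome and TTI ----------------------------------------------
  mm <- delay_model_matrix(covs)
  effects <- config$true_effects
  lp <- as.vector(mm[, names(effects), drop = FALSE] %*% log(effects))
  b0 <- calibrate_intercept(lp, config$overall_delay_target)
  p_delay <- plogis(b0 + lp)
  delay <- rbinom(n, 1L, p_delay)

  pmf <- config$tti$pmf
  tti <- integer(n)
  n1 <- sum(delay == 1L)
  if (n1 > 0) {
    tti[delay == 1L] <- sample(31:365, n1, replace = TRUE, prob = pmf[32:366])
  }
  if (n1 < n) {
    tti[delay == 0L] <- sample(0:30, n - n1, replace = TRUE, prob = pmf[1:31])
  }

  ## -- missingness (MAR) ---------------------------------------------------
  rates <- config$missingness_rates
  total_rate <- sum(rates)
  incomplete <- rep(FALSE, n)
  blanked <- rep(NA_character_, n)
  if (total_rate > 0) {
    lpm <- config$missingness_predictor(covs, delay)
    stopifnot(length(lpm) == n)
    a0 <- calibrate_intercept(lpm, total_rate)
    incomplete <- rbinom(n, 1L, plogis(a0 + lpm)) == 1L
    if (any(incomplete)) {
      blanked[incomplete] <- sample_levels(sum(incomplete), rates / total_rate)
    }
  }

  ## -- output tables --------------------------------------------------------
  patients <- tibble::tibble(
    patient_id = covs$patient_id,
    birth_date = covs$birth_date,
    gender = covs$gender,
    race_ethnicity = ifelse(blanked %in% "race_ethnicity", NA_character_,
                            covs$race),
    marital = ifelse(blanked %in% "marital", NA_character_, covs$marital),
    poverty_stratum = ifelse(blanked %in% "poverty_stratum", NA_integer_,
                             as.integer(covs$poverty)),
    stage = ifelse(blanked %in% "stage", NA_integer_, covs$stage_raw),
    dx_date = covs$dx_date,
    histology_confirmed = 1L,
    first_primary = 1L,
    dx_source = "clinical"
  )

  providers <- dplyr::bind_rows(
    tibble::tibble(provider_id = dyads$dx_provider_id,
                   gender = dyads$dx_gender,
                   specialty = dyads$dx_raw_specialty,
                   facility_id = dyads$dx_facility),
    tibble::tibble(provider_id = dyads$tx_provider_id,
                   gender = dyads$tx_gender,
                   specialty = dyads$tx_raw_specialty,
                   facility_id = dyads$tx_facility)
  )

  dx_claims <- tibble::tibble(
    patient_id = covs$patient_id,
    provider_id = dyads$dx_provider_id[dyad_ix],
    service_date = covs$dx_date,
    code = CANCER_DX_CODE, code_class = "diagnosis",
    treatment_type = NA_character_
  )
  lag <- config$pathology_lag_days
  path_claims <- dplyr::mutate(
    dx_claims,
    service_date = .data$service_date +
      sample(seq(lag[1], lag[2]), n, replace = TRUE),
    code = PATHOLOGY_CODE, code_class = "pathology"
  )
  tx_claims <- tibble::tibble(
    patient_id = covs$patient_id,
    provider_id = dyads$tx_provider_id[dyad_ix],
    service_date = covs$dx_date + tti,
    code = unname(TREATMENT_CODES[covs$treatment_type]),
    code_class = "treatment",
    treatment_type = covs$treatment_type
  )

  cmap <- default_condition_map()
  cond_names <- names(cmap)
  n_cond <- integer(n)
  n_cond[covs$cmi == "one"] <- 1L
  two_plus <- covs$cmi == "two_plus"
  n_cond[two_plus] <- 2L + rbinom(sum(two_plus), 1L, 0.3)
  with_cond <- which(n_cond > 0)
  comorb_claims <- NULL
  if (length(with_cond) > 0) {
    picks <- draw_distinct(n_cond[with_cond], length(cond_names))
    row_ix <- rep(with_cond, n_cond[with_cond])
    cond_ix <- unlist(picks, use.names = FALSE)
    comorb_claims <- tibble::tibble(
      patient_id = covs$patient_id[row_ix],
      provider_id = dyads$dx_provider_id[dyad_ix[row_ix]],
      service_date = covs$dx_date[row_ix] -
        sample(30:365, length(row_ix), replace = TRUE),
      code = vapply(cmap[cond_ix], function(p) p[[1]], character(1),
                    USE.NAMES = FALSE),
      code_class = "diagnosis",
      treatment_type = NA_character_
    )
  }

  encounters <- dplyr::arrange(
    dplyr::bind_rows(dx_claims, path_claims, tx_claims, comorb_claims),
    .data$patient_id, .data$service_date, .data$code_class
  )

  truth <- tibble::tibble(
    patient_id = covs$patient_id,
    dyad_id = covs$dyad_id,
    shared_count = as.integer(sizes[dyad_ix]),
    psn = factor(covs$psn, levels = PSN_LEVELS),
    stage_group = covs$stage_group,
    cmi = covs$cmi,
    gender = covs$gender,
    age_band = covs$age_band,
    age_at_dx = covs$age_at_dx,
    race = covs$race,
    marital = covs$marital,
    poverty = covs$poverty,
    dyad_gender = covs$dyad_gender,
    colocation = covs$colocation,
    dx_specialty = covs$dx_specialty,
    tx_specialty = covs$tx_specialty,
    treatment_type = covs$treatment_type,
    dx_date = covs$dx_date,
    linear_predictor = lp,
    p_delay = p_delay,
    delay = delay,
    tti_days = tti,
    incomplete = incomplete,
    blanked_field = blanked
  )

  structure(
    list(patients = patients, providers = providers, encounters = encounters,
         truth = truth, intercept = b0, config = config),
    class = "synthetic_claims"
  )
}

#' @export
print.synthetic_claims <- function(x, ...) {
  cat("Synthetic claims dataset\n")
  cat(sprintf("  %d patients, %d providers, %d claim lines (seed %d)\n",
              nrow(x$patients), nrow(x$providers), nrow(x$encounters),
              x$config$seed))
  cat(sprintf("  true delay rate %.4f, true PSN share %.4f, mean TTI %.2f d\n",
              mean(x$truth$delay), mean(x$truth$psn == "psn"),
              mean(x$truth$tti_days)))
  invisible(x)
}

#' Write a synthetic dataset to CSV
#'
#' Emits `patients.csv`, `providers.csv` and `encounters.csv` in `directory`
#' (created if needed), in the schemas the readers expect.  Missing values are
#' written as empty fields; dates are ISO-8601.
#'
#' @param dataset A `synthetic_claims` object (or any list with `patients`,
#'   `providers`, `encounters` tibbles).
#' @param directory Output directory.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      abort(sprintf("Cannot create directory '%s'.", directory))
    }
  }
  paths <- c(
    patients = file.path(directory, "patients.csv"),
    providers = file.path(directory, "providers.csv"),
    encounters = file.path(directory, "encounters.csv")
  )
  readr::write_csv(dataset$patients, paths[["patients"]], na = "")
  readr::write_csv(dataset$providers, paths[["providers"]], na = "")
  readr::write_csv(dataset$encounters, paths[["encounters"]], na = "")
  invisible(paths)
}

#' Read the three claims tables from a directory
#'
#' Inverse of [write_dataset()]: reads `patients.csv`, `providers.csv` and
#' `encounters.csv` with explicit column types (dates parsed as `Date`,
#' empty fields as `NA`).
#'
#' @param directory Directory containing the three CSV files.
#' @return List with tibbles `patients`, `providers`, `encounters`.
#' @export
read_dataset <- function(directory) {
  path <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) abort(sprintf("File not found: '%s'.", p))
    p
  }
  patients <- readr::read_csv(
    path("patients.csv"), na = "",
    col_types = readr::cols(
      patient_id = "c", birth_date = "D", gender = "c",
      race_ethnicity = "c", marital = "c", poverty_stratum = "i",
      stage = "i", dx_date = "D", histology_confirmed = "i",
      first_primary = "i", dx_source = "c"
    )
  )
  providers <- readr::read_csv(
    path("providers.csv"), na = "",
    col_types = readr::cols(provider_id = "c", gender = "c",
                            specialty = "c", facility_id = "c")
  )
  encounters <- readr::read_csv(
    path("encounters.csv"), na = "",
    col_types = readr::cols(patient_id = "c", provider_id = "c",
                            service_date = "D", code = "c",
                            code_class = "c", treatment_type = "c")
  )
  list(patients = patients, providers = providers, encounters = encounters)
}
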