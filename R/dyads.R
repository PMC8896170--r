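#' Identify each patient's diagnosing provider
#'
#' The diagnosing provider is the provider on the diagnosis-class claim
#' closest in time at or before the patient's earliest pathology-confirmation
#' claim (diagnosis is anchored to pathologic confirmation).  Patients with
#' no pathology claim, or no diagnosis claim at or before it, are unresolved
#' (`NA`).  Same-day ties are broken by the lexicographically lower provider
#' id, so resolution is deterministic.
#'
#' @param encounters Claims tibble (`patient_id`, `provider_id`,
#'   `service_date`, `code_class`); may contain any number of patients.
#' @return Tibble with one row per patient present in `encounters`:
#'   `patient_id`, `dx_provider_id` (`NA` when unresolved).
#' @export
identify_dx_provider <- function(encounters) {
  all_ids <- dplyr::distinct(encounters, .data$patient_id)
  if (nrow(encounters) == 0) {
    return(tibble::tibble(patient_id = character(),
                          dx_provider_id = character()))
  }
  path <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(encounters, .data$code_class == "pathology"),
                    .data$patient_id),
    path_date = min(.data$service_date), .groups = "drop"
  )
  cand <- dplyr::inner_join(
    dplyr::filter(encounters, .data$code_class == "diagnosis"),
    path, by = "patient_id"
  )
  cand <- dplyr::filter(cand, .data$service_date <= .data$path_date)
  picked <- dplyr::slice_head(
    dplyr::group_by(
      dplyr::arrange(cand, .data$patient_id,
                     dplyr::desc(.data$service_date), .data$provider_id),
      .data$patient_id
    ),
    n = 1
  )
  dplyr::left_join(
    all_ids,
    dplyr::select(dplyr::ungroup(picked), "patient_id",
                  dx_provider_id = "provider_id"),
    by = "patient_id"
  )
}

#' Identify each patient's treating provider
#'
#' The treating provider is the provider on the earliest treatment-class
#' claim (chemotherapy, radiotherapy or surgery) on or after the diagnosis
#' date.  Same-day ties are broken by treatment priority surgery >
#' radiotherapy > chemotherapy, then by lower provider id.
#'
#' @param encounters Claims tibble.
#' @param index_dates Tibble `patient_id`, `dx_date`.
#' @return Tibble with one row per patient in `index_dates`: `patient_id`,
#'   `tx_provider_id`, `first_treatment_date`, `treatment_type` (`NA` when no
#'   qualifying treatment claim exists).
#' @export
identify_tx_provider <- function(encounters, index_dates) {
  tx <- dplyr::filter(encounters, .data$code_class == "treatment")
  if (anyNA(tx$treatment_type)) {
    abort("Treatment-class claims with missing `treatment_type` found.")
  }
  bad <- setdiff(unique(tx$treatment_type), TREATMENT_TYPES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown treatment type(s): %s.", paste(bad, collapse = ", ")))
  }
  tx <- dplyr::inner_join(tx, dplyr::select(index_dates, "patient_id",
                                            "dx_date"),
                          by = "patient_id")
  tx <- dplyr::filter(tx, .data$service_date >= .data$dx_date)
  tx$.priority <- match(tx$treatment_type, TREATMENT_TYPES)
  picked <- dplyr::slice_head(
    dplyr::group_by(
      dplyr::arrange(tx, .data$patient_id, .data$service_date,
                     .data$.priority, .data$provider_id),
      .data$patient_id
    ),
    n = 1
  )
  dplyr::left_join(
    dplyr::select(index_dates, "patient_id"),
    dplyr::select(dplyr::ungroup(picked), "patient_id",
                  tx_provider_id = "provider_id",
                  first_treatment_date = "service_date", "treatment_type"),
    by = "patient_id"
  )
}

#' Build the diagnosing-treating dyad table
#'
#' One record per unique ordered (diagnosing, treating) provider pair among
#' the cohort, with the shared-patient count, the dates of the first and last
#' shared patient (diagnosis dates), the tie strength in patients per year,
#' and the PSN flag at `threshold`.  Shared counts sum to the cohort size:
#' each patient belongs to exactly one dyad.
#'
#' @param cohort Tibble with `patient_id`, `dx_provider_id`,
#'   `tx_provider_id`, `dx_date`; providers must be resolved and distinct
#'   within each patient.
#' @param threshold PSN shared-count cut (default 3).
#' @return Tibble of dyad records sorted by decreasing `shared_count`.
#' @export
build_dyads <- function(cohort, threshold = 3L) {
  if (nrow(cohort) > 0 &&
      (anyNA(cohort$dx_provider_id) || anyNA(cohort$tx_provider_id))) {
    abort("All cohort patients must have resolved providers before dyad construction.")
  }
  if (any(cohort$dx_provider_id == cohort$tx_provider_id)) {
    abort("Self-sharing dyads found (dx provider == tx provider); a provider cannot self-share a patient.")
  }
  dyads <- dplyr::summarise(
    dplyr::group_by(cohort, .data$dx_provider_id, .data$tx_provider_id),
    shared_count = dplyr::n(),
    first_shared_date = min(.data$dx_date),
    last_shared_date = max(.data$dx_date),
    .groups = "drop"
  )
  dyads$tie_strength <- compute_tie_strength(
    dyads$shared_count, dyads$first_shared_date, dyads$last_shared_date
  )
  dyads$psn_flag <- dyads$shared_count >= as.integer(threshold)
  dplyr::arrange(dyads, dplyr::desc(.data$shared_count),
                 .data$dx_provider_id, .data$tx_provider_id)
}

#' Dyad tie strength in shared patients per year
#'
#' Shared-patient count divided by the tie duration in whole years: the
#' ceiling of the span between the first and last shared patient, floored at
#' one year (a single shared patient gives 1 patient/year).
#'
#' @param shared_count Positive integer counts.
#' @param first_shared_date,last_shared_date Date vectors.
#' @param study_window Optional length-2 Date vector; dates outside it raise
#'   an error.
#' @return Numeric patients-per-year.
#' @export
compute_tie_strength <- function(shared_count, first_shared_date,
                                 last_shared_date, study_window = NULL) {
  if (any(shared_count < 1)) abort("`shared_count` must be >= 1.")
  first_shared_date <- as.Date(first_shared_date)
  last_shared_date <- as.Date(last_shared_date)
  if (any(last_shared_date < first_shared_date)) {
    abort("`last_shared_date` precedes `first_shared_date`.")
  }
  if (!is.null(study_window)) {
    study_window <- as.Date(study_window)
    if (any(first_shared_date < study_window[1]) ||
        any(last_shared_date > study_window[2])) {
      abort("Shared dates fall outside the study window.")
    }
  }
  span_years <- as.numeric(last_shared_date - first_shared_date) / 365.25
  shared_count / pmax(1, ceiling(span_years))
}

#' Classify patients by PSN membership
#'
#' Flags each patient as PSN when their dyad's shared-patient count reaches
#' `threshold` (default 3, the top quartile of sharing; the literature uses
#' cuts from 2 to 10).  The flag is coded with PSN as the reference level, as
#' used by the delay model.
#'
#' @param cohort Tibble with `dx_provider_id`, `tx_provider_id`.
#' @param dyads Dyad table from [build_dyads()]; its counts may be computed
#'   on a larger population than `cohort` (sharing is a property of the
#'   provider pair, not of the analysed subsample).
#' @param threshold Integer `>= 2`.
#' @return `cohort` with `shared_count` and a `psn` factor
#'   (levels `psn`, `no_psn`).
#' @export
classify_psn <- function(cohort, dyads, threshold = 3L) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 2) {
    abort("`threshold` must be >= 2: a dyad definition requires sharing.")
  }
  cohort$shared_count <- NULL
  out <- dplyr::left_join(
    cohort,
    dplyr::select(dyads, "dx_provider_id", "tx_provider_id", "shared_count"),
    by = c("dx_provider_id", "tx_provider_id")
  )
  out$psn <- factor(ifelse(out$shared_count >= threshold, "psn", "no_psn"),
                    levels = PSN_LEVELS)
  out
}

# Regularized asymptotic Kolmogorov survival function Q(lambda).
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the day-level time-to-treatment distributions of two groups (used
#' to validate the PSN cut point): the statistic is the supremum gap between
#' the two empirical CDFs, and the p-value comes from the asymptotic
#' Kolmogorov distribution with effective sample size
#' `n_eff = n1 n2 / (n1 + n2)`, evaluated at Stephens' finite-sample
#' argument `(sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) D` (the uncorrected
#' asymptotic argument is measurably conservative at a few hundred
#' observations per group).
#'
#' @param x,y Numeric samples (e.g. TTI days of PSN and non-PSN patients).
#' @return Object of class `ks_result`: `D_statistic`, `p_value`, `n1`,
#'   `n2`, and the two samples (for plotting).
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.")
  }
  grid <- sort(unique(c(x, y)))
  d <- max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
  n1 <- length(x); n2 <- length(y)
  n_eff <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  structure(
    list(D_statistic = d, p_value = kolmogorov_sf(lambda),
         n1 = n1, n2 = n2, sample1 = x, sample2 = y),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat("Two-sample Kolmogorov-Smirnov (asymptotic)\n")
  cat(sprintf("  D = %.4f, p = %.4g  (n1 = %d, n2 = %d)\n",
              x$D_statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Export the dyad network
#'
#' Writes the directed diagnosing-to-treating dyad network with
#' `shared_count`, `tie_strength` and `psn_flag` edge attributes, either as a
#' plain edge-list TSV or as GraphML (readable by igraph, Gephi, etc.).
#'
#' @param dyads Dyad table from [build_dyads()].
#' @param path Output file path.
#' @param format `"edge_list"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(dyads, path, format = c("edge_list", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(sprintf("Unknown network format '%s'.", format[1]))
  })
  edges <- dplyr::select(dyads, "dx_provider_id", "tx_provider_id",
                         "shared_count", "tie_strength", "psn_flag")
  if (format == "edge_list") {
    readr::write_tsv(edges, path)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
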