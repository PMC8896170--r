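#' Default covariate marginals for the synthetic cohort
#'
#' Category probabilities for every patient- and provider-level covariate the
#' generator draws, calibrated to the descriptive profile of a large
#' SEER-Medicare colorectal-cancer cohort of adults aged 66 and over.  Raw
#' tumor stage is generated on 1--4 (stages 3 and 4 are collapsed again
#' downstream, as the delay model uses a 3|4 group); `treatment_type` sets the
#' mix of first treatments; `dyad_gender`, `colocation` and the two specialty
#' entries are drawn per provider dyad.
#'
#' @return Named list of named probability vectors, one per covariate.
#' @export
default_covariate_marginals <- function() {
  list(
    stage = c("1" = 0.367, "2" = 0.426, "3" = 0.130, "4" = 0.078),
    cmi = c(none = 0.588, one = 0.257, two_plus = 0.155),
    gender = c(M = 0.435, F = 0.565),
    age_band = c("66-70" = 0.161, "71-75" = 0.215, "76-80" = 0.237,
                 "81-85" = 0.214, "85+" = 0.173),
    race = c(White = 0.866, Black = 0.069, Hispanic = 0.013,
             Asian = 0.031, Other = 0.022),
    marital = c(Single = 0.080, Divorced = 0.055, Married = 0.486,
                Other = 0.379),
    poverty = c("1" = 0.311, "2" = 0.282, "3" = 0.251, "4" = 0.156),
    dyad_gender = c(MM = 0.878, FF = 0.021, FM = 0.049, MF = 0.052),
    colocation = c(colocated = 0.299, not_colocated = 0.701),
    dx_specialty = c(non_oncology = 0.809, primary_care = 0.179,
                     oncology = 0.012),
    tx_specialty = c(oncology = 0.083, primary_care = 0.016,
                     non_oncology = 0.901),
    treatment_type = c(surgery = 0.60, radio = 0.15, chemo = 0.25)
  )
}

#' Default true conditional effects for the delay mechanism
#'
#' Conditional odds ratios placed on the logit of a 30-day treatment delay by
#' the generator, one per non-reference level of the delay model.  Defaults are
#' the published multivariable estimates the package is calibrated against
#' (e.g. no-PSN 2.20, non-colocated dyad 1.95, female-female dyad 0.66).  Names
#' are `<variable>.<level>` term ids as returned by [delay_model_terms()].
#'
#' @return Named numeric vector of odds ratios.
#' @export
default_true_effects <- function() {
  c(
    "psn.no_psn" = 2.20,
    "stage_group.2" = 0.74,
    "stage_group.3_4" = 0.50,
    "cmi.one" = 1.18,
    "cmi.two_plus" = 1.16,
    "gender.F" = 0.89,
    "age_band.71-75" = 1.05,
    "age_band.76-80" = 1.08,
    "age_band.81-85" = 1.03,
    "age_band.85+" = 0.98,
    "race.Black" = 1.46,
    "race.Hispanic" = 1.43,
    "race.Asian" = 1.09,
    "race.Other" = 1.09,
    "marital.Divorced" = 1.11,
    "marital.Married" = 0.94,
    "marital.Other" = 0.95,
    "poverty.2" = 1.09,
    "poverty.3" = 1.10,
    "poverty.4" = 1.06,
    "dyad_gender.FF" = 0.66,
    "dyad_gender.FM" = 1.02,
    "dyad_gender.MF" = 1.23,
    "colocation.not_colocated" = 1.95,
    "dx_specialty.primary_care" = 0.61,
    "dx_specialty.oncology" = 0.40,
    "tx_specialty.primary_care" = 0.61,
    "tx_specialty.non_oncology" = 0.14
  )
}

#' Calibrate the dyad shared-patient count distribution
#'
#' Finds the parameters of a zero-truncated count mixture -- point masses on 1
#' and 2 shared patients plus a geometric tail on 3+ -- such that the
#' dyad-level mean count equals `target_mean` and the *patient-level*
#' (size-biased) probability of belonging to a dyad sharing at least 3
#' patients equals `target_prevalence`.  Both moments are available in closed
#' form, so the calibration is exact up to feasibility.
#'
#' The patient-level prevalence of membership in a dyad with count `>= 3` is
#' `E[C 1(C >= 3)] / E[C]` where `C` is the dyad count: a patient samples
#' dyads with probability proportional to their size.
#'
#' @param target_prevalence Patient-level probability of a dyad count `>= 3`,
#'   in (0, 1).  Default 0.048.
#' @param target_mean Dyad-level mean shared count, `>= 1`.  Default 1.2.
#' @param tail_ratio Geometric decay of the tail on `{3, 4, ...}` in `[0, 1)`;
#'   controls tail heaviness beyond the two calibrated moments.
#' @return An object of class `sharing_distribution`: the component masses
#'   (`p1`, `p2`, `p_tail`), `tail_ratio`, and the achieved `mean`, `sd` and
#'   `patient_prevalence`.
#' @examples
#' d <- calibrate_sharing_distribution(0.048, 1.2)
#' d$mean
#' d$patient_prevalence
#' @export
calibrate_sharing_distribution <- function(target_prevalence = 0.048,
                                           target_mean = 1.2,
                                           tail_ratio = 0.25) {
  if (!is.numeric(target_prevalence) || target_prevalence < 0 ||
      target_prevalence >= 1) {
    abort("`target_prevalence` must be in [0, 1).")
  }
  if (!is.numeric(target_mean) || target_mean < 1) {
    abort("`target_mean` must be >= 1 (counts are positive integers).")
  }
  check_probability(tail_ratio, "tail_ratio")
  if (tail_ratio >= 1) abort("`tail_ratio` must be < 1.")

  tail_mean <- 3 + tail_ratio / (1 - tail_ratio)
  tail_mass <- target_prevalence * target_mean     # = E[C 1(C >= 3)]
  p_tail <- tail_mass / tail_mean
  p2 <- (target_mean - tail_mass) - (1 - p_tail)
  p1 <- (1 - p_tail) - p2

  eps <- 1e-8
  if (p1 < -eps || p2 < -eps || p_tail < -eps || p_tail > 1 + eps) {
    ach_mean <- max(1, min(target_mean, 2 * (1 - p_tail) + tail_mass))
    abort(sprintf(
      paste0("Infeasible sharing-count calibration: prevalence %.4f with ",
             "mean %.3f yields component masses (p1=%.4f, p2=%.4f, ",
             "p_tail=%.4f); closest achievable mean with this tail is %.3f. ",
             "Adjust the targets or `tail_ratio`."),
      target_prevalence, target_mean, p1, p2, p_tail, ach_mean
    ))
  }
  p1 <- max(p1, 0); p2 <- max(p2, 0); p_tail <- max(min(p_tail, 1), 0)

  tail_var <- tail_ratio / (1 - tail_ratio)^2
  m1 <- p1 + 2 * p2 + p_tail * tail_mean
  m2 <- p1 + 4 * p2 + p_tail * (tail_var + tail_mean^2)
  prev <- if (m1 > 0) p_tail * tail_mean / m1 else 0

  if (abs(m1 - target_mean) > 0.005 || abs(prev - target_prevalence) > 0.005) {
    abort(sprintf(
      paste0("Sharing-count calibration failed: achieved mean %.4f ",
             "(target %.4f) and patient prevalence %.4f (target %.4f)."),
      m1, target_mean, prev, target_prevalence
    ))
  }

  structure(
    list(
      family = "zero-truncated {1,2} + geometric tail mixture",
      p1 = p1, p2 = p2, p_tail = p_tail, tail_ratio = tail_ratio,
      mean = m1, sd = sqrt(max(m2 - m1^2, 0)), patient_prevalence = prev
    ),
    class = "sharing_distribution"
  )
}

#' @export
print.sharing_distribution <- function(x, ...) {
  cat("Shared-patient count distribution (", x$family, ")\n", sep = "")
  cat(sprintf("  P(1)=%.4f  P(2)=%.4f  P(>=3)=%.4f (tail ratio %.2f)\n",
              x$p1, x$p2, x$p_tail, x$tail_ratio))
  cat(sprintf("  dyad mean %.3f, sd %.3f; patient-level P(count>=3) = %.4f\n",
              x$mean, x$sd, x$patient_prevalence))
  invisible(x)
}

#' Probability mass function of a calibrated sharing distribution
#'
#' @param k Vector of positive integer counts.
#' @param dist A `sharing_distribution` from [calibrate_sharing_distribution()].
#' @return `P(C = k)` for each `k`.
#' @export
dsharing <- function(k, dist) {
  stopifnot(inherits(dist, "sharing_distribution"))
  out <- numeric(length(k))
  out[k == 1] <- dist$p1
  out[k == 2] <- dist$p2
  tail <- k >= 3
  out[tail] <- dist$p_tail * (1 - dist$tail_ratio) * dist$tail_ratio^(k[tail] - 3)
  out
}

#' Draw dyad shared-patient counts
#'
#' @param n Number of dyads.
#' @param dist A `sharing_distribution`.
#' @return Integer vector of counts `>= 1`.
#' @export
rsharing <- function(n, dist) {
  stopifnot(inherits(dist, "sharing_distribution"))
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c(dist$p1, dist$p2, dist$p_tail))
  out <- comp
  in_tail <- comp == 3L
  if (any(in_tail)) {
    out[in_tail] <- 3L + stats::rgeom(sum(in_tail), prob = 1 - dist$tail_ratio)
  }
  as.integer(out)
}

#' Calibrate the time-to-treatment-initiation distribution
#'
#' Time to treatment initiation (TTI) in administrative claims is strongly
#' right-skewed.  The generator models it as a gamma distribution discretized
#' to whole days (floor) and truncated at `max_days`.  The two gamma
#' parameters are solved so that the discretized distribution has the target
#' mean and -- when `p_delay` is supplied -- the target probability of
#' exceeding 30 days (the delay fraction).  With `p_delay = NULL` the solve
#' targets the mean and standard deviation instead.
#'
#' @param mean_days Target mean TTI in days.  Default 17.3.
#' @param sd_days Target standard deviation (used only when `p_delay` is
#'   `NULL`; otherwise reported as achieved).  Default 34.6.
#' @param p_delay Target `P(TTI > 30)`, or `NULL`.
#' @param max_days Truncation point (inclusive support `0..max_days`).
#' @return An object of class `tti_distribution` with the gamma `shape` and
#'   `scale`, the day-level `pmf` over `0:max_days`, and the achieved `mean`,
#'   `sd` and `p_delay`.
#' @export
calibrate_tti_distribution <- function(mean_days = 17.3, sd_days = 34.6,
                                       p_delay = NULL, max_days = 365L) {
  if (mean_days <= 0 || mean_days >= max_days) {
    abort("`mean_days` must be in (0, max_days).")
  }
  if (!is.null(p_delay)) check_probability(p_delay, "p_delay")

  days <- 0:max_days
  disc <- function(shape, scale) {
    p <- pgamma(days + 1, shape, scale = scale) -
      pgamma(days, shape, scale = scale)
    p / pgamma(max_days + 1, shape, scale = scale)
  }
  moments <- function(p) {
    m <- sum(days * p)
    list(mean = m, sd = sqrt(max(sum(days^2 * p) - m^2, 0)),
         p_delay = sum(p[days > 30]))
  }
  objective <- function(par) {
    mo <- moments(disc(exp(par[1]), exp(par[2])))
    if (is.null(p_delay)) {
      (mo$mean / mean_days - 1)^2 + (mo$sd / sd_days - 1)^2
    } else {
      (mo$mean / mean_days - 1)^2 + ((mo$p_delay - p_delay) / 0.01)^2
    }
  }
  init <- c(log((mean_days / sd_days)^2), log(sd_days^2 / mean_days))
  fit <- stats::optim(init, objective,
                      control = list(reltol = 1e-14, maxit = 5000))
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  pmf <- disc(shape, scale)
  mo <- moments(pmf)

  ok_mean <- abs(mo$mean - mean_days) < 0.05
  ok_tail <- is.null(p_delay) || abs(mo$p_delay - p_delay) < 0.002
  if (!ok_mean || !ok_tail) {
    abort(sprintf(
      paste0("TTI calibration failed: achieved mean %.3f d (target %.3f), ",
             "P(TTI>30) %.4f%s."),
      mo$mean, mean_days, mo$p_delay,
      if (is.null(p_delay)) "" else sprintf(" (target %.4f)", p_delay)
    ))
  }

  structure(
    list(family = "discretized truncated gamma", shape = shape, scale = scale,
         max_days = as.integer(max_days), pmf = pmf,
         mean = mo$mean, sd = mo$sd, p_delay = mo$p_delay),
    class = "tti_distribution"
  )
}

#' @export
print.tti_distribution <- function(x, ...) {
  cat("TTI distribution (", x$family, ")\n", sep = "")
  cat(sprintf("  gamma shape %.4f, scale %.2f, truncated at %d days\n",
              x$shape, x$scale, x$max_days))
  cat(sprintf("  mean %.2f d, sd %.2f d, P(TTI > 30 d) = %.4f\n",
              x$mean, x$sd, x$p_delay))
  invisible(x)
}

# Default MAR missingness linear predictor (no intercept; intercept is
# calibrated to the marginal rate).  Depends only on always-observed
# covariates, so complete-case estimates have no slope bias under the default
# mechanism; supply a predictor using `delay` to study confounded missingness.
default_missingness_predictor <- function(covariates, delay) {
  0.4 * (covariates$age_band == "85+") - 0.2 * (covariates$gender == "F")
}

#' Build a synthetic-claims simulation configuration
#'
#' Bundles and validates every knob of the synthetic claims generator.  The
#' defaults ARE the calibration: a cohort whose marginals, dyad sharing
#' structure, TTI distribution and embedded conditional effects reproduce the
#' published SEER-Medicare colorectal-cancer delay analysis the package is
#' benchmarked against (delay prevalence about 17%, PSN prevalence 4.8%, mean
#' TTI 17.3 days).
#'
#' @param n_patients Number of patients to simulate.
#' @param study_start,study_end Study window (coerced with `as.Date`).
#' @param psn_target_prevalence Patient-level probability of belonging to a
#'   dyad sharing `>=` `psn_threshold` patients.
#' @param sharing_mean Dyad-level mean shared-patient count.
#' @param sharing_tail_ratio Geometric tail decay passed to
#'   [calibrate_sharing_distribution()].
#' @param tti_mean_days,tti_sd_days TTI calibration targets in days.
#' @param delay_prob_psn,delay_prob_non_psn Stratum delay proportions; their
#'   prevalence-weighted average is the overall delay rate the generator's
#'   intercept is calibrated to.
#' @param covariate_marginals As [default_covariate_marginals()].
#' @param true_effects Named odds ratios as [default_true_effects()]; names
#'   must be delay-model term ids.
#' @param missingness_rates Named per-covariate marginal blanking
#'   probabilities; allowed names are `race_ethnicity`, `marital`,
#'   `poverty_stratum`, `stage`.
#' @param missingness_predictor Function `(covariates, delay) -> numeric`
#'   giving the interceptless logit of being an incomplete case (MAR given its
#'   arguments).
#' @param psn_threshold Shared-count cut defining a PSN (default 3).
#' @param pathology_lag_days Range of days between the diagnosis claim and the
#'   pathology-confirmation claim.
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 27689L,
                       study_start = "2004-01-01",
                       study_end = "2013-12-31",
                       psn_target_prevalence = 0.048,
                       sharing_mean = 1.2,
                       sharing_tail_ratio = 0.25,
                       tti_mean_days = 17.3,
                       tti_sd_days = 34.6,
                       delay_prob_psn = 0.053,
                       delay_prob_non_psn = 0.176,
                       covariate_marginals = default_covariate_marginals(),
                       true_effects = default_true_effects(),
                       missingness_rates = c(race_ethnicity = 0.015,
                                             marital = 0.020,
                                             poverty_stratum = 0.025,
                                             stage = 0.015),
                       missingness_predictor = default_missingness_predictor,
                       psn_threshold = 3L,
                       pathology_lag_days = c(1L, 14L),
                       seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1) abort("`n_patients` must be >= 1.")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end) || study_end <= study_start) {
    abort("`study_end` must be after `study_start`.")
  }
  if (days_between(study_start, study_end) < 3 * 366) {
    abort("Study window must span at least 3 years (lookback + diagnosis + treatment).")
  }
  check_probability(psn_target_prevalence, "psn_target_prevalence")
  check_probability(delay_prob_psn, "delay_prob_psn")
  check_probability(delay_prob_non_psn, "delay_prob_non_psn")

  defaults <- default_covariate_marginals()
  if (!all(names(defaults) %in% names(covariate_marginals))) {
    abort(sprintf("`covariate_marginals` must contain entries for: %s.",
                  paste(names(defaults), collapse = ", ")))
  }
  covariate_marginals <- purrr::imap(
    covariate_marginals[names(defaults)],
    function(p, nm) check_marginal(p, names(defaults[[nm]]), nm)
  )

  valid_terms <- delay_model_terms()
  bad <- setdiff(names(true_effects), valid_terms)
  if (length(bad) > 0) {
    abort(sprintf("Unknown `true_effects` term(s): %s. Valid terms: %s.",
                  paste(bad, collapse = ", "),
                  paste(valid_terms, collapse = ", ")))
  }
  if (any(!is.finite(true_effects)) || any(true_effects <= 0)) {
    abort("`true_effects` must be positive finite odds ratios.")
  }

  allowed_missing <- c("race_ethnicity", "marital", "poverty_stratum", "stage")
  if (length(missingness_rates) > 0) {
    bad <- setdiff(names(missingness_rates), allowed_missing)
    if (length(bad) > 0) {
      abort(sprintf("`missingness_rates` names must be in {%s}; got: %s.",
                    paste(allowed_missing, collapse = ", "),
                    paste(bad, collapse = ", ")))
    }
    check_probability(missingness_rates, "missingness_rates")
    if (sum(missingness_rates) >= 1) {
      abort("Summed `missingness_rates` must be < 1.")
    }
  }
  stopifnot(is.function(missingness_predictor))
  psn_threshold <- as.integer(psn_threshold)
  if (psn_threshold < 2) abort("`psn_threshold` must be >= 2.")
  pathology_lag_days <- as.integer(pathology_lag_days)
  if (length(pathology_lag_days) != 2 || any(pathology_lag_days < 0) ||
      diff(pathology_lag_days) < 0) {
    abort("`pathology_lag_days` must be a non-decreasing pair of days >= 0.")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")

  overall_delay <- psn_target_prevalence * delay_prob_psn +
    (1 - psn_target_prevalence) * delay_prob_non_psn

  structure(
    list(
      n_patients = n_patients,
      study_start = study_start, study_end = study_end,
      psn_target_prevalence = psn_target_prevalence,
      sharing = calibrate_sharing_distribution(psn_target_prevalence,
                                               sharing_mean,
                                               sharing_tail_ratio),
      tti = calibrate_tti_distribution(tti_mean_days, tti_sd_days,
                                       p_delay = overall_delay),
      delay_prob_psn = delay_prob_psn,
      delay_prob_non_psn = delay_prob_non_psn,
      overall_delay_target = overall_delay,
      covariate_marginals = covariate_marginals,
      true_effects = true_effects,
      missingness_rates = missingness_rates,
      missingness_predictor = missingness_predictor,
      psn_threshold = psn_threshold,
      pathology_lag_days = pathology_lag_days,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic claims configuration\n")
  cat(sprintf("  %d patients, %s to %s, seed %d\n", x$n_patients,
              format(x$study_start), format(x$study_end), x$seed))
  cat(sprintf("  PSN target prevalence %.3f at threshold >= %d shared patients\n",
              x$psn_target_prevalence, x$psn_threshold))
  cat(sprintf("  overall delay target %.4f (PSN %.3f / non-PSN %.3f)\n",
              x$overall_delay_target, x$delay_prob_psn, x$delay_prob_non_psn))
  cat(sprintf("  sharing: mean %.2f, patient P(>=3) %.3f | TTI: mean %.1f d, sd %.1f d\n",
              x$sharing$mean, x$sharing$patient_prevalence,
              x$tti$mean, x$tti$sd))
  cat(sprintf("  %d embedded conditional effects; missingness %.1f%% of patients\n",
              length(x$true_effects), 100 * sum(x$missingness_rates)))
  invisible(x)
}
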