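#' Fit the completeness propensity model
#'
#' Models the probability that a patient is a complete case (no missing
#' demographics) as a logistic function of fully observed covariates, the
#' first stage of inverse-propensity weighting for complete-case selection.
#' Only covariates observable for incomplete cases may enter.
#'
#' @param data Analytic rows (see [build_analytic_table()]) including
#'   incomplete cases, with an `is_complete` logical column (derived from the
#'   demographic variables if absent).
#' @param covariates Character vector of column names; none may contain `NA`.
#' @return Object of class `completeness_fit`: the glm `fit`, the `data` with
#'   a `p_complete` column, and `covariates`.  Has [tidy()] and [glance()]
#'   methods.
#' @export
fit_completeness_propensity <- function(data,
                                        covariates = c("age_band", "gender",
                                                       "cmi", "psn",
                                                       "dyad_gender",
                                                       "colocation",
                                                       "delay")) {
  # interaction terms ("a:b") are allowed; checks apply to the base columns
  base_vars <- unique(unlist(strsplit(covariates, ":", fixed = TRUE)))
  missing_cols <- setdiff(base_vars, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Propensity covariate(s) not in `data`: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"is_complete" %in% names(data)) {
    demo <- intersect(c("race", "stage_group", "marital", "poverty", "gender"),
                      names(data))
    data$is_complete <- stats::complete.cases(data[demo])
  }
  with_na <- base_vars[vapply(data[base_vars], anyNA, logical(1))]
  if (length(with_na) > 0) {
    abort(sprintf(
      "Propensity covariates must be fully observed; `%s` contain NA.",
      paste(with_na, collapse = ", ")
    ))
  }

  if (all(data$is_complete)) {
    # degenerate: nothing is missing, every completeness probability is 1
    data$p_complete <- 1
    return(structure(list(fit = NULL, data = data, covariates = covariates),
                     class = "completeness_fit"))
  }
  if (!any(data$is_complete)) abort("No complete cases to weight.")

  formula <- as.formula(paste("is_complete ~",
                              paste(covariates, collapse = " + ")))
  fit <- glm(formula, data = data, family = binomial())
  eps <- 1e-8
  p <- fitted(fit)
  if ((any(p < eps) || any(p > 1 - eps)) && any(abs(coef(fit)) > 15)) {
    abort(paste("Complete separation detected in the completeness model;",
                "reduce or coarsen the propensity covariates."))
  }
  data$p_complete <- as.numeric(p)

  structure(list(fit = fit, data = data, covariates = covariates),
            class = "completeness_fit")
}

#' @export
print.completeness_fit <- function(x, ...) {
  cat("Completeness propensity model\n")
  cat(sprintf("  %d patients, %.1f%% complete; covariates: %s\n",
              nrow(x$data), 100 * mean(x$data$is_complete),
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.completeness_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @exportS3Method generics::glance
glance.completeness_fit <- function(x, ...) {
  tibble::tibble(n = nrow(x$data),
                 n_complete = sum(x$data$is_complete),
                 completeness_rate = mean(x$data$is_complete),
                 deviance = x$fit$deviance %||% NA_real_,
                 df.residual = x$fit$df.residual %||% NA_integer_)
}

#' Inverse-propensity weights for complete cases
#'
#' Computes `1 / p` (or, stabilized, `completeness rate / p`) from fitted
#' completeness probabilities.  Given a `completeness_fit`, returns the
#' complete cases with their `ipw_weight` filled in; given a bare numeric
#' vector of probabilities, returns the weights.
#'
#' @param x A `completeness_fit` or a numeric probability vector in (0, 1].
#' @param stabilize Multiply by the marginal completeness rate.
#' @param truncate Optional upper percentile in (0, 1) at which weights are
#'   capped (e.g. `0.99`).
#' @return Tibble of complete cases with `ipw_weight`, or a numeric weight
#'   vector.
#' @export
compute_ipw <- function(x, stabilize = FALSE, truncate = NULL) {
  finish <- function(w) {
    if (!is.null(truncate)) {
      check_probability(truncate, "truncate")
      w <- pmin(w, quantile(w, truncate, names = FALSE))
    }
    if (any(!is.finite(w)) || any(w <= 0)) {
      abort("Weights must be positive and finite.")
    }
    w
  }
  if (is.numeric(x)) {
    if (any(x <= 0)) abort("Zero completeness probability for a complete case.")
    if (any(x > 1)) abort("Probabilities must be in (0, 1].")
    if (stabilize) {
      abort(paste("Stabilization needs a `completeness_fit`: the marginal",
                  "completeness rate is not identified from the complete",
                  "cases' probabilities alone."))
    }
    return(finish(1 / x))
  }
  stopifnot(inherits(x, "completeness_fit"))
  data <- x$data
  complete <- data[data$is_complete, , drop = FALSE]
  p <- complete$p_complete
  if (any(p <= 0)) abort("Zero completeness probability for a complete case.")
  w <- 1 / p
  if (stabilize) w <- mean(data$is_complete) * w
  complete$ipw_weight <- finish(w)
  complete
}

#' Fit the weighted multivariable 30-day delay model
#'
#' Maximum-likelihood (weighted) logistic regression of the delay flag on the
#' full term set: PSN membership, stage group, comorbidity category, patient
#' gender, age band, race/ethnicity, marital status, poverty stratum, dyad
#' gender pair, colocation, and diagnosing/treating specialty -- all coded
#' against the standard reference levels.  Reports adjusted odds ratios
#' (`exp(coef)`), Wald 95% confidence intervals and p-values, and the model
#' c-statistic.  With estimated IPW weights the default standard errors are
#' robust (HC0 sandwich); set `robust = FALSE` for model-based ones.
#'
#' @param data Analytic rows with a 0/1 `delay` column and every model
#'   variable; rows with missing model variables are dropped (they belong in
#'   the propensity stage).
#' @param weights Optional: a column name (e.g. `"ipw_weight"`) or a numeric
#'   vector aligned with `data`.
#' @param robust Use sandwich (HC0) standard errors (default `TRUE`).
#' @param conf.level Confidence level for the reported intervals.
#' @param terms Model variables to include (default: the full term set).
#'   Subsetting supports reduced fits, e.g. a single-covariate model.
#' @return Object of class `delay_fit` with [tidy()], [glance()],
#'   [autoplot()] and `print()` methods.
#' @export
fit_delay_model <- function(data, weights = NULL, robust = TRUE,
                            conf.level = 0.95,
                            terms = names(delay_model_variables())) {
  vars <- terms
  bad <- setdiff(vars, names(delay_model_variables()))
  if (length(bad) > 0) {
    abort(sprintf("Unknown model variable(s): %s.", paste(bad, collapse = ", ")))
  }
  if (!"delay" %in% names(data)) abort("`data` must contain a `delay` column.")
  data <- coerce_model_factors(data)

  if (is.character(weights)) {
    if (!weights %in% names(data)) {
      abort(sprintf("Weight column '%s' not found.", weights))
    }
    w <- data[[weights]]
  } else if (is.numeric(weights)) {
    if (length(weights) != nrow(data)) {
      abort("`weights` must match `nrow(data)`.")
    }
    w <- weights
  } else {
    w <- rep(1, nrow(data))
  }

  keep <- stats::complete.cases(data[c("delay", vars)]) & !is.na(w)
  df <- data[keep, , drop = FALSE]
  df$.w <- w[keep]
  if (nrow(df) == 0) abort("No complete rows to fit on.")
  if (any(df$.w <= 0)) abort("Weights must be positive.")

  mm <- delay_model_matrix(df, vars)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(sprintf("Collinear model term(s): %s.",
                  paste(aliased, collapse = ", ")))
  }

  formula <- as.formula(paste("delay ~", paste(vars, collapse = " + ")))
  # quasibinomial: identical ML point estimates, no spurious warning for
  # fractional IPW weights.
  fit <- glm(formula, data = df, weights = .w, family = stats::quasibinomial())
  if (!fit$converged) {
    abort(sprintf("Delay model did not converge in %d IRLS iterations.",
                  fit$iter))
  }

  vc <- if (robust) sandwich::vcovHC(fit, type = "HC0") else vcov(fit)
  est <- unname(coef(fit))
  se <- unname(sqrt(diag(vc)))
  z <- qnorm(1 - (1 - conf.level) / 2)

  term_ids <- colnames(mm)  # same order/contrasts as the glm model matrix
  split_id <- stringr::str_split_fixed(term_ids, stringr::fixed("."), 2)
  results <- tibble::tibble(
    term = term_ids,
    variable = ifelse(term_ids == "(Intercept)", "(Intercept)", split_id[, 1]),
    level = ifelse(term_ids == "(Intercept)", NA_character_, split_id[, 2]),
    estimate = exp(est),
    std.error = se,
    conf.low = exp(est - z * se),
    conf.high = exp(est + z * se),
    p.value = 2 * stats::pnorm(-abs(est / se))
  )

  cidx <- survival::concordance(df$delay ~ fitted(fit), weights = df$.w)

  structure(
    list(fit = fit, vcov = vc, results = results,
         c_statistic = as.numeric(cidx$concordance),
         n = nrow(df), n_delay = sum(df$delay == 1),
         weighted = !is.null(weights), robust = robust,
         conf.level = conf.level),
    class = "delay_fit"
  )
}

#' @exportS3Method generics::tidy
tidy.delay_fit <- function(x, exponentiate = TRUE, ...) {
  out <- x$results
  if (!exponentiate) {
    out$estimate <- log(out$estimate)
    out$conf.low <- log(out$conf.low)
    out$conf.high <- log(out$conf.high)
  }
  out
}

#' @exportS3Method generics::glance
glance.delay_fit <- function(x, ...) {
  tibble::tibble(c_statistic = x$c_statistic, n = x$n, n_delay = x$n_delay,
                 df = length(coef(x$fit)), deviance = x$fit$deviance,
                 converged = x$fit$converged, robust = x$robust,
                 weighted = x$weighted)
}

#' @export
print.delay_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Multivariable odds of a 30-day treatment delay (C = %.2f; N = %d)\n\n",
              x$c_statistic, x$n))
  res <- x$results[x$results$term != "(Intercept)", ]
  lines <- sprintf(
    "  %-28s %6.2f  %5.2f-%-5.2f  %s",
    paste0(res$variable, ": ", res$level), res$estimate, res$conf.low,
    res$conf.high,
    ifelse(res$p.value < 1e-4, "<.0001", sprintf("%.4f", res$p.value))
  )
  cat(sprintf("  %-28s %6s  %11s  %s\n", "term", "AOR",
              sprintf("%d%% CI", round(100 * x$conf.level)), "p"))
  cat(lines, sep = "\n")
  cat(sprintf("\n  %s standard errors; %s\n",
              if (x$robust) "robust (HC0 sandwich)" else "model-based",
              if (x$weighted) "inverse-propensity weighted" else "unweighted"))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration of all tables with the
#' observed margins whose probability does not exceed the observed table's.
#'
#' @param x 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) abort("`x` must be a 2x2 count matrix.")
  if (any(x < 0) || any(x != round(x))) {
    abort("Counts must be non-negative integers.")
  }
  stats::fisher.test(x)$p.value
}
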