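# The delay model's fixed term structure.  Every stage of the package --
# generator, analytic-table builder, model fit, tidiers -- shares these
# variables, level orders (first level = reference) and term ids, so embedded
# effects and recovered coefficients line up by name.

delay_model_variables <- function() {
  list(
    psn = PSN_LEVELS,
    stage_group = STAGE_GROUP_LEVELS,
    cmi = CMI_LEVELS,
    gender = c("M", "F"),
    age_band = AGE_BANDS,
    race = RACE_LEVELS,
    marital = MARITAL_LEVELS,
    poverty = POVERTY_LEVELS,
    dyad_gender = DYAD_GENDER_LEVELS,
    colocation = COLOCATION_LEVELS,
    dx_specialty = DX_SPECIALTY_LEVELS,
    tx_specialty = TX_SPECIALTY_LEVELS
  )
}

delay_model_rhs <- function(vars = names(delay_model_variables())) {
  as.formula(paste("~", paste(vars, collapse = " + ")))
}

#' Term ids of the 30-day delay model
#'
#' One id per non-reference factor level, formatted `<variable>.<level>`
#' (e.g. `"psn.no_psn"`, `"colocation.not_colocated"`).  These are the valid
#' names for `true_effects` in [sim_config()] and the `term` labels returned
#' by [tidy()] on a fitted delay model.
#'
#' @return Character vector of term ids.
#' @export
delay_model_terms <- function() {
  vars <- delay_model_variables()
  unlist(purrr::imap(vars, function(lv, nm) paste(nm, lv[-1], sep = ".")),
         use.names = FALSE)
}

# Coerce the model variables of `data` to factors with canonical level order.
# Unknown categories become NA (they would silently vanish from the model
# otherwise), reported by the caller.
coerce_model_factors <- function(data) {
  vars <- delay_model_variables()
  for (nm in intersect(names(vars), names(data))) {
    data[[nm]] <- factor(as.character(data[[nm]]), levels = vars[[nm]])
  }
  data
}

# Model matrix with term-id column names (intercept kept, named
# "(Intercept)").  `data` must carry the requested model variables.
delay_model_matrix <- function(data, vars = names(delay_model_variables())) {
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(sprintf("Missing delay-model variable(s): %s.",
                  paste(missing_vars, collapse = ", ")))
  }
  data <- coerce_model_factors(data)
  rhs <- delay_model_rhs(vars)
  mm <- model.matrix(rhs, data)
  labels <- attr(stats::terms(rhs), "term.labels")
  assign <- attr(mm, "assign")
  new_names <- colnames(mm)
  for (j in seq_along(new_names)) {
    if (assign[j] == 0) next
    var <- labels[assign[j]]
    new_names[j] <- paste(var, substring(colnames(mm)[j], nchar(var) + 1),
                          sep = ".")
  }
  colnames(mm) <- new_names
  mm
}
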