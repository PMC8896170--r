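# Shared level sets; ordering fixes the reference level used throughout the
# modelling stage (first level = reference).
AGE_BANDS <- c("66-70", "71-75", "76-80", "81-85", "85+")
RACE_LEVELS <- c("White", "Black", "Hispanic", "Asian", "Other")
MARITAL_LEVELS <- c("Single", "Divorced", "Married", "Other")
DYAD_GENDER_LEVELS <- c("MM", "FF", "FM", "MF")
PSN_LEVELS <- c("psn", "no_psn")
STAGE_GROUP_LEVELS <- c("1", "2", "3_4")
CMI_LEVELS <- c("none", "one", "two_plus")
POVERTY_LEVELS <- c("1", "2", "3", "4")
COLOCATION_LEVELS <- c("colocated", "not_colocated")
DX_SPECIALTY_LEVELS <- c("non_oncology", "primary_care", "oncology")
TX_SPECIALTY_LEVELS <- c("oncology", "primary_care", "non_oncology")
TREATMENT_TYPES <- c("surgery", "radio", "chemo")
CODE_CLASSES <- c("diagnosis", "pathology", "treatment")

# Completed years of age at `at` for someone born `birth` (calendar-exact).
age_at <- function(birth, at) {
  as.integer(lubridate::interval(birth, at) %/% lubridate::years(1))
}

# Whole-day difference used for all claim-date arithmetic.
days_between <- function(from, to) {
  as.integer(round(as.numeric(difftime(as.Date(to), as.Date(from), units = "days"))))
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

# Named probability vector over exactly `levels`, renormalised.
check_marginal <- function(p, levels, name) {
  if (is.null(names(p)) || !setequal(names(p), levels)) {
    abort(sprintf(
      "`%s` must be a named probability vector over {%s}.",
      name, paste(levels, collapse = ", ")
    ))
  }
  p <- p[levels]
  check_probability(p, name)
  if (sum(p) <= 0) abort(sprintf("`%s` must have positive mass.", name))
  p / sum(p)
}
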