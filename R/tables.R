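#' Mask small cells in a count table
#'
#' Applies CMS-style cell suppression: counts from 1 to `threshold - 1`
#' (default 1-10) are rendered as `"<11"`.  When exactly one cell of a group
#' is masked, the group margin would reveal it by subtraction, so the
#' smallest remaining cell of the group is masked too (complementary
#' suppression).  Zero cells are not masked by default.
#'
#' @param x A tibble with an integer count column, or a bare integer vector.
#' @param count_col Name of the count column (default `"n"`).
#' @param group_cols Optional character vector of columns defining the margin
#'   groups for complementary suppression.
#' @param threshold Minimum displayable count (default 11).
#' @param suppress_zero Also mask zero counts.
#' @return The tibble with logical `suppressed` and character `display`
#'   columns appended; for a vector input, the character display vector.
#' @export
suppress_small_cells <- function(x, count_col = "n", group_cols = NULL,
                                 threshold = 11L, suppress_zero = FALSE) {
  threshold <- as.integer(threshold)
  label <- paste0("<", threshold)
  mask_primary <- function(n) {
    (n >= 1L & n < threshold) | (suppress_zero & n == 0L)
  }

  if (is.numeric(x) && is.null(dim(x))) {
    if (any(x != round(x), na.rm = TRUE)) abort("Counts must be integers.")
    return(ifelse(mask_primary(x), label, as.character(x)))
  }

  if (!count_col %in% names(x)) {
    abort(sprintf("Count column '%s' not found.", count_col))
  }
  n <- x[[count_col]]
  if (any(n != round(n), na.rm = TRUE)) abort("Counts must be integers.")
  suppressed <- mask_primary(n)

  group_key <- if (is.null(group_cols)) {
    rep("all", nrow(x))
  } else {
    do.call(paste, c(x[group_cols], sep = "\r"))
  }
  for (g in unique(group_key)) {
    idx <- which(group_key == g)
    if (sum(suppressed[idx]) == 1L && length(idx) > 1L) {
      open <- idx[!suppressed[idx]]
      comp <- open[which.min(n[open])]
      suppressed[comp] <- TRUE
    }
  }

  x$suppressed <- suppressed
  x$display <- ifelse(suppressed, label, as.character(n))
  x
}

default_descriptive_variables <- function() {
  c("stage_group", "cmi", "gender", "age_band", "race", "marital",
    "poverty", "dyad_gender", "colocation", "dx_specialty", "tx_specialty")
}

#' Stratified descriptive table with tests and suppression
#'
#' For each covariate and each stratum (PSN membership by default), tabulates
#' patients *without* a care delay by covariate level, as counts and column
#' percentages, with a p-value from the level-by-delay crosstab within the
#' stratum: Pearson chi-square, replaced by a Fisher exact test when any
#' observed cell is below `fisher_threshold` (exact enumeration for 2x2
#' tables; Monte-Carlo otherwise).  Small cells are masked last (see
#' [suppress_small_cells()]), including the percentages of masked cells.
#'
#' @param analytic Analytic rows with `delay` and the covariates.
#' @param stratifier Stratifying column (default `"psn"`).
#' @param variables Covariates to tabulate.
#' @param fisher_threshold Cell count below which Fisher's exact test is
#'   used (default 5).
#' @param suppress Apply cell suppression (default `TRUE`).
#' @param threshold Suppression threshold (default 11).
#' @return Tibble: `variable`, `level`, `stratum`, `n_no_delay`,
#'   `pct_no_delay`, `p_value`, `test`, plus `suppressed` / `display` /
#'   `display_pct` when `suppress` is `TRUE`.
#' @export
descriptive_table <- function(analytic, stratifier = "psn",
                              variables = default_descriptive_variables(),
                              fisher_threshold = 5L, suppress = TRUE,
                              threshold = 11L) {
  if (!stratifier %in% names(analytic)) {
    abort(sprintf("Stratifier '%s' not found.", stratifier))
  }
  svals <- analytic[[stratifier]]
  strata <- if (is.factor(svals)) levels(svals) else sort(unique(svals[!is.na(svals)]))
  rows <- purrr::map_dfr(strata, function(s) {
    sub <- analytic[!is.na(analytic[[stratifier]]) &
                      analytic[[stratifier]] == s, , drop = FALSE]
    if (nrow(sub) == 0) abort(sprintf("Empty stratum '%s'.", s))
    purrr::map_dfr(variables, function(v) {
      keep <- !is.na(sub[[v]]) & !is.na(sub$delay)
      tab <- table(factor(sub[[v]][keep]), factor(sub$delay[keep],
                                                  levels = c(0, 1)))
      if (any(tab < fisher_threshold)) {
        if (all(dim(tab) == c(2, 2))) {
          p <- fisher_exact(tab); test <- "fisher_exact"
        } else {
          p <- stats::fisher.test(tab, simulate.p.value = TRUE,
                                  B = 10000)$p.value
          test <- "fisher_monte_carlo"
        }
      } else {
        p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
        test <- "chi_square"
      }
      no_delay <- tab[, "0"]
      tibble::tibble(
        variable = v, level = rownames(tab), stratum = s,
        n_no_delay = as.integer(no_delay),
        pct_no_delay = 100 * as.numeric(no_delay) / sum(no_delay),
        p_value = p, test = test
      )
    })
  })

  if (suppress) {
    rows <- suppress_small_cells(rows, count_col = "n_no_delay",
                                 group_cols = c("variable", "stratum"),
                                 threshold = threshold)
    rows$display_pct <- ifelse(rows$suppressed, "--",
                               sprintf("%.1f", rows$pct_no_delay))
  }
  rows
}
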