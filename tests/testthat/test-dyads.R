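test_that("diagnosing provider is the diagnosis claim closest before pathology", {
  # unique candidate
  enc <- dplyr::bind_rows(
    make_claim("P1", "A", "2006-01-07", "diagnosis"),
    make_claim("P1", "X", "2006-01-10", "pathology")
  )
  expect_equal(identify_dx_provider(enc)$dx_provider_id, "A")

  # closest-preceding rule: B (day -2) beats A (day -10)
  enc <- dplyr::bind_rows(
    make_claim("P1", "A", "2006-01-01", "diagnosis"),
    make_claim("P1", "B", "2006-01-09", "diagnosis"),
    make_claim("P1", "X", "2006-01-11", "pathology")
  )
  expect_equal(identify_dx_provider(enc)$dx_provider_id, "B")

  # diagnosis after pathology does not qualify
  enc <- dplyr::bind_rows(
    make_claim("P1", "C", "2006-01-12", "diagnosis"),
    make_claim("P1", "X", "2006-01-11", "pathology")
  )
  expect_true(is.na(identify_dx_provider(enc)$dx_provider_id))

  # only pathology claims: unresolved
  enc <- make_claim("P1", "X", "2006-01-11", "pathology")
  expect_true(is.na(identify_dx_provider(enc)$dx_provider_id))

  # same-day tie broken by lower provider id
  enc <- dplyr::bind_rows(
    make_claim("P1", "B", "2006-01-10", "diagnosis"),
    make_claim("P1", "A", "2006-01-10", "diagnosis"),
    make_claim("P1", "X", "2006-01-10", "pathology")
  )
  expect_equal(identify_dx_provider(enc)$dx_provider_id, "A")
})

test_that("treating provider is the earliest treatment after diagnosis", {
  idx <- tibble::tibble(patient_id = "P1", dx_date = as.Date("2006-01-01"))

  enc <- dplyr::bind_rows(
    make_claim("P1", "S", "2006-01-13", "treatment", treatment_type = "surgery"),
    make_claim("P1", "C", "2006-02-10", "treatment", treatment_type = "chemo")
  )
  got <- identify_tx_provider(enc, idx)
  expect_equal(got$tx_provider_id, "S")
  expect_equal(got$first_treatment_date, as.Date("2006-01-13"))
  expect_equal(got$treatment_type, "surgery")

  # same-day tie: surgery > radiotherapy > chemotherapy
  enc <- dplyr::bind_rows(
    make_claim("P1", "C", "2006-01-13", "treatment", treatment_type = "chemo"),
    make_claim("P1", "R", "2006-01-13", "treatment", treatment_type = "radio"),
    make_claim("P1", "S", "2006-01-13", "treatment", treatment_type = "surgery")
  )
  expect_equal(identify_tx_provider(enc, idx)$treatment_type, "surgery")

  # treatment strictly before diagnosis only: unresolved
  enc <- make_claim("P1", "S", "2005-12-30", "treatment",
                    treatment_type = "surgery")
  expect_true(is.na(identify_tx_provider(enc, idx)$tx_provider_id))

  # missing treatment type is a data error
  enc <- make_claim("P1", "S", "2006-01-13", "treatment")
  expect_error(identify_tx_provider(enc, idx), "treatment_type")
})

test_that("the five-patient worked example yields dyad counts 2,1,1,1", {
  dyads <- build_dyads(fig1_cohort())
  expect_equal(nrow(dyads), 4)
  key <- paste(dyads$dx_provider_id, dyads$tx_provider_id)
  counts <- setNames(dyads$shared_count, key)
  expect_equal(counts[["A 1"]], 2L)
  expect_equal(counts[["B 1"]], 1L)
  expect_equal(counts[["B 2"]], 1L)
  expect_equal(counts[["C 2"]], 1L)
  expect_false(any(dyads$psn_flag))  # 2 shared is below the >=3 cut
})

test_that("dyad counts equal a brute-force group-by and conserve the cohort", {
  ds <- generate_cohort(small_config(n = 200, seed = 12))
  res <- apply_eligibility(ds$patients, ds$encounters, ds$providers)
  dyads <- build_dyads(res$cohort)
  brute <- table(paste(res$cohort$dx_provider_id, res$cohort$tx_provider_id))
  got <- setNames(dyads$shared_count,
                  paste(dyads$dx_provider_id, dyads$tx_provider_id))
  expect_equal(sort(names(got)), sort(names(brute)))
  expect_equal(as.integer(got[names(brute)]), as.integer(brute),
               ignore_attr = TRUE)
  expect_equal(sum(dyads$shared_count), nrow(res$cohort))
})

test_that("self-sharing providers are rejected at dyad construction", {
  bad <- fig1_cohort()
  bad$tx_provider_id[1] <- "A"
  expect_error(build_dyads(bad), "self-share")
})

test_that("tie strength divides shared count by the (floored) year span", {
  d0 <- as.Date("2006-01-01")
  expect_equal(compute_tie_strength(4L, d0, d0 + 730), 2.0)
  expect_equal(compute_tie_strength(1L, d0, d0), 1.0)
  expect_equal(compute_tie_strength(3L, d0, d0 + 100), 3.0)   # span < 1y
  expect_equal(compute_tie_strength(2L, d0, d0 + 400), 1.0)   # ceil to 2y
  expect_error(compute_tie_strength(2L, d0 + 10, d0), "precedes")
  expect_error(compute_tie_strength(2L, d0, d0 + 10,
                                    study_window = c(d0 + 5, d0 + 20)),
               "study window")
})

test_that("mean tie strength on the calibrated generator is about 1.2/yr", {
  ds <- generate_cohort(small_config(n = 8000, seed = 14))
  res <- apply_eligibility(ds$patients, ds$encounters, ds$providers)
  other <- setdiff(eligibility_rule_names(), "demographic_complete")
  pass <- Reduce(`&`, res$flags[other], rep(TRUE, nrow(res$flags)))
  dyads <- build_dyads(res$linked[pass, ])
  expect_lt(abs(mean(dyads$tie_strength) - 1.2), 0.1)
})

test_that("PSN classification is exact at the threshold and monotone in it", {
  cohort <- fig1_cohort()
  dyads <- build_dyads(cohort)
  dyads$shared_count <- c(3L, 2L, 1L, 1L)  # force boundary values
  out3 <- classify_psn(cohort, dyads, threshold = 3)
  joined <- setNames(as.character(out3$psn),
                     paste(out3$dx_provider_id, out3$tx_provider_id))
  by_count <- setNames(dyads$shared_count,
                       paste(dyads$dx_provider_id, dyads$tx_provider_id))
  expect_true(all(joined[names(by_count)[by_count >= 3]] == "psn"))
  expect_true(all(joined[names(by_count)[by_count < 3]] == "no_psn"))

  prev <- vapply(2:6, function(th) {
    mean(classify_psn(cohort, dyads, threshold = th)$psn == "psn")
  }, numeric(1))
  expect_true(all(diff(prev) <= 0))
  expect_error(classify_psn(cohort, dyads, threshold = 1), ">= 2")
})

test_that("KS statistic equals an exhaustive ECDF scan and matches ks.test", {
  withr::with_seed(99, {
    x <- rnorm(50); y <- rnorm(50, mean = 0.5)
  })
  got <- ks_two_sample(x, y)
  # independent brute force over all observed points
  pts <- c(x, y)
  d_brute <- max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
  expect_equal(got$D_statistic, d_brute, tolerance = 1e-12)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(got$D_statistic, unname(ref$statistic), tolerance = 1e-12)
  # p from the Kolmogorov series at Stephens' finite-sample argument,
  # recomputed independently here
  n_eff <- 50 * 50 / 100
  lam <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d_brute
  k <- 1:200
  p_ref <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  expect_equal(got$p_value, p_ref, tolerance = 1e-8)
  # the finite-sample argument only sharpens the plain asymptotic p a little
  expect_lt(abs(got$p_value - ref$p.value), 0.02)
})

test_that("KS boundary cases: identical samples give D = 0, disjoint give D = 1", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ks_two_sample(x, x)$D_statistic, 0)
  got <- ks_two_sample(x, x + 100)
  expect_equal(got$D_statistic, 1)
  expect_lt(got$p_value, 0.05)
  expect_error(ks_two_sample(numeric(0), x), "non-empty")
})

test_that("network exports round-trip through both formats", {
  dyads <- build_dyads(fig1_cohort())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(dyads, tsv, format = "edge_list")
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), 4)
  expect_equal(sort(back$shared_count), sort(dyads$shared_count))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(dyads, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 4)
  eattr <- igraph::edge_attr(g, "shared_count")
  expect_equal(sort(eattr), sort(dyads$shared_count))

  expect_error(export_network(dyads, tsv, format = "dot"), "Unknown")
})
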