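test_that("cohort generation is deterministic and honours degenerate prevalences", {
  prm <- cohort_params(n_patients = 120, seed = 9)
  a <- generate_cohort(prm)
  b <- generate_cohort(prm)
  expect_identical(a, b)
  expect_equal(nrow(a), 120)
  expect_true(all(a$n_visits >= 1))
  expect_true(all(a$mme_per_day > 0))
  expect_true(all(a$age_years >= 18))

  none <- generate_cohort(cohort_params(n_patients = 80, seed = 9,
                                        benzodiazepine_prevalence = 0))
  expect_false(any(none$benzodiazepine))
  all_b <- generate_cohort(cohort_params(n_patients = 80, seed = 9,
                                         benzodiazepine_prevalence = 1))
  expect_true(all(all_b$benzodiazepine))
})

test_that("synthetic marginals match their targets at large n", {
  prm <- cohort_params(n_patients = 10000, seed = 21)
  cohort <- generate_cohort(prm)
  expect_within_binom99(mean(cohort$benzodiazepine), nrow(cohort), 0.284)
  # log-normal dose distribution reproduces its mean/SD targets
  expect_lt(abs(mean(cohort$mme_per_day) - 70), 3)
  expect_lt(abs(stats::sd(cohort$mme_per_day) - 66), 6)
})

test_that("visit simulation is reproducible and structurally coherent", {
  prm <- cohort_params(n_patients = 60, seed = 31)
  cohort <- generate_cohort(prm)
  v1 <- simulate_visits(cohort, prm)
  v2 <- simulate_visits(cohort, prm)
  expect_identical(v1, v2)
  # verdict present iff tested
  expect_true(all(is.na(v1$status) == !v1$tested))
  expect_true(all(vapply(v1$panel, is.null, logical(1)) == !v1$tested))
  # every visit count matches the cohort's draw
  counts <- dplyr::count(v1, .data$patient_id)
  expect_equal(counts$n[match(cohort$patient_id, counts$patient_id)],
               cohort$n_visits)
})

test_that("every simulated verdict round-trips through the classifier", {
  prm <- cohort_params(n_patients = 150, seed = 17)
  sim <- simulate_cohort(prm)
  tested <- dplyr::filter(sim$visits, tested)
  rx_by_patient <- split(sim$prescriptions$drug, sim$prescriptions$patient_id)
  redo <- mapply(function(panel, pid) {
    v <- classify_panel(panel, rx_by_patient[[pid]])
    list(status = v$status, primary = v$primary_reason)
  }, tested$panel, tested$patient_id, SIMPLIFY = FALSE)
  expect_equal(vapply(redo, `[[`, character(1), "status"), tested$status,
               ignore_attr = TRUE)
  expect_equal(vapply(redo, `[[`, character(1), "primary"),
               tested$primary_reason, ignore_attr = TRUE)
  # synthesized consistent panels are exactly the expected analytes (+- THC)
  consistent <- dplyr::filter(tested, .data$status == "consistent")
  expect_gt(nrow(consistent), 0)
  ok <- mapply(function(panel, pid) {
    setequal(setdiff(panel, "thc"),
             expected_analytes(rx_by_patient[[pid]]))
  }, consistent$panel, consistent$patient_id)
  expect_true(all(ok))
})

test_that("recommendation frequencies calibrate to the policy per category", {
  prm <- cohort_params(n_patients = 4000, seed = 41)
  visits <- simulate_visits(generate_cohort(prm), prm)
  pol <- default_policy()
  by_cat <- dplyr::summarise(dplyr::group_by(visits, .data$category),
                             n = dplyr::n(), rec = mean(.data$recommended))
  for (i in seq_len(nrow(by_cat))) {
    p <- unname(pol$test_probabilities[as.character(by_cat$category[i])])
    expect_within_binom99(by_cat$rec[i], by_cat$n[i], p)
  }
  expect_true(all(by_cat$n > 1000))
})

test_that("a degenerate generative model collapses to a plain Bernoulli rate", {
  prm <- cohort_params(n_patients = 4000, seed = 55,
                       patient_random_intercept_sd = 0,
                       category_effects = c(low = 0, moderate = 0, high = 0,
                                            high_plus = 0))
  visits <- simulate_visits(generate_cohort(prm), prm)
  tested <- dplyr::filter(visits, tested)
  expect_gt(nrow(tested), 3000)
  expect_within_binom99(mean(tested$status == "inconsistent"), nrow(tested),
                        0.044)
})

test_that("category-dependent effects order the low band below the others", {
  prm <- cohort_params(n_patients = 6000, seed = 63)
  visits <- simulate_visits(generate_cohort(prm), prm)
  stats <- summarize_visits(visits)
  low <- stats$pct_inconsistent[stats$category == "low"]
  others <- stats$pct_inconsistent[stats$category %in%
                                     c("moderate", "high", "high_plus")]
  expect_true(all(low < others))
})

test_that("an inconsistent verdict escalates the patient's later categories", {
  prm <- cohort_params(n_patients = 400, seed = 77)
  visits <- dplyr::arrange(simulate_visits(generate_cohort(prm), prm),
                           .data$patient_id, .data$visit_index)
  per <- split(visits, visits$patient_id)
  for (pv in per) {
    first_bad <- match(TRUE, !is.na(pv$status) & pv$status == "inconsistent")
    if (is.na(first_bad) || first_bad == nrow(pv)) next
    after <- pv[(first_bad + 1):nrow(pv), ]
    # after the flag is set the category is the escalated base at every visit
    expect_equal(as.character(after$category),
                 as.character(escalate(after$base_category, TRUE)))
    # and the category sequence never drops below the pre-flag level
    expect_true(all(as.integer(after$category) >=
                      as.integer(pv$category[first_bad])))
  }
})

test_that("a positive random intercept SD induces within-patient clustering", {
  prm <- cohort_params(n_patients = 600, seed = 91,
                       patient_random_intercept_sd = 1.5)
  visits <- simulate_visits(generate_cohort(prm), prm)
  tested <- dplyr::filter(visits, tested)
  y <- as.numeric(tested$status == "inconsistent")
  id <- tested$patient_id
  stat <- function(y) {
    m <- rowsum(y, id)[, 1] / as.integer(table(id))
    sum(as.integer(table(id)) * (m - mean(y))^2)
  }
  observed <- stat(y)
  set.seed(1)
  perms <- replicate(500, stat(sample(y)))
  # patient-level permutation: observed between-patient dispersion in the
  # top percentile demonstrates positive intraclass correlation
  expect_gt(observed, stats::quantile(perms, 0.99))
})
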