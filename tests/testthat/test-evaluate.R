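study_stats <- summarize_counts(udt_study_counts()$tests)

test_that("category summaries count tested visits only and respect invariants", {
  prm <- cohort_params(n_patients = 200, seed = 13)
  visits <- simulate_visits(generate_cohort(prm), prm)
  stats <- summarize_visits(visits)
  body <- stats[stats$category != "overall", ]
  overall <- stats[stats$category == "overall", ]
  expect_equal(overall$n_tests, sum(body$n_tests))
  expect_equal(body$n_consistent + body$n_inconsistent, body$n_tests)
  expect_equal(overall$n_tests, sum(visits$tested))
  # reason counts partition the inconsistent tests (one primary per test)
  expect_equal(body$n_negative_for_prescribed_opioid +
                 body$n_positive_for_unprescribed_opioid +
                 body$n_positive_for_illicit_drug,
               body$n_inconsistent)
  # a tested visit without a verdict is a data error naming the row
  broken <- visits
  broken$status[which(broken$tested)[1]] <- NA
  expect_error(summarize_visits(broken), "lacking a verdict")
})

test_that("degenerate summary inputs are handled explicitly", {
  empty <- tibble::tibble(category = character(0), tested = logical(0),
                          status = character(0))
  s <- summarize_visits(empty)
  expect_true(all(s$n_tests == 0))
  expect_true(all(is.na(s$pct_inconsistent)))
  all_cons <- tibble::tibble(category = rep("moderate", 50), tested = TRUE,
                             status = "consistent")
  s2 <- summarize_visits(all_cons)
  expect_equal(s2$pct_inconsistent[s2$category == "moderate"], 0)
})

test_that("reason shares report both denominators explicitly", {
  shares <- reason_shares(study_stats)
  high_neg <- shares[shares$category == "high" &
                       shares$reason == "negative_for_prescribed_opioid", ]
  # 12 of 28 inconsistent high-category tests vs 12 of 338 high-category tests
  expect_equal(high_neg$pct_of_inconsistent, 42.9)
  expect_equal(high_neg$pct_of_tests, 3.6)
  low_neg <- shares[shares$category == "low" &
                      shares$reason == "negative_for_prescribed_opioid", ]
  expect_equal(low_neg$pct_of_tests, 1.9)
})

test_that("percentages round half away from zero to one decimal", {
  expect_equal(round_half_up(c(16.25, 99.375, 4.375, 53.75) / 100 * 100, 1),
               c(16.3, 99.4, 4.4, 53.8))
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("crude odds ratios have the symmetry and correction properties", {
  for (k in c(1, 5, 12)) {
    expect_equal(crude_odds_ratio(k, k, k, k)$estimate, 1)
  }
  zero <- crude_odds_ratio(0, 10, 5, 20)
  expect_true(zero$corrected)
  expect_true(is.finite(zero$estimate) && zero$estimate > 0)
  expect_equal(zero$estimate, (0.5 * 20.5) / (10.5 * 5.5))
  expect_error(crude_odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("category odds ratios against low reproduce the cross-products", {
  ors <- category_odds_ratios(study_stats)
  expect_equal(ors$estimate[ors$category == "moderate"],
               (32 * 153) / (317 * 7))
  expect_equal(ors$estimate[ors$category == "high"],
               (28 * 153) / (310 * 7))
  # Woolf interval matches its closed form
  mod <- ors[ors$category == "moderate", ]
  se <- sqrt(1 / 32 + 1 / 317 + 1 / 7 + 1 / 153)
  expect_equal(mod$conf.low, exp(log(mod$estimate) - 1.959964 * se),
               tolerance = 1e-6)
})

test_that("collapsing categories conserves counts and composes with the fit", {
  identity_scheme <- stats::setNames(risk_levels(), risk_levels())
  two_band <- c(low = "low", moderate = "high", high = "high",
                high_plus = "high")
  collapsed <- collapse_categories(study_stats, two_band)
  expect_equal(collapsed$n_tests[collapsed$category == "high"], 349 + 338 + 132)
  expect_equal(collapsed$n_inconsistent[collapsed$category == "high"],
               32 + 28 + 9)
  expect_equal(collapsed$n_tests[collapsed$category == "overall"], 979)

  prm <- cohort_params(n_patients = 300, seed = 19)
  visits <- simulate_visits(generate_cohort(prm), prm)
  same <- collapse_categories(visits, identity_scheme)
  expect_equal(as.character(same$category), as.character(visits$category))
  merged <- collapse_categories(visits, two_band)
  s_orig <- summarize_visits(visits)
  s_merged <- summarize_visits(merged)
  expect_equal(s_merged$n_tests[s_merged$category == "overall"],
               s_orig$n_tests[s_orig$category == "overall"])
  expect_error(collapse_categories(visits, two_band[-1]), "missing")
  # the two-category analysis runs end to end on collapsed data
  fit <- fit_category_model(merged)
  expect_true(fit$converged)
  expect_true("categoryhigh" %in% names(fit$coefficients))
})

test_that("GEE equals ordinary logistic ML with independent observations", {
  set.seed(101)
  n <- 500
  d <- tibble::tibble(patient_id = sprintf("p%04d", 1:n), x = rnorm(n))
  d$y <- runif(n) < plogis(-1 + 0.7 * d$x)
  fit <- fit_gee_logistic(d, y ~ x, cluster = "patient_id")
  ml <- stats::glm(y ~ x, data = d, family = binomial())
  expect_lt(max(abs(fit$coefficients - coef(ml)) / abs(coef(ml))), 1e-6)
  expect_equal(fit$alpha, 0)
})

test_that("the sandwich variance matches an independent implementation", {
  set.seed(202)
  g <- 120
  d <- tibble::tibble(patient_id = rep(sprintf("c%03d", 1:g), each = 4),
                      x = rnorm(4 * g),
                      b = rep(rnorm(g, 0, 1), each = 4))
  d$y <- runif(4 * g) < plogis(-0.5 + 0.6 * d$x + d$b)
  fit <- fit_gee_logistic(d, y ~ x, cluster = "patient_id",
                          working = "independence")
  ml <- stats::glm(y ~ x, data = d, family = binomial())
  vc <- sandwich::vcovCL(ml, cluster = d$patient_id, type = "HC0",
                         cadjust = FALSE)
  expect_lt(max(abs(fit$robust_se - sqrt(diag(vc))) / sqrt(diag(vc))), 1e-6)
  # exchangeable alpha picks up the induced correlation
  fit_ex <- fit_gee_logistic(d, y ~ x, cluster = "patient_id",
                             working = "exchangeable")
  expect_gt(fit_ex$alpha, 0.05)
})

test_that("degenerate designs are flagged instead of crashing", {
  set.seed(303)
  d <- tibble::tibble(patient_id = rep(sprintf("c%02d", 1:30), each = 3),
                      visit_index = rep(1:3, 30), x = rnorm(90))
  # all-zero outcome: no events to fit
  d$y <- FALSE
  fit0 <- fit_gee_logistic(d, y ~ x, cluster = "patient_id")
  expect_false(fit0$converged)
  # constant indicator: aliased with the intercept, reported NA
  d$y <- runif(90) < 0.3
  d$thc <- TRUE
  fit1 <- fit_gee_logistic(d, y ~ thc + visit_index, cluster = "patient_id")
  expect_true(any(fit1$aliased))
  expect_true(is.na(fit1$coefficients["thcTRUE"]))
  # fewer than two clusters is an error
  expect_error(fit_gee_logistic(dplyr::mutate(d, patient_id = "one"),
                                y ~ x, cluster = "patient_id"),
               "2 clusters")
})

test_that("a THC model with no positive tests flags the term inestimable", {
  prm <- cohort_params(n_patients = 100, seed = 23, thc_rate = 0)
  visits <- simulate_visits(generate_cohort(prm), prm)
  fit <- fit_thc_model(visits)
  expect_true(is.na(fit$coefficients["thc_positiveTRUE"]))
  expect_true(any(fit$aliased))
})

test_that("THC confidence intervals cover the null when THC has no effect", {
  covered <- 0
  for (s in 1:30) {
    prm <- cohort_params(n_patients = 800, seed = 4000 + s)
    visits <- simulate_visits(generate_cohort(prm), prm)
    fit <- fit_thc_model(visits)
    ci <- tidy(fit, exponentiate = TRUE)
    row <- ci[ci$term == "thc_positiveTRUE", ]
    if (!is.na(row$conf.low) && row$conf.low <= 1 && row$conf.high >= 1) {
      covered <- covered + 1
    }
  }
  # nominal 95%: central 99% binomial band for 30 replicates reaches down to 25
  expect_gte(covered, 25)
})

test_that("tidy and glance expose the broom-style summaries", {
  prm <- cohort_params(n_patients = 150, seed = 29)
  visits <- simulate_visits(generate_cohort(prm), prm)
  fit <- fit_category_model(visits)
  td <- tidy(fit, exponentiate = TRUE)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high")
                  %in% names(td)))
  expect_equal(td$estimate[td$term != "(Intercept)" & !is.na(td$estimate)],
               exp(fit$coefficients[names(fit$coefficients) != "(Intercept)" &
                                      !is.na(fit$coefficients)]),
               ignore_attr = TRUE)
  gl <- glance(fit)
  expect_equal(gl$n_obs, sum(visits$tested))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(summarize_visits(visits)), "ggplot")
})
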