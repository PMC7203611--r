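# Synthetic COAT cohorts and visit histories.
#
# The generative model for a tested visit's outcome is a patient-level
# random-intercept logistic model,
#   logit P(inconsistent) = baseline_logit + category_effect + b_i,
#   b_i ~ N(0, patient_random_intercept_sd^2),
# which induces the within-patient correlation the GEE evaluation exists to
# handle. Defaults anchor the synthetic marginals to the retrospective cohort
# the scheduler was evaluated on: mean (SD) daily dose 70 (66) MME, 28.4%
# benzodiazepine co-prescription, ~3.06 visits/patient, 11.4% oral-fluid
# specimens, 12.2% THC-positive tests, a 4.4% low-risk inconsistency rate and
# category odds ratios of about 2 for the escalated bands.

#' Parameters of a synthetic cohort
#'
#' Builds and validates the parameter set consumed by [generate_cohort()]
#' and [simulate_visits()].
#'
#' @param n_patients Number of patients.
#' @param visits_mean,visits_dispersion Mean and size (dispersion) of the
#'   negative-binomial visit count, truncated to at least one visit.
#' @param age_mean,age_sd,age_min Age distribution (normal, rounded, floored
#'   at `age_min` years).
#' @param mme_mean,mme_sd Daily-dose distribution (log-normal with this mean
#'   and SD on the MME/day scale).
#' @param benzodiazepine_prevalence Probability of a benzodiazepine
#'   co-prescription.
#' @param history_prevalence Probability the persistent
#'   history-of-inconsistency flag is already set at entry.
#' @param baseline_rate Inconsistency probability of a low-risk tested visit
#'   for a patient with zero random intercept; its logit is the model
#'   intercept.
#' @param category_effects Named log-odds offsets per risk category
#'   (reference low = 0).
#' @param patient_random_intercept_sd SD of the patient random intercept on
#'   the log-odds scale (0 collapses the model to independent Bernoulli
#'   outcomes).
#' @param oral_fluid_rate Probability a performed test is on oral fluid
#'   rather than urine (no effect on classification).
#' @param thc_rate Probability a performed test is THC-positive,
#'   independent of everything else (THC never affects the ruling).
#' @param reason_weights Mixture weights over the three inconsistency
#'   mechanisms used to synthesise inconsistent panels; the default is the
#'   pooled reason distribution of the reference evaluation (31:36:9).
#' @param drug_pool Opioids (linear conversion factors) sampled for the
#'   single-drug regimens the generator prescribes.
#' @param seed Master seed; all randomness flows from it through named
#'   substreams (`cohort`, `visits`).
#' @return A validated `udt_cohort_params` list.
#' @export
#' @examples
#' cohort_params(n_patients = 50, seed = 7)$baseline_rate
cohort_params <- function(n_patients = 320,
                          visits_mean = 979 / 320,
                          visits_dispersion = 2,
                          age_mean = 57, age_sd = 12, age_min = 18,
                          mme_mean = 70, mme_sd = 66,
                          benzodiazepine_prevalence = 0.284,
                          history_prevalence = 0,
                          baseline_rate = 0.044,
                          category_effects = c(low = 0,
                                               moderate = log(2.1),
                                               high = log(2.0),
                                               high_plus = log(2.0)),
                          patient_random_intercept_sd = 0.5,
                          oral_fluid_rate = 0.114,
                          thc_rate = 0.122,
                          reason_weights = c(
                            negative_for_prescribed_opioid = 31 / 76,
                            positive_for_unprescribed_opioid = 36 / 76,
                            positive_for_illicit_drug = 9 / 76),
                          drug_pool = c("morphine", "oxycodone",
                                        "hydrocodone", "hydromorphone"),
                          seed = 1L) {
  p <- list(n_patients = as.integer(n_patients), visits_mean = visits_mean,
            visits_dispersion = visits_dispersion, age_mean = age_mean,
            age_sd = age_sd, age_min = age_min, mme_mean = mme_mean,
            mme_sd = mme_sd,
            benzodiazepine_prevalence = benzodiazepine_prevalence,
            history_prevalence = history_prevalence,
            baseline_rate = baseline_rate,
            category_effects = category_effects,
            patient_random_intercept_sd = patient_random_intercept_sd,
            oral_fluid_rate = oral_fluid_rate, thc_rate = thc_rate,
            reason_weights = reason_weights, drug_pool = drug_pool,
            seed = as.integer(seed))
  probs <- c(p$benzodiazepine_prevalence, p$history_prevalence,
             p$oral_fluid_rate, p$thc_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("prevalences and rates must lie in [0, 1]")
  }
  if (p$n_patients < 1) abort("n_patients must be at least 1")
  if (p$baseline_rate <= 0 || p$baseline_rate >= 1) {
    abort("baseline_rate must lie in (0, 1)")
  }
  if (p$patient_random_intercept_sd < 0 || p$age_sd < 0 || p$mme_sd < 0) {
    abort("standard deviations must be non-negative")
  }
  if (p$visits_mean <= 0 || p$visits_dispersion <= 0) {
    abort("visit distribution parameters must be positive")
  }
  missing <- setdiff(risk_levels(), names(p$category_effects))
  if (length(missing) > 0) {
    abort(paste0("category_effects missing: ", paste(missing, collapse = ", ")))
  }
  if (abs(sum(p$reason_weights) - 1) > 1e-8 || any(p$reason_weights < 0)) {
    abort("reason_weights must be non-negative and sum to 1")
  }
  missing_r <- setdiff(REASON_LEVELS, names(p$reason_weights))
  if (length(missing_r) > 0) {
    abort(paste0("reason_weights missing: ", paste(missing_r, collapse = ", ")))
  }
  structure(p, class = "udt_cohort_params")
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` patients with ages, a single-opioid regimen hitting a
#' log-normal daily MME target, benzodiazepine and history flags, a
#' patient-level random intercept, and a truncated negative-binomial number
#' of visits. Bit-identical on re-run with the same parameters.
#'
#' @param params A `udt_cohort_params`.
#' @param table A `udt_conversion_table` used to back-compute doses and to
#'   verify the realised daily MME.
#' @return A tibble with one row per patient: `patient_id`, `age_years`,
#'   `drug`, `dose_amount`, `frequency_per_day`, `route`, `mme_per_day`,
#'   `benzodiazepine`, `history_flag`, `random_intercept`, `n_visits`.
#' @export
#' @examples
#' generate_cohort(cohort_params(n_patients = 5, seed = 1))
generate_cohort <- function(params = cohort_params(),
                            table = default_conversion_table()) {
  stopifnot(inherits(params, "udt_cohort_params"))
  bad <- setdiff(params$drug_pool, names(table$linear))
  if (length(bad) > 0) {
    abort(paste0("drug_pool entries must have linear conversion factors: ",
                 paste(bad, collapse = ", ")))
  }
  withr::with_seed(substream_seed(params$seed, "cohort"), {
    n <- params$n_patients
    age <- pmax(params$age_min, round(rnorm(n, params$age_mean, params$age_sd)))
    # log-normal parameterised by its mean/SD on the natural scale
    cv2 <- (params$mme_sd / params$mme_mean)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(params$mme_mean) - sdlog^2 / 2
    mme <- rlnorm(n, meanlog, sdlog)
    drug <- sample(params$drug_pool, n, replace = TRUE)
    freq <- 2
    dose <- mme / (freq * unname(unlist(table$linear)[match(drug, names(table$linear))]))
    benzo <- runif(n) < params$benzodiazepine_prevalence
    hist0 <- runif(n) < params$history_prevalence
    b <- rnorm(n, 0, params$patient_random_intercept_sd)
    visits <- rnbinom(n, size = params$visits_dispersion, mu = params$visits_mean)
    while (any(visits < 1)) {
      k <- visits < 1
      visits[k] <- rnbinom(sum(k), size = params$visits_dispersion,
                           mu = params$visits_mean)
    }
    cohort <- tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      age_years = as.integer(age),
      drug = drug, dose_amount = dose, frequency_per_day = freq,
      route = "oral",
      benzodiazepine = benzo, history_flag = hist0,
      random_intercept = b, n_visits = as.integer(visits))
    realised <- compute_daily_mme(cohort_prescriptions(cohort), table)
    left_join(cohort, realised, by = "patient_id") %>%
      select("patient_id", "age_years", "drug", "dose_amount",
             "frequency_per_day", "route", "mme_per_day",
             "benzodiazepine", "history_flag", "random_intercept", "n_visits")
  })
}

#' Prescription table of a synthetic cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @return Tibble in the standard prescription schema (`patient_id`, `drug`,
#'   `dose_amount`, `frequency_per_day`, `route`).
#' @export
cohort_prescriptions <- function(cohort) {
  select(as_tibble(cohort), "patient_id", "drug", "dose_amount",
         "frequency_per_day", "route")
}

#' Simulate visit histories under the testing policy
#'
#' Walks every patient through their visits. At each visit the current risk
#' category is assigned from the patient's state (the history flag evolves),
#' a test is recommended with the category's probability, and — when tested —
#' the true compliance outcome is drawn from the random-intercept logistic
#' model, a matching analyte panel is synthesised (the full expected set for
#' a consistent test; a perturbed panel realising a sampled inconsistency
#' mechanism otherwise), the verdict is computed by the toxicology
#' classifier from that panel, and the history flag is updated before the
#' next visit. THC is added to panels at `thc_rate` independently of the
#' outcome; specimens are urine or oral fluid at `oral_fluid_rate`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param params The `udt_cohort_params` used to generate the cohort.
#' @param policy A `udt_policy`.
#' @param substances A `udt_substances`.
#' @return A tibble with one row per visit: `patient_id`, `visit_index`,
#'   `mme_per_day`, `base_category`, `category`, `test_probability`,
#'   `recommended`, `tested`, `specimen`, `panel` (list-column of detected
#'   analytes), `status`, `reasons` (list-column), `primary_reason`,
#'   `thc_positive`.
#' @export
#' @examples
#' prm <- cohort_params(n_patients = 20, seed = 42)
#' visits <- simulate_visits(generate_cohort(prm), prm)
simulate_visits <- function(cohort, params = cohort_params(),
                            policy = default_policy(),
                            substances = default_substances()) {
  stopifnot(inherits(params, "udt_cohort_params"))
  cohort <- as_tibble(cohort)
  stop_if_missing_cols(cohort, c("patient_id", "age_years", "drug",
                                 "mme_per_day", "benzodiazepine",
                                 "history_flag", "random_intercept",
                                 "n_visits"), "cohort table")
  n <- nrow(cohort)
  base <- base_category(cohort$mme_per_day, policy)
  static_factor <- (cohort$age_years < 45) | cohort$benzodiazepine
  hist_flag <- cohort$history_flag
  expected_by_drug <- lapply(
    setNames(nm = unique(cohort$drug)),
    function(d) expected_analytes(d, substances))
  # opioid parents available to contaminate a panel with, per prescribed drug
  perturb_pool <- intersect(names(substances$metabolites),
                            c("morphine", "oxycodone", "hydrocodone",
                              "fentanyl", "methadone"))
  candidates_by_drug <- lapply(expected_by_drug,
                               function(e) setdiff(perturb_pool, e))
  effects <- params$category_effects[risk_levels()]
  baseline_logit <- qlogis(params$baseline_rate)
  reason_names <- names(params$reason_weights)

  waves <- withr::with_seed(substream_seed(params$seed, "visits"), {
    lapply(seq_len(max(cohort$n_visits)), function(j) {
      act <- which(cohort$n_visits >= j)
      m <- length(act)
      cat_j <- escalate(base[act], static_factor[act] | hist_flag[act])
      p <- unname(policy$test_probabilities[as.character(cat_j)])
      rec <- runif(m) < p
      tested <- rec
      eta <- baseline_logit + unname(effects[as.integer(cat_j)]) +
        cohort$random_intercept[act]
      inc <- rep(NA, m)
      inc[tested] <- runif(sum(tested)) < plogis(eta[tested])
      reason <- rep(NA_character_, m)
      k_inc <- which(tested & !is.na(inc) & inc)
      if (length(k_inc) > 0) {
        reason[k_inc] <- sample(reason_names, length(k_inc), replace = TRUE,
                                prob = params$reason_weights)
      }
      thc <- rep(NA, m)
      thc[tested] <- runif(sum(tested)) < params$thc_rate
      specimen <- rep(NA_character_, m)
      specimen[tested] <- sample(c("urine", "oral_fluid"), sum(tested),
                                 replace = TRUE,
                                 prob = c(1 - params$oral_fluid_rate,
                                          params$oral_fluid_rate))
      panel <- vector("list", m)
      status <- rep(NA_character_, m)
      reasons <- vector("list", m)
      primary <- rep(NA_character_, m)
      for (i in which(tested)) {
        drug_i <- cohort$drug[act[i]]
        expected <- expected_by_drug[[drug_i]]
        pnl <- switch(
          ifelse(is.na(reason[i]), "consistent", reason[i]),
          consistent = expected,
          negative_for_prescribed_opioid = character(0),
          positive_for_unprescribed_opioid = {
            cand <- candidates_by_drug[[drug_i]]
            c(expected, cand[sample.int(length(cand), 1)])
          },
          positive_for_illicit_drug = {
            c(expected, substances$illicit[sample.int(length(substances$illicit), 1)])
          })
        if (thc[i]) pnl <- c(pnl, substances$excluded[1])
        verdict <- classify_core(pnl, expected, substances)
        panel[[i]] <- pnl
        status[i] <- verdict$status
        reasons[[i]] <- verdict$reasons
        primary[i] <- verdict$primary_reason
      }
      hist_flag[act] <<- update_history(hist_flag[act], status)
      tibble(patient_id = cohort$patient_id[act], visit_index = j,
             mme_per_day = cohort$mme_per_day[act],
             base_category = base[act], category = cat_j,
             test_probability = p, recommended = rec, tested = tested,
             specimen = specimen, panel = panel, status = status,
             reasons = reasons, primary_reason = primary,
             thc_positive = thc)
    })
  })
  bind_rows(waves) %>% arrange(.data$patient_id, .data$visit_index)
}

#' Generate a cohort and simulate its visits in one call
#'
#' @inheritParams simulate_visits
#' @param table A `udt_conversion_table`.
#' @return A list with elements `cohort`, `prescriptions`, `visits`.
#' @export
simulate_cohort <- function(params = cohort_params(),
                            policy = default_policy(),
                            substances = default_substances(),
                            table = default_conversion_table()) {
  cohort <- generate_cohort(params, table)
  list(cohort = cohort,
       prescriptions = cohort_prescriptions(cohort),
       visits = simulate_visits(cohort, params, policy, substances))
}
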