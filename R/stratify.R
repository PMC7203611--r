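# Risk stratification and the probabilistic test recommendation.

#' Load or build a testing policy
#'
#' A policy holds the two MME/day cutpoints that define the dose-based risk
#' bands and the per-category probabilities at which a test is recommended.
#' Defaults: cutpoints 40 and 100 MME/day; probabilities 0.25 (low),
#' 0.33 (moderate), 0.50 (high), 0.60 (high_plus).
#'
#' @param path Path to a YAML policy file; defaults to the shipped policy.
#' @return A validated `udt_policy` (list with `dose_cutpoints`,
#'   `test_probabilities`).
#' @export
#' @examples
#' default_policy()$test_probabilities
load_policy <- function(path = udt_extdata("policy.yaml")) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("dose_cutpoints", "test_probabilities"))
  if (length(unknown) > 0) {
    abort(paste0("unknown policy section(s): ", paste(unknown, collapse = ", ")))
  }
  policy(dose_cutpoints = as.numeric(raw$dose_cutpoints),
         test_probabilities = vapply(raw$test_probabilities, as.numeric, numeric(1)))
}

#' @rdname load_policy
#' @param dose_cutpoints Two strictly increasing positive MME/day values.
#' @param test_probabilities Named numeric vector over [risk_levels()], each
#'   in (0, 1].
#' @export
policy <- function(dose_cutpoints = c(40, 100),
                   test_probabilities = c(low = 0.25, moderate = 0.33,
                                          high = 0.50, high_plus = 0.60)) {
  if (length(dose_cutpoints) != 2 || any(!is.finite(dose_cutpoints)) ||
      any(dose_cutpoints <= 0) || diff(dose_cutpoints) <= 0) {
    abort("dose_cutpoints must be two strictly increasing positive values")
  }
  missing <- setdiff(risk_levels(), names(test_probabilities))
  if (length(missing) > 0) {
    abort(paste0("test_probabilities missing categories: ",
                 paste(missing, collapse = ", ")))
  }
  p <- test_probabilities[risk_levels()]
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("test_probabilities must lie in (0, 1]")
  }
  structure(list(dose_cutpoints = unname(dose_cutpoints),
                 test_probabilities = p),
            class = "udt_policy")
}

#' @rdname load_policy
#' @export
default_policy <- function() policy()

#' Dose-based risk band
#'
#' Maps a daily MME dose to the base risk category: `[0, c1)` is low,
#' `[c1, c2]` moderate, `(c2, Inf)` high (defaults c1 = 40, c2 = 100). The
#' base band never exceeds `high`; `high_plus` is reachable only by
#' escalation ([escalate()]).
#'
#' @param mme Numeric vector of daily MME doses (non-negative).
#' @param policy A `udt_policy`.
#' @return Ordered risk-category factor, same length as `mme`.
#' @export
#' @examples
#' base_category(c(0, 39.99, 40, 100, 100.01))
base_category <- function(mme, policy = default_policy()) {
  if (any(!is.finite(mme)) || any(mme < 0)) {
    abort("mme must be non-negative and finite")
  }
  cp <- policy$dose_cutpoints
  out <- ifelse(mme < cp[1], "low", ifelse(mme <= cp[2], "moderate", "high"))
  as_risk_category(out)
}

#' Escalate a risk category by one level
#'
#' When one or more clinical risk factors are present (age under 45 years,
#' concomitant benzodiazepine use, or a history of inconsistent toxicology),
#' the category is raised by exactly one level — a single step regardless of
#' how many factors are present — saturating at `high_plus`. The base
#' category must come from [base_category()] and so is never `high_plus`.
#'
#' @param category Risk-category vector among low/moderate/high.
#' @param any_factor Logical vector: is at least one risk factor present?
#' @return Ordered risk-category factor.
#' @export
#' @examples
#' escalate(as_risk_category(c("low", "high")), c(FALSE, TRUE))
escalate <- function(category, any_factor) {
  category <- as_risk_category(category)
  if (any(is.na(category)) || any(is.na(any_factor))) {
    abort("category and any_factor must be known (no NA)")
  }
  if (any(category == "high_plus")) {
    abort("base category 'high_plus' is not escalatable (contract violation)")
  }
  idx <- as.integer(category) + as.integer(any_factor)
  as_risk_category(risk_levels()[pmin(idx, 4L)])
}

# Risk factors from a patient table; unknown values are rejected, never imputed.
derive_risk_factors <- function(patients) {
  stop_if_missing_cols(patients, c("age_years", "benzodiazepine", "history_flag"),
                       "patient table")
  if (any(!complete.cases(patients[, c("age_years", "benzodiazepine", "history_flag")]))) {
    abort("risk-factor fields (age_years, benzodiazepine, history_flag) must not be missing")
  }
  if (any(patients$age_years < 0)) abort("age_years must be non-negative")
  tibble(
    age_under_45 = patients$age_years < 45,
    concomitant_benzodiazepine = as.logical(patients$benzodiazepine),
    history_inconsistent = as.logical(patients$history_flag)
  )
}

#' Assign risk categories to patients
#'
#' Composes the full stratification rule: daily MME from the active
#' prescriptions ([compute_daily_mme()]), the dose band
#' ([base_category()]), and one-step escalation ([escalate()]) when any of
#' age < 45 years, benzodiazepine co-prescription, or the persistent
#' history-of-inconsistency flag is present. Patients without prescriptions
#' in `rx` are assigned 0 MME/day.
#'
#' @param patients Tibble with columns `patient_id`, `age_years`,
#'   `benzodiazepine` (logical), `history_flag` (logical).
#' @param rx Prescription table with `patient_id` (see [daily_dose()]).
#' @param table A `udt_conversion_table`.
#' @param policy A `udt_policy`.
#' @return `patients` with columns `mme_per_day`, `base_category`, `category`
#'   appended.
#' @export
assign_categories <- function(patients, rx,
                              table = default_conversion_table(),
                              policy = default_policy()) {
  patients <- as_tibble(patients)
  stop_if_missing_cols(patients, "patient_id", "patient table")
  factors <- derive_risk_factors(patients)
  mme <- compute_daily_mme(as_tibble(rx), table)
  out <- left_join(patients, mme, by = "patient_id") %>%
    mutate(mme_per_day = ifelse(is.na(.data$mme_per_day), 0, .data$mme_per_day))
  any_factor <- factors$age_under_45 | factors$concomitant_benzodiazepine |
    factors$history_inconsistent
  out$base_category <- base_category(out$mme_per_day, policy)
  out$category <- escalate(out$base_category, any_factor)
  out
}

#' Draw test recommendations at category-specific frequencies
#'
#' For each row, recommends a drug test with the probability configured for
#' its risk category — a Bernoulli draw per visit, not a fixed schedule. With
#' the same seed, policy and categories the recommendation sequence is
#' identical on re-run.
#'
#' @param data Tibble with a `category` column (per-visit rows).
#' @param policy A `udt_policy`.
#' @param seed Optional integer seed; when supplied, draws come from a local
#'   RNG state and the caller's RNG is untouched.
#' @return `data` with `test_probability` and `recommended` columns appended.
#' @export
#' @examples
#' visits <- tibble::tibble(category = as_risk_category(rep("low", 5)))
#' recommend_tests(visits, seed = 1)
recommend_tests <- function(data, policy = default_policy(), seed = NULL) {
  data <- as_tibble(data)
  stop_if_missing_cols(data, "category", "visit table")
  category <- as_risk_category(data$category)
  if (any(is.na(category))) abort("category must be known for every row")
  p <- unname(policy$test_probabilities[as.character(category)])
  draw <- function() runif(nrow(data)) < p
  rec <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  mutate(data, test_probability = p, recommended = rec)
}

#' Update the persistent history-of-inconsistency flag
#'
#' The flag is monotone: once a patient has produced an inconsistent test it
#' remains set for the duration of treatment. Untested visits (`NA` status)
#' leave the flag unchanged.
#'
#' @param history_flag Logical vector of current flags.
#' @param status Character vector of verdict statuses (`"consistent"`,
#'   `"inconsistent"`, or `NA` for untested).
#' @return Updated logical vector.
#' @export
#' @examples
#' update_history(c(FALSE, FALSE, TRUE), c("inconsistent", "consistent", "consistent"))
update_history <- function(history_flag, status) {
  history_flag | (!is.na(status) & status == "inconsistent")
}
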