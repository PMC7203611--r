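# Independent brute-force oracles and small fixtures used across tests.
# These are deliberately coded differently from the package internals.

# Literal transcription of the stratification rule: dose bands [0,40) /
# [40,100] / (100,Inf), then one single-step escalation when any factor holds.
oracle_base_category <- function(mme) {
  if (mme < 40) "low" else if (mme <= 100) "moderate" else "high"
}

oracle_assign_category <- function(mme, age_under_45, benzo, history) {
  lv <- c("low", "moderate", "high", "high_plus")
  base <- oracle_base_category(mme)
  if (age_under_45 || benzo || history) lv[match(base, lv) + 1] else base
}

# Brute-force set computation of the consistency ruling.
oracle_classify <- function(detected, expected, opioids, illicit, excluded) {
  det <- detected[!detected %in% excluded]
  reasons <- character(0)
  if (length(intersect(det, illicit)) > 0) {
    reasons <- c(reasons, "positive_for_illicit_drug")
  }
  if (length(setdiff(intersect(det, opioids), expected)) > 0) {
    reasons <- c(reasons, "positive_for_unprescribed_opioid")
  }
  if (length(intersect(det, expected)) == 0) {
    reasons <- c(reasons, "negative_for_prescribed_opioid")
  }
  list(status = if (length(reasons) == 0) "consistent" else "inconsistent",
       reasons = sort(reasons))
}

# Central 99% interval of the exact binomial, as a proportion.
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p) / n

expect_within_binom99 <- function(x, n, p) {
  iv <- binom99(n, p)
  expect_gte(x, iv[1])
  expect_lte(x, iv[2])
}

# A compact 10-analyte dictionary for exhaustive panel sweeps:
# two prescribable opioids (one with two metabolites), one unprescribed
# opioid, two illicit markers, THC, and two benzodiazepines.
sweep_substances <- function() {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(list(
    opioids = list("oxycodone", "oxymorphone", "noroxycodone", "morphine",
                   "hydrocodone"),
    illicit = list("cocaine", "six_mam"),
    excluded = list("thc"),
    benzodiazepines = list("alprazolam", "diazepam"),
    metabolites = list(oxycodone = list("oxycodone", "oxymorphone", "noroxycodone"),
                      morphine = list("morphine"))), path)
  load_substances(path)
}

# All subsets of a character vector (list of character vectors).
all_subsets <- function(x) {
  n <- length(x)
  lapply(seq_len(2^n) - 1, function(mask) x[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
}
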