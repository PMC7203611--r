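# Evaluation surface: category summary tables, crude odds ratios,
# printed-count study fixture, category collapsing.

category_stats_shell <- function(levels = risk_levels()) {
  tibble(category = factor(c(levels, "overall"),
                           levels = c(levels, "overall")),
         n_tests = 0L, n_consistent = 0L, n_inconsistent = 0L,
         pct_inconsistent = NA_real_,
         n_negative_for_prescribed_opioid = 0L,
         n_positive_for_unprescribed_opioid = 0L,
         n_positive_for_illicit_drug = 0L)
}

finalize_category_stats <- function(stats) {
  stats$pct_inconsistent <- ifelse(
    stats$n_tests > 0,
    round_half_up(100 * stats$n_inconsistent / stats$n_tests, 1),
    NA_real_)
  class(stats) <- c("udt_category_stats", class(stats))
  stats
}

#' Summarise tested visits per risk category
#'
#' Per-category counts of performed tests, consistent and inconsistent
#' results, primary-reason counts, and the inconsistency percentage (half-up,
#' one decimal), plus an `overall` row. Untested visits are excluded from
#' every denominator.
#'
#' @param visits Visit table as produced by [simulate_visits()] or assembled
#'   from [classify_panels()] + [recommend_tests()] output; needs columns
#'   `category`, `tested`, `status` and (optionally) `primary_reason`.
#' @return A `udt_category_stats` tibble (one row per category + overall).
#' @export
#' @examples
#' prm <- cohort_params(n_patients = 40, seed = 3)
#' summarize_visits(simulate_visits(generate_cohort(prm), prm))
summarize_visits <- function(visits) {
  visits <- as_tibble(visits)
  stop_if_missing_cols(visits, c("category", "tested", "status"), "visit table")
  bad <- visits$tested & is.na(visits$status)
  if (any(bad)) {
    where <- utils::head(which(bad), 3)
    abort(paste0("tested visit(s) lacking a verdict at row(s): ",
                 paste(where, collapse = ", ")))
  }
  tested <- filter(visits, .data$tested)
  if (!"primary_reason" %in% names(tested)) tested$primary_reason <- NA_character_
  cat_levels <- if (is.factor(visits$category)) {
    setdiff(levels(visits$category), "overall")
  } else {
    risk_levels()
  }
  bad_cat <- setdiff(unique(as.character(tested$category)), cat_levels)
  if (length(bad_cat) > 0) {
    abort(paste0("unknown category: ", paste(bad_cat, collapse = ", ")))
  }
  cat <- factor(as.character(tested$category), levels = cat_levels)
  per <- tibble(category = cat,
                inconsistent = tested$status == "inconsistent",
                primary_reason = tested$primary_reason) %>%
    group_by(.data$category) %>%
    summarise(
      n_tests = dplyr::n(),
      n_inconsistent = sum(.data$inconsistent),
      n_negative_for_prescribed_opioid =
        sum(.data$primary_reason %in% "negative_for_prescribed_opioid"),
      n_positive_for_unprescribed_opioid =
        sum(.data$primary_reason %in% "positive_for_unprescribed_opioid"),
      n_positive_for_illicit_drug =
        sum(.data$primary_reason %in% "positive_for_illicit_drug"),
      .groups = "drop")
  stats <- category_stats_shell(cat_levels)
  idx <- match(as.character(per$category), as.character(stats$category))
  for (col in setdiff(names(per), "category")) {
    stats[[col]][idx] <- as.integer(per[[col]])
  }
  count_cols <- c("n_tests", "n_inconsistent",
                  "n_negative_for_prescribed_opioid",
                  "n_positive_for_unprescribed_opioid",
                  "n_positive_for_illicit_drug")
  stats[stats$category == "overall", count_cols] <-
    as.list(vapply(stats[stats$category != "overall", count_cols],
                   sum, numeric(1)))
  stats$n_consistent <- stats$n_tests - stats$n_inconsistent
  finalize_category_stats(stats)
}

#' Build category statistics from printed counts
#'
#' For evaluations where only aggregated counts are available (no per-visit
#' records), computes the same `udt_category_stats` table as
#' [summarize_visits()] directly from per-category counts.
#'
#' @param counts Tibble with columns `category`, `n_tests`, `n_inconsistent`
#'   and optionally the three primary-reason count columns.
#' @return A `udt_category_stats` tibble.
#' @export
#' @examples
#' summarize_counts(udt_study_counts()$tests)
summarize_counts <- function(counts) {
  counts <- as_tibble(counts)
  stop_if_missing_cols(counts, c("category", "n_tests", "n_inconsistent"),
                       "count table")
  if (any(counts$n_inconsistent > counts$n_tests)) {
    abort("n_inconsistent cannot exceed n_tests")
  }
  stats <- category_stats_shell()
  idx <- match(as.character(counts$category), as.character(stats$category))
  if (any(is.na(idx))) abort("count table categories must be among risk_levels()")
  for (col in intersect(names(counts), names(stats))) {
    if (col != "category") stats[[col]][idx] <- as.integer(counts[[col]])
  }
  count_cols <- c("n_tests", "n_inconsistent",
                  "n_negative_for_prescribed_opioid",
                  "n_positive_for_unprescribed_opioid",
                  "n_positive_for_illicit_drug")
  stats[stats$category == "overall", count_cols] <-
    as.list(vapply(stats[stats$category != "overall", count_cols],
                   sum, numeric(1)))
  stats$n_consistent <- stats$n_tests - stats$n_inconsistent
  finalize_category_stats(stats)
}

#' Reason shares within the category table
#'
#' The primary-reason counts can be expressed against two denominators: the
#' inconsistent tests of the category, or all tests of the category. Both are
#' reported explicitly.
#'
#' @param stats A `udt_category_stats`.
#' @return Long tibble with `category`, `reason`, `n`, `pct_of_inconsistent`,
#'   `pct_of_tests`.
#' @export
reason_shares <- function(stats) {
  stopifnot(inherits(stats, "udt_category_stats"))
  long <- tidyr::pivot_longer(
    as_tibble(stats),
    cols = dplyr::starts_with("n_negative_for_") |
      dplyr::starts_with("n_positive_for_"),
    names_to = "reason", names_prefix = "n_", values_to = "n")
  long %>%
    mutate(
      pct_of_inconsistent = ifelse(.data$n_inconsistent > 0,
                                   round_half_up(100 * .data$n / .data$n_inconsistent, 1),
                                   NA_real_),
      pct_of_tests = ifelse(.data$n_tests > 0,
                            round_half_up(100 * .data$n / .data$n_tests, 1),
                            NA_real_)) %>%
    select("category", "reason", "n", "pct_of_inconsistent", "pct_of_tests")
}

#' Printed counts of the reference evaluation
#'
#' The aggregate counts of the 12-month retrospective evaluation of this
#' risk-stratified testing policy at a multi-site pain practice (320 COAT
#' patients, 979 performed tests). Patient-level records of that cohort are
#' not published; these aggregate counts are the package's built-in fixture
#' for exact reproduction of the reported summary statistics.
#'
#' @return A list of three tibbles:
#' * `tests`: per-category tests, inconsistent results and primary-reason
#'   counts;
#' * `cohort`: patient- and test-level totals (patients with at least one
#'   inconsistent result, specimen split, THC-positive tests and patients);
#' * `uptake`: tool-use and adherence counts (first-visit use, first-visit
#'   recommendations followed, "Yes" recommendations followed over the whole
#'   period, tests performed against a "No").
#' @export
#' @examples
#' udt_study_counts()$tests
udt_study_counts <- function() {
  list(
    tests = tibble(
      category = risk_levels(),
      n_tests = c(160L, 349L, 338L, 132L),
      n_inconsistent = c(7L, 32L, 28L, 9L),
      n_negative_for_prescribed_opioid = c(3L, 13L, 12L, 3L),
      n_positive_for_unprescribed_opioid = c(3L, 15L, 12L, 6L),
      n_positive_for_illicit_drug = c(1L, 4L, 4L, 0L)),
    cohort = tibble(
      n_patients = 320L,
      n_patients_inconsistent = 52L,
      n_tests = 979L,
      n_urine = 867L,
      n_oral_fluid = 112L,
      n_thc_positive_tests = 119L,
      n_thc_positive_patients = 25L),
    uptake = tibble(
      first_visit_tool_used = 318L,
      first_visit_total = 320L,
      first_visit_followed = 314L,
      yes_followed = 945L,
      yes_total = 964L,
      tests_against_no = 34L))
}

#' Headline metrics from aggregate study counts
#'
#' Computes the reported cohort-level percentages (half-up, one decimal)
#' from the aggregate counts: overall and per-patient inconsistency, specimen
#' split, THC positivity, and tool uptake/adherence.
#'
#' @param counts A list as returned by [udt_study_counts()].
#' @return Tibble with `metric`, `numerator`, `denominator`, `pct`.
#' @export
#' @examples
#' study_metrics()
study_metrics <- function(counts = udt_study_counts()) {
  ch <- counts$cohort
  up <- counts$uptake
  tests <- summarize_counts(counts$tests)
  overall <- tests[tests$category == "overall", ]
  out <- tibble(
    metric = c("tests_inconsistent", "patients_with_inconsistent_result",
               "urine_specimens", "oral_fluid_specimens",
               "thc_positive_tests", "thc_positive_patients",
               "first_visit_tool_used", "first_visit_recommendation_followed",
               "yes_recommendation_followed"),
    numerator = c(overall$n_inconsistent, ch$n_patients_inconsistent,
                  ch$n_urine, ch$n_oral_fluid, ch$n_thc_positive_tests,
                  ch$n_thc_positive_patients, up$first_visit_tool_used,
                  up$first_visit_followed, up$yes_followed),
    denominator = c(overall$n_tests, ch$n_patients, ch$n_tests, ch$n_tests,
                    ch$n_tests, ch$n_patients, up$first_visit_total,
                    up$first_visit_tool_used, up$yes_total))
  mutate(out, pct = round_half_up(100 * .data$numerator / .data$denominator, 1))
}

#' Crude odds ratio of a 2x2 table
#'
#' Cross-product odds ratio with a Woolf (log-normal) confidence interval.
#' When any cell is zero the Haldane–Anscombe correction (+0.5 to every
#' cell) is applied before both the estimate and the interval.
#'
#' Cell layout: `a`/`b` are outcome-positive/negative counts in the exposed
#' group, `c`/`d` in the reference group, so `OR = (a d) / (b c)`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `corrected`.
#' @export
#' @examples
#' crude_odds_ratio(32, 317, 7, 153) # moderate vs low, reference counts
crude_odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    abort("cell counts must be non-negative and finite")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  if (any(c(cells["a"] + cells["b"], cells["c"] + cells["d"],
            cells["a"] + cells["c"], cells["b"] + cells["d"]) <= 0)) {
    abort("odds ratio undefined: a table margin is zero")
  }
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  tibble(estimate = or,
         conf.low = exp(log(or) - z * se),
         conf.high = exp(log(or) + z * se),
         corrected = corrected)
}

#' Category-versus-reference crude odds ratios
#'
#' Builds the 2x2 table of each non-reference category against the reference
#' from a category statistics table and applies [crude_odds_ratio()]. These
#' are crude (unadjusted, visit-level) contrasts; they ignore within-patient
#' correlation, unlike [fit_gee_logistic()].
#'
#' @param stats A `udt_category_stats`.
#' @param reference Reference category (default `"low"`).
#' @param conf_level Confidence level.
#' @return Tibble with one row per contrast: `category`, `estimate`,
#'   `conf.low`, `conf.high`, `corrected`.
#' @export
#' @examples
#' category_odds_ratios(summarize_counts(udt_study_counts()$tests))
category_odds_ratios <- function(stats, reference = "low", conf_level = 0.95) {
  stopifnot(inherits(stats, "udt_category_stats"))
  levels <- setdiff(as.character(stats$category), c("overall", reference))
  ref <- stats[stats$category == reference, ]
  if (nrow(ref) != 1) abort("reference category not found")
  purrr::map_dfr(levels, function(lv) {
    row <- stats[stats$category == lv, ]
    or <- crude_odds_ratio(row$n_inconsistent, row$n_consistent,
                           ref$n_inconsistent, ref$n_consistent, conf_level)
    mutate(or, category = lv, .before = 1)
  })
}

#' Merge risk categories
#'
#' Relabels the `category` column of a visit table under a total merging
#' scheme (every one of the four categories must be mapped), e.g. collapsing
#' moderate/high/high_plus into a single high band for a two-category
#' analysis. Counts are conserved: only labels change.
#'
#' @param visits Visit table with a `category` column.
#' @param scheme Named character vector mapping each of [risk_levels()] to a
#'   merged label.
#' @return `visits` with `category` replaced by a factor over the merged
#'   labels (in first-appearance order of the original levels). For a
#'   `udt_category_stats` input, a re-aggregated statistics table whose
#'   counts are the sums of the merged categories' counts.
#' @export
#' @examples
#' scheme <- c(low = "low", moderate = "high", high = "high", high_plus = "high")
#' collapse_categories(summarize_counts(udt_study_counts()$tests), scheme)
collapse_categories <- function(visits, scheme) {
  missing <- setdiff(risk_levels(), names(scheme))
  if (length(missing) > 0) {
    abort(paste0("collapse scheme must cover every category; missing: ",
                 paste(missing, collapse = ", ")))
  }
  new_levels <- unique(unname(scheme[risk_levels()]))
  if (inherits(visits, "udt_category_stats")) {
    counts <- as_tibble(visits) %>%
      filter(.data$category != "overall") %>%
      mutate(category = factor(unname(scheme[as.character(.data$category)]),
                               levels = new_levels)) %>%
      group_by(.data$category) %>%
      summarise(dplyr::across(dplyr::starts_with("n_"), sum), .groups = "drop")
    stats <- category_stats_shell(new_levels)
    idx <- match(as.character(counts$category), as.character(stats$category))
    for (col in setdiff(names(counts), "category")) {
      stats[[col]][idx] <- counts[[col]]
    }
    count_cols <- c("n_tests", "n_inconsistent",
                    "n_negative_for_prescribed_opioid",
                    "n_positive_for_unprescribed_opioid",
                    "n_positive_for_illicit_drug")
    stats[stats$category == "overall", count_cols] <-
      as.list(vapply(stats[stats$category != "overall", count_cols],
                     sum, numeric(1)))
    stats$n_consistent <- stats$n_tests - stats$n_inconsistent
    return(finalize_category_stats(stats))
  }
  visits <- as_tibble(visits)
  stop_if_missing_cols(visits, "category", "visit table")
  old <- as.character(visits$category)
  bad <- setdiff(unique(old), risk_levels())
  if (length(bad) > 0) abort(paste0("unknown category: ", paste(bad, collapse = ", ")))
  mutate(visits, category = factor(unname(scheme[old]), levels = new_levels))
}

#' Print a category statistics table
#'
#' @param x A `udt_category_stats`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
print.udt_category_stats <- function(x, ...) {
  cat("Consistency of performed drug tests by risk category\n")
  NextMethod()
  invisible(x)
}
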