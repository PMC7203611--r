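# Equianalgesic (MME) conversion: configurable table, daily doses, totals.

#' Load an equianalgesic conversion table
#'
#' Reads a YAML conversion table with sections `linear:` (drug -> MME per
#' mg/day), `tiered:` (drug -> ordered list of `upper`/`factor` pairs applied
#' to the pooled daily dose of that drug; the last `upper` must be `.inf`) and
#' `rate:` (drug -> MME per mcg/hr for continuous transdermal formulations),
#' and validates it. The morphine factor must be exactly 1: MME is defined as
#' milligrams of oral morphine per day.
#'
#' @param path Path to a YAML file; defaults to the shipped table
#'   (CDC-2016-style factors, versioned under `inst/extdata/`).
#' @return A validated `udt_conversion_table` (list with elements `linear`,
#'   `tiered`, `rate`).
#' @seealso [compute_daily_mme()], [write_conversion_table()]
#' @export
#' @examples
#' tbl <- default_conversion_table()
#' tbl$linear[["oxycodone"]]
load_conversion_table <- function(path = udt_extdata("conversion_table.yaml")) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("linear", "tiered", "rate"))
  if (length(unknown) > 0) {
    abort(paste0("unknown conversion-table section(s): ",
                 paste(unknown, collapse = ", ")))
  }
  linear <- vapply(raw$linear %||% list(), as.numeric, numeric(1))
  rate <- vapply(raw$rate %||% list(), as.numeric, numeric(1))
  tiered <- lapply(raw$tiered %||% list(), function(tiers) {
    tibble(
      upper = vapply(tiers, function(t) as.numeric(t$upper), numeric(1)),
      factor = vapply(tiers, function(t) as.numeric(t$factor), numeric(1))
    )
  })
  table <- structure(list(linear = linear, tiered = tiered, rate = rate),
                     class = "udt_conversion_table")
  validate_conversion_table(table)
}

validate_conversion_table <- function(table) {
  all_drugs <- c(names(table$linear), names(table$tiered), names(table$rate))
  if (anyDuplicated(all_drugs)) {
    abort(paste0("drug listed in more than one conversion section: ",
                 paste(unique(all_drugs[duplicated(all_drugs)]), collapse = ", ")))
  }
  for (drug in names(table$linear)) {
    if (!is.finite(table$linear[[drug]]) || table$linear[[drug]] <= 0) {
      abort(paste0("conversion factor for '", drug, "' must be positive"))
    }
  }
  for (drug in names(table$rate)) {
    if (!is.finite(table$rate[[drug]]) || table$rate[[drug]] <= 0) {
      abort(paste0("rate conversion factor for '", drug, "' must be positive"))
    }
  }
  if ("morphine" %in% names(table$linear) && table$linear[["morphine"]] != 1) {
    abort("the morphine factor must be exactly 1 (definition of MME)")
  }
  for (drug in names(table$tiered)) {
    tiers <- table$tiered[[drug]]
    if (nrow(tiers) == 0 || any(!is.finite(tiers$factor)) || any(tiers$factor <= 0)) {
      abort(paste0("tier factors for '", drug, "' must be positive"))
    }
    if (any(diff(tiers$upper) <= 0)) {
      abort(paste0("tier bounds for '", drug, "' must be strictly increasing"))
    }
    if (is.finite(tiers$upper[nrow(tiers)])) {
      abort(paste0("last tier for '", drug, "' must be unbounded (.inf)"))
    }
  }
  table
}

#' Write a conversion table back to YAML
#'
#' Inverse of [load_conversion_table()]; `load(write(x))` reproduces `x`.
#'
#' @param table A `udt_conversion_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(table, path) {
  stopifnot(inherits(table, "udt_conversion_table"))
  out <- list(
    linear = as.list(table$linear),
    tiered = lapply(table$tiered, function(tiers) {
      lapply(seq_len(nrow(tiers)), function(i) {
        list(upper = tiers$upper[i], factor = tiers$factor[i])
      })
    }),
    rate = as.list(table$rate)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname load_conversion_table
#' @export
default_conversion_table <- function() {
  load_conversion_table(udt_extdata("conversion_table.yaml"))
}

validate_prescriptions <- function(rx) {
  stop_if_missing_cols(rx, c("drug", "dose_amount", "frequency_per_day", "route"),
                       "prescription table")
  if (nrow(rx) == 0) return(invisible(rx))
  if (any(!is.finite(rx$dose_amount)) || any(rx$dose_amount <= 0)) {
    abort("dose_amount must be positive")
  }
  if (any(!is.finite(rx$frequency_per_day)) || any(rx$frequency_per_day <= 0)) {
    abort("frequency_per_day must be positive")
  }
  bad_route <- setdiff(unique(rx$route), c("oral", "transdermal", "other"))
  if (length(bad_route) > 0) {
    abort(paste0("unknown route: ", paste(bad_route, collapse = ", ")))
  }
  invisible(rx)
}

#' Daily dose of each prescription
#'
#' Adds a `daily_dose` column: `dose_amount * frequency_per_day` in mg/day
#' for oral and other routes, and `dose_amount` unchanged (a continuous
#' mcg/hr rate) for transdermal formulations.
#'
#' @param rx Prescription table with columns `drug`, `dose_amount`,
#'   `frequency_per_day`, `route` (and optionally `patient_id`).
#' @return The input as a tibble with a `daily_dose` column appended.
#' @export
#' @examples
#' daily_dose(tibble::tibble(drug = "morphine", dose_amount = 15,
#'                           frequency_per_day = 2, route = "oral"))
daily_dose <- function(rx) {
  rx <- as_tibble(rx)
  validate_prescriptions(rx)
  mutate(rx, daily_dose = ifelse(.data$route == "transdermal",
                                 .data$dose_amount,
                                 .data$dose_amount * .data$frequency_per_day))
}

# Factor lookup for one drug at its pooled daily dose.
mme_factor <- function(drug, pooled_daily, table) {
  if (drug %in% names(table$linear)) return(table$linear[[drug]])
  if (drug %in% names(table$rate)) return(table$rate[[drug]])
  if (drug %in% names(table$tiered)) {
    tiers <- table$tiered[[drug]]
    return(tiers$factor[match(TRUE, pooled_daily <= tiers$upper)])
  }
  abort(paste0("drug not in conversion table: ", drug))
}

#' Total daily morphine milligram equivalents
#'
#' Sums `daily_dose * factor` over all prescriptions. Prescriptions of the
#' same drug are pooled before the factor lookup, so dose-dependent (tiered)
#' drugs such as methadone use the factor of the tier containing the pooled
#' daily dose; different drugs never pool. Transdermal rate drugs contribute
#' `rate_mcg_hr * rate_factor`.
#'
#' @param rx Prescription table (see [daily_dose()]); may have a `patient_id`
#'   column, in which case one total per patient is returned.
#' @param table A `udt_conversion_table`.
#' @return A tibble with columns `patient_id` (if present in `rx`) and
#'   `mme_per_day`. An empty prescription set yields 0 MME/day.
#' @export
#' @examples
#' rx <- tibble::tibble(drug = c("morphine", "oxycodone"),
#'                      dose_amount = c(15, 10),
#'                      frequency_per_day = c(2, 4), route = "oral")
#' compute_daily_mme(rx) # 30 * 1 + 40 * 1.5 = 90
compute_daily_mme <- function(rx, table = default_conversion_table()) {
  rx <- as_tibble(rx)
  has_id <- "patient_id" %in% names(rx)
  if (nrow(rx) == 0) {
    if (has_id) {
      return(tibble(patient_id = rx$patient_id[0], mme_per_day = numeric(0)))
    }
    return(tibble(mme_per_day = 0))
  }
  rx <- daily_dose(rx)
  known <- c(names(table$linear), names(table$tiered), names(table$rate))
  missing <- setdiff(unique(rx$drug), known)
  if (length(missing) > 0) {
    abort(paste0("drug not in conversion table: ",
                 paste(missing, collapse = ", ")))
  }
  if (!has_id) rx$patient_id <- "__single__"
  out <- rx %>%
    group_by(.data$patient_id, .data$drug) %>%
    summarise(pooled = sum(.data$daily_dose), .groups = "drop") %>%
    mutate(mme = purrr::map2_dbl(.data$pooled, .data$drug,
                                 function(d, drug) d * mme_factor(drug, d, table))) %>%
    group_by(.data$patient_id) %>%
    summarise(mme_per_day = sum(.data$mme), .groups = "drop")
  if (!has_id) out <- select(out, "mme_per_day")
  out
}
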