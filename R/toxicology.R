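# Toxicology-consistency classification of analyte panels.

REASON_LEVELS <- c("positive_for_illicit_drug",
                   "positive_for_unprescribed_opioid",
                   "negative_for_prescribed_opioid")

#' Load a substance dictionary and metabolite map
#'
#' The dictionary partitions analytes into four pairwise-disjoint classes —
#' `opioids`, `illicit`, `excluded` (THC by default) and `benzodiazepines` —
#' and maps each prescribable opioid to the set of analytes detectable after
#' its use (the parent plus its metabolites). Excluded analytes never
#' influence the consistency ruling; benzodiazepine findings are carried
#' through as annotations only.
#'
#' @param path Path to a YAML dictionary; defaults to the shipped one.
#' @return A validated `udt_substances` (list with `opioids`, `illicit`,
#'   `excluded`, `benzodiazepines`, `metabolites`).
#' @export
#' @examples
#' default_substances()$metabolites$oxycodone
load_substances <- function(path = udt_extdata("substances.yaml")) {
  raw <- yaml::read_yaml(path)
  need <- c("opioids", "illicit", "excluded", "benzodiazepines", "metabolites")
  unknown <- setdiff(names(raw), need)
  if (length(unknown) > 0) {
    abort(paste0("unknown substance section(s): ", paste(unknown, collapse = ", ")))
  }
  subst <- structure(
    list(opioids = as.character(raw$opioids %||% character(0)),
         illicit = as.character(raw$illicit %||% character(0)),
         excluded = as.character(raw$excluded %||% "thc"),
         benzodiazepines = as.character(raw$benzodiazepines %||% character(0)),
         metabolites = lapply(raw$metabolites %||% list(), as.character)),
    class = "udt_substances")
  validate_substances(subst)
}

validate_substances <- function(subst) {
  sets <- subst[c("opioids", "illicit", "excluded", "benzodiazepines")]
  pooled <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(pooled)) {
    abort(paste0("analyte classes must be pairwise disjoint; duplicated: ",
                 paste(unique(pooled[duplicated(pooled)]), collapse = ", ")))
  }
  for (parent in names(subst$metabolites)) {
    set <- subst$metabolites[[parent]]
    if (length(set) == 0 || !(parent %in% set)) {
      abort(paste0("metabolite set for '", parent,
                   "' must be non-empty and contain the parent analyte"))
    }
  }
  subst
}

#' @rdname load_substances
#' @export
default_substances <- function() load_substances(udt_extdata("substances.yaml"))

# All analytes the dictionary knows about.
all_analytes <- function(subst) {
  unique(c(subst$opioids, subst$illicit, subst$excluded, subst$benzodiazepines))
}

#' Analytes expected after use of the prescribed opioids
#'
#' Union of the metabolite sets (parent + metabolites) of the prescribed
#' drugs. A drug test is consistent only if at least one of these analytes
#' is detected.
#'
#' @param drugs Character vector of prescribed opioid identifiers.
#' @param substances A `udt_substances`.
#' @return Character vector of analyte identifiers (empty for no drugs).
#' @export
#' @examples
#' expected_analytes("oxycodone")
expected_analytes <- function(drugs, substances = default_substances()) {
  drugs <- unique(as.character(drugs))
  missing <- setdiff(drugs, names(substances$metabolites))
  if (length(missing) > 0) {
    abort(paste0("drug not in metabolite map: ", paste(missing, collapse = ", ")))
  }
  unique(unlist(substances$metabolites[drugs], use.names = FALSE)) %||% character(0)
}

# Fast core: no validation, assumes analytes known. Used row-wise by the
# simulator and by classify_panel().
classify_core <- function(detected, expected, subst) {
  detected <- setdiff(detected, subst$excluded)
  reasons <- character(0)
  det_opioids <- detected[detected %in% subst$opioids]
  if (any(!det_opioids %in% expected)) {
    reasons <- c(reasons, "positive_for_unprescribed_opioid")
  }
  if (any(detected %in% subst$illicit)) {
    reasons <- c(reasons, "positive_for_illicit_drug")
  }
  if (!any(detected %in% expected)) {
    reasons <- c(reasons, "negative_for_prescribed_opioid")
  }
  reasons <- REASON_LEVELS[REASON_LEVELS %in% reasons]
  list(status = if (length(reasons) == 0) "consistent" else "inconsistent",
       reasons = reasons,
       primary_reason = if (length(reasons) == 0) NA_character_ else reasons[1])
}

#' Classify one toxicology panel
#'
#' Rules a detected-analyte set consistent or inconsistent with the
#' prescribed opioids. After removing excluded analytes (THC by default), a
#' panel is *consistent* iff it is positive for at least one prescribed
#' opioid or metabolite and negative for unprescribed opioids and illicit
#' substances. Each violated condition fires a reason code; when several
#' fire, `primary_reason` follows the fixed priority illicit >
#' unprescribed opioid > negative for prescribed. Benzodiazepine findings do
#' not affect the status and are reported as an annotation.
#'
#' @param detected Character vector of detected analyte identifiers (may be
#'   empty). Analytes unknown to the dictionary are an error.
#' @param prescribed Character vector of prescribed opioid drugs (non-empty:
#'   chronic opioid therapy implies an active opioid).
#' @param substances A `udt_substances`.
#' @return A list with `status`, `reasons`, `primary_reason`, `thc_positive`,
#'   `benzodiazepine_positive`.
#' @export
#' @examples
#' classify_panel(c("oxycodone", "oxymorphone", "thc"), "oxycodone")$status
classify_panel <- function(detected, prescribed,
                           substances = default_substances()) {
  detected <- unique(as.character(detected))
  detected <- detected[!is.na(detected) & nzchar(detected)]
  unknown <- setdiff(detected, all_analytes(substances))
  if (length(unknown) > 0) {
    abort(paste0("unknown analyte(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(prescribed) == 0) {
    abort("prescriptions must be non-empty: consistency is defined against an active opioid")
  }
  expected <- expected_analytes(prescribed, substances)
  out <- classify_core(detected, expected, substances)
  out$thc_positive <- any(detected %in% substances$excluded)
  out$benzodiazepine_positive <- any(detected %in% substances$benzodiazepines)
  out
}

#' Classify a long-format panel table
#'
#' Vectorised interface over [classify_panel()]: one input row per detected
#' analyte (`analyte` `NA` or empty marks a visit with no detections), one
#' output row per visit.
#'
#' @param panels Tibble with columns `patient_id`, `visit_id`, `analyte` and
#'   optionally `specimen` (`"urine"` or `"oral_fluid"`).
#' @param rx Prescription table with `patient_id` and `drug`.
#' @param substances A `udt_substances`.
#' @return A tibble with one row per visit: `patient_id`, `visit_id`,
#'   `specimen` (if supplied), `status`, `reasons` (list-column),
#'   `primary_reason`, `thc_positive`, `benzodiazepine_positive`.
#' @export
classify_panels <- function(panels, rx, substances = default_substances()) {
  panels <- as_tibble(panels)
  stop_if_missing_cols(panels, c("patient_id", "visit_id", "analyte"), "panel table")
  rx <- as_tibble(rx)
  stop_if_missing_cols(rx, c("patient_id", "drug"), "prescription table")
  has_specimen <- "specimen" %in% names(panels)
  rx_by_patient <- split(rx$drug, rx$patient_id)
  grouped <- panels %>%
    group_by(.data$patient_id, .data$visit_id) %>%
    summarise(
      detected = list(unique(.data$analyte[!is.na(.data$analyte) & nzchar(.data$analyte)])),
      specimen = if (has_specimen) .data$specimen[1] else NA_character_,
      .groups = "drop")
  verdicts <- purrr::map2(grouped$detected, grouped$patient_id, function(det, pid) {
    prescribed <- rx_by_patient[[as.character(pid)]]
    if (is.null(prescribed)) {
      abort(paste0("no prescriptions on file for patient ", pid))
    }
    classify_panel(det, prescribed, substances)
  })
  out <- grouped %>%
    mutate(status = purrr::map_chr(verdicts, "status"),
           reasons = purrr::map(verdicts, "reasons"),
           primary_reason = purrr::map_chr(verdicts, "primary_reason"),
           thc_positive = purrr::map_lgl(verdicts, "thc_positive"),
           benzodiazepine_positive = purrr::map_lgl(verdicts, "benzodiazepine_positive")) %>%
    select(-"detected")
  if (!has_specimen) out <- select(out, -"specimen")
  out
}
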