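# Shared helpers: risk-category levels, rounding, seeded substreams.

#' Ordered risk-category levels
#'
#' The four risk categories used throughout the package, in increasing order
#' of presumed risk of a drug test inconsistent with the prescribed opioid
#' therapy.
#'
#' @return Character vector `c("low", "moderate", "high", "high_plus")`.
#' @export
risk_levels <- function() c("low", "moderate", "high", "high_plus")

#' Coerce to an ordered risk-category factor
#'
#' @param x Character or factor with values among [risk_levels()].
#' @return An ordered factor with levels low < moderate < high < high_plus.
#' @export
#' @examples
#' as_risk_category(c("high", "low"))
as_risk_category <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), risk_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown risk category: ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = risk_levels(), ordered = TRUE)
}

#' Round half away from zero
#'
#' Deterministic half-up rounding, the convention used for all reported
#' percentages (base [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(16.25, 1) # 16.3, where round() gives 16.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a reproducible 32-bit seed for a named substream of a master seed.
# Streams (cohort, visits, recommendations, ...) stay decoupled so that e.g.
# re-simulating outcomes does not disturb the cohort draw.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

# Path to a shipped default configuration file.
udt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "udtrisk")
  if (!nzchar(path)) abort(paste0("shipped configuration not found: ", file))
  path
}

stop_if_missing_cols <- function(data, cols, what) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(data)
}
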