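# ggplot2 displays for the result types.

#' Plot a category statistics table
#'
#' Bar chart of the inconsistency percentage per risk category, annotated
#' with the inconsistent/total counts. The `overall` row is drawn as a
#' dashed reference line.
#'
#' @param object A `udt_category_stats`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.udt_category_stats <- function(object, ...) {
  df <- as_tibble(object)
  overall <- df[df$category == "overall", ]
  df <- df[df$category != "overall" & df$n_tests > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$pct_inconsistent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_inconsistent, .data$n_tests)),
      vjust = -0.4, size = 3) +
    {if (nrow(overall) == 1 && !is.na(overall$pct_inconsistent))
      ggplot2::geom_hline(yintercept = overall$pct_inconsistent,
                          linetype = "dashed")} +
    ggplot2::labs(x = "risk category", y = "% inconsistent tests",
                  title = "Drug-test inconsistency by risk category") +
    ggplot2::theme_minimal()
}

#' Forest plot of a GEE fit
#'
#' Odds ratios with confidence intervals on a log scale, intercept omitted.
#'
#' @param object A `udt_gee`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.udt_gee <- function(object, ...) {
  df <- tidy(object, exponentiate = TRUE) %>%
    filter(.data$term != "(Intercept)", !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL,
                  title = "Cluster-robust odds ratios") +
    ggplot2::theme_minimal()
}

#' Recommendation-frequency calibration plot
#'
#' Compares the empirical share of recommended tests per category with the
#' policy's configured probabilities.
#'
#' @param visits Visit table with `category` and `recommended` columns.
#' @param policy The `udt_policy` in force.
#' @return A ggplot object.
#' @export
plot_calibration <- function(visits, policy = default_policy()) {
  visits <- as_tibble(visits)
  stop_if_missing_cols(visits, c("category", "recommended"), "visit table")
  emp <- visits %>%
    group_by(category = as_risk_category(.data$category)) %>%
    summarise(n = dplyr::n(), observed = mean(.data$recommended),
              .groups = "drop") %>%
    mutate(target = unname(policy$test_probabilities[as.character(.data$category)]))
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$target), colour = "red",
                        shape = 95, size = 10) +
    ggplot2::labs(x = "risk category",
                  y = "share of visits with test recommended",
                  title = "Randomizer calibration (red = configured probability)") +
    ggplot2::theme_minimal()
}
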