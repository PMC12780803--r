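#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot symbol prevalence by category and arm
#'
#' Dot plot of the percentage of products that would display the 'high in'
#' symbol in each TRA subcategory, CAP versus non-CAP, with the overall row
#' emphasised.
#'
#' @param object A [summarize_supply()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot supply_summary
#' @export
autoplot.supply_summary <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displays_pct,
                                   y = stats::reorder(.data$stratum, .data$displays_pct),
                                   colour = .data$arm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Products displaying 'high in' symbol (%)", y = NULL,
                  colour = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot the threshold-count distribution by arm
#'
#' Stacked proportions of products exempt or meeting 0-3 nutrient
#' thresholds, for the CAP and non-CAP arms overall.
#'
#' @param summary A [summarize_supply()] result.
#' @return A ggplot object.
#' @export
plot_threshold_counts <- function(summary) {
  df <- table_threshold_counts(summary)
  df <- df[df$stratum == "Overall", ] |>
    tidyr::pivot_longer(dplyr::ends_with("_pct"),
                        names_to = "bucket", values_to = "pct") |>
    dplyr::mutate(bucket = factor(
      sub("_pct$", "", sub("^n_", "", .data$bucket)),
      levels = c("exempt", "zero", "one", "two", "three"),
      labels = c("exempt", "0", "1", "2", "3")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$pct,
                                   fill = .data$bucket)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Products (%)",
                  fill = "Thresholds met") +
    ggplot2::theme_minimal()
}

#' Plot per-nutrient 'high in' prevalence by arm
#'
#' @param summary A [summarize_supply()] result.
#' @return A ggplot object.
#' @export
plot_nutrient_prevalence <- function(summary) {
  df <- table_nutrients(summary)
  df <- df[df$stratum == "Overall", ] |>
    tidyr::pivot_longer(dplyr::ends_with("_pct"),
                        names_to = "nutrient", values_to = "pct") |>
    dplyr::mutate(nutrient = sub("_pct$", "", sub("^n_high_", "", .data$nutrient)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nutrient, y = .data$pct,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Products 'high in' nutrient (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
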