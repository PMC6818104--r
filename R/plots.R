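#' Plot the COMCAT distribution of a processed dataset
#'
#' Bar chart of the fraction of deaths assigned to each COMCAT (the
#' derived `"multiple"` category included), in canonical category order.
#'
#' @param object A `va_results` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot va_results
#' @export
autoplot.va_results <- function(object, ...) {
  fr <- category_fractions(object, "comcat")
  fr$category <- factor(fr$category,
                        levels = c(comcat_categories(), "multiple"))
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "share of deaths",
                  title = "Circumstances of mortality categories") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot COMCATs ranked within each broad cause group
#'
#' Faceted bar chart mirroring the within-cause COMCAT rankings: one panel
#' per broad cause-of-death group, COMCAT proportions in ranked order.
#'
#' @param ranking Output of [comcat_by_cause_ranking()].
#' @return A ggplot object.
#' @export
plot_comcat_by_cause <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$comcat, .data$rank),
                               y = .data$proportion)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(ggplot2::vars(.data$broad_cause), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "share within cause group",
                  title = "COMCATs ranked within broad causes of death") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot stratum-specific or standardised mortality rates
#'
#' For stratified rates (output of [stratum_rates()]) draws one line per
#' category across age bands; for standardised rates (output of
#' [standardize_rates()]) draws a bar per category.
#'
#' @param rates A tibble from [stratum_rates()] or [standardize_rates()].
#' @param per Rate scale used, for the axis label.
#' @return A ggplot object.
#' @export
plot_rates <- function(rates, per = 1000) {
  ylab <- sprintf("deaths per %s person-years", format(per, big.mark = ","))
  if ("std_rate" %in% names(rates)) {
    ggplot2::ggplot(rates, ggplot2::aes(x = .data$category,
                                        y = .data$std_rate)) +
      ggplot2::geom_col(fill = "seagreen") +
      ggplot2::labs(x = NULL, y = ylab, title = "Age/sex standardised rates") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  } else {
    ggplot2::ggplot(rates, ggplot2::aes(x = .data$age_band, y = .data$rate,
                                        group = .data$category,
                                        colour = .data$category)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "age band", y = ylab, colour = NULL,
                    title = "Stratum-specific mortality rates") +
      ggplot2::theme_minimal()
  }
}
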