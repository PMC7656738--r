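# ggplot2 views of attrition results.

#' Plot attrition percentages by line
#'
#' Bar chart of the attrition percent at each line, faceted by transplant
#' stratum.
#'
#' @param att an [attrition_table()] result.
#' @return a ggplot object.
#' @export
plot_attrition <- function(att) {
  dat <- dplyr::filter(att, !is.na(.data$attrition_pct))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$lot_number),
                                    y = .data$attrition_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Line of therapy", y = "Attrition (%)",
                  title = "Attrition by line of therapy") +
    ggplot2::theme_minimal()
}

#' Plot mean treatment duration by line
#'
#' Mean duration in months per line and stratum, with the median as a
#' point label.
#'
#' @param att an [attrition_table()] result.
#' @return a ggplot object.
#' @export
plot_duration <- function(att) {
  dat <- dplyr::filter(att, !is.na(.data$duration_mean))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$lot_number),
                                    y = .data$duration_mean,
                                    fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Line of therapy", y = "Mean duration (months)",
                  fill = NULL, title = "Treatment duration by line") +
    ggplot2::theme_minimal()
}

#' @rdname plot_attrition
#' @param object an `mm_attrition` table.
#' @param ... unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot mm_attrition
#' @export
autoplot.mm_attrition <- function(object, ...) {
  plot_attrition(object)
}
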