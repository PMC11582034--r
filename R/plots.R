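#' Plot the efficiency timeline
#'
#' Scatter of unit efficiency against FDA approval year, the standard view
#' of technological progress across drug generations.
#'
#' @param timeline An [efficiency_timeline()] data frame.
#' @return A ggplot object.
#' @export
plot_timeline <- function(timeline) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(timeline,
                  ggplot2::aes(x = .data$approval_year,
                               y = .data$efficiency)) +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "approval year", y = "efficiency") +
    ggplot2::theme_minimal()
}

#' Plot per-unit normalized slacks
#'
#' Grouped bars of range-normalized slacks per unit and variable; the
#' tallest bar per unit names the factor driving its inefficiency.
#'
#' @param slacks A list of [compute_slacks()] reports.
#' @return A ggplot object.
#' @export
plot_slacks <- function(slacks) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the ggplot2 package", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(slacks, function(s) {
    data.frame(id = s$unit_id, variable = names(s$normalized),
               normalized_slack = unname(s$normalized))
  }))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$id, y = .data$normalized_slack,
                                    fill = .data$variable)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "normalized slack") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

utils::globalVariables(".data")
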