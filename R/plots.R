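#' Plot active densities of a simulation
#'
#' Time series of the active (asexual + sexual) density of the selected
#' classes, the standard way results of this model are displayed.
#'
#' @param object A `daphnia_sim`.
#' @param classes Class indices to show (default 1:3: the two parental
#'   species and F1 hybrids).
#' @param log10 Plot densities on a log10 axis (zeros dropped).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' ggplot2::autoplot(sim)
#' @method autoplot daphnia_sim
#' @export
autoplot.daphnia_sim <- function(object, classes = 1:3, log10 = FALSE, ...) {
  dat <- tidy(object) |>
    dplyr::filter(.data$stage != "ephippia",
                  .data$class_index %in% classes) |>
    dplyr::summarise(
      density = sum(.data$density),
      .by = c("time_days", "class_index", "class_role")
    )
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$time_days / 365, y = .data$density,
    colour = .data$class_role)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (years)", y = "Active individuals per litre",
      colour = "Class",
      title = sprintf("Scenario %s", object$spec$id)
    ) +
    ggplot2::theme_minimal()
  if (log10) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot annual class proportions
#'
#' @param stats Annual statistics tibble from [annual_statistics()].
#' @param classes Class indices to show.
#' @return A ggplot object.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' plot_annual_proportions(annual_statistics(sim))
#' @export
plot_annual_proportions <- function(stats, classes = 1:3) {
  dat <- dplyr::filter(stats, .data$class_index %in% classes)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$year, y = .data$proportion, colour = .data$class_role)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Proportion of active community",
                  colour = "Class") +
    ggplot2::theme_minimal()
}
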