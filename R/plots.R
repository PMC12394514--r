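# ggplot2 views of the main result types. The screening-curve autoplot lives
# next to its class in screening.R.

#' @rdname fit_ll3
#' @param object an `ll3_fit`.
#' @method autoplot ll3_fit
#' @export
autoplot.ll3_fit <- function(object, ...) {
  temps <- seq(min(object$data$temperature) - 1,
               max(object$data$temperature) + 1, length.out = 200)
  curve <- tibble::tibble(
    temperature = temps,
    fvfm = ll3_predict(temps, object$params["hill"], object$params["fmax"],
                       object$params["ed50"]))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$temperature, y = .data$fvfm)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$params["ed50"],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Hold temperature (°C)", y = "Fv/Fm",
                  subtitle = sprintf("ED50 = %.2f °C",
                                     object$params["ed50"])) +
    ggplot2::theme_minimal()
}

#' Plot group mean relative thresholds with SEM bars
#'
#' One panel per species; site-condition groups on the x axis, mean relative
#' ED50 +/- SEM on the y axis.
#'
#' @param summaries a [summarize_groups()] tibble.
#' @return a ggplot object.
#' @export
plot_group_summaries <- function(summaries) {
  check_columns(summaries, c("species", "site", "condition", "timepoint",
                             "mean_relative_ed50", "sem"), "summaries")
  summaries |>
    dplyr::mutate(group = paste0(.data$site, "\n", .data$condition)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group,
                                 y = .data$mean_relative_ed50,
                                 colour = .data$timepoint)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_relative_ed50 - .data$sem,
                   ymax = .data$mean_relative_ed50 + .data$sem),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "Relative ED50 (ED50 − MMM, °C)",
                  colour = "Season") +
    ggplot2::theme_minimal()
}

#' Plot the growth-tolerance trade-off
#'
#' Scatter of specific growth rate against colony ED50 with a least-squares
#' line, one panel per species x site group.
#'
#' @param growth a [growth_rates()] tibble with `colony_id`, `species`,
#'   `site`, `sgr`.
#' @param fits colony-level fits with `colony_id`, `ed50` (one season and
#'   condition, typically first-season nursery fits).
#' @return a ggplot object.
#' @export
plot_tradeoff <- function(growth, fits) {
  check_columns(growth, c("colony_id", "species", "site", "sgr"), "growth")
  check_columns(fits, c("colony_id", "ed50"), "fits")
  merged <- dplyr::inner_join(growth, fits[, c("colony_id", "ed50")],
                              by = "colony_id")
  ggplot2::ggplot(merged, ggplot2::aes(x = .data$ed50, y = .data$sgr)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~ species + site, scales = "free") +
    ggplot2::labs(x = "ED50 (°C)", y = "SGR (% growth/day)") +
    ggplot2::theme_minimal()
}
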