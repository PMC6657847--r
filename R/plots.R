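#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a daily temperature series
#'
#' Line plot of the daily record, coloured by provenance so interpolated or
#' predicted stretches stand out.
#'
#' @param object A `daily_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.daily_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$provenance),
                        size = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Temperature (°C)",
                  title = paste("Daily", object$variable[[1]], "temperature")) +
    ggplot2::theme_minimal()
}

#' Plot a projection ensemble
#'
#' Daily ensemble mean with a one-standard-deviation ribbon, and the 9
#' degree Celsius overwintering threshold for reference.
#'
#' @param object A `projection_ensemble`.
#' @param threshold Reference temperature line; default 9.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.projection_ensemble <- function(object, threshold = 9, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$date, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "Water temperature (°C)",
                  title = paste0("Projected water temperature (", object$scenario,
                                 ", n = ", object$n_members, ")")) +
    ggplot2::theme_minimal()
}

#' Plot per-winter records
#'
#' Overwintering-period length by winter year (and survival, when present,
#' as a second panel-worthy variable via faceting on the long form).
#'
#' @param object A `winter_records` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.winter_records <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::any_of(c("length_days", "survival")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$winter_year, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), na.rm = TRUE) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Winter year", y = NULL) +
    ggplot2::theme_minimal()
}
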