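#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Seasonal time-series panel of a simulated or observed lake year
#'
#' Faceted time series of NH4+, NO3-+NO2-, chlorophyll a and AO rate, with
#' the ice-covered period shaded.
#'
#' @param seasonal A seasonal-sample tibble (see [simulate_year()]).
#' @return A ggplot object.
#' @export
plot_seasonal <- function(seasonal) {
  vars <- intersect(c("nh4", "no3no2", "chla", "ao_rate"), names(seasonal))
  long <- seasonal |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable",
                        values_to = "value")
  ice <- seasonal[seasonal$under_ice, , drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value,
                                          colour = .data$depth_label))
  if (nrow(ice) > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = min(ice$date), xmax = max(ice$date),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    )
  }
  p +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = "depth") +
    ggplot2::theme_minimal()
}

#' Rate estimates with uncertainty and QC flags
#'
#' Dot plot of AO rate estimates (nmol/L/day) with Monte-Carlo error bars;
#' non-detects sit at zero and over-spiked incubations are marked.
#'
#' @param rates Output of [estimate_ao_rates()].
#' @return A ggplot object.
#' @export
plot_rates <- function(rates) {
  x <- if ("date" %in% names(rates)) "date" else "sample_id"
  p <- ggplot2::ggplot(rates, ggplot2::aes(
    x = .data[[x]], y = .data$rate,
    shape = .data$detected, colour = .data$overspike_flag
  )) +
    ggplot2::geom_point(size = 2.5)
  if (any(!is.na(rates$rate_sd))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$rate - .data$rate_sd, 0),
                   ymax = .data$rate + .data$rate_sd),
      width = 0
    )
  }
  p +
    ggplot2::labs(y = "AO rate (nmol L⁻¹ d⁻¹)", x = NULL,
                  colour = "over-spiked", shape = "detected") +
    ggplot2::theme_minimal()
}

#' @rdname forward_mlr
#' @param object An `ao_mlr` object.
#' @method autoplot ao_mlr
#' @export
autoplot.ao_mlr <- function(object, ...) {
  if (length(object$selected) == 0) {
    rlang::abort("empty model: nothing to plot")
  }
  first <- object$selected[1]
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data[[first]],
                                            y = .data[[object$response]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::labs(
      x = paste(first, "(standardised)"), y = object$response,
      title = sprintf("Forward-selection fit: R² = %.2f", object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname fit_urt
#' @param object An `ao_urt` object.
#' @method autoplot ao_urt
#' @export
autoplot.ao_urt <- function(object, ...) {
  cv <- object$cv
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$n_splits + 1,
                                   y = .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$cv_error - .data$cv_se,
                                        ymax = .data$cv_error + .data$cv_se),
                           width = 0.1) +
    ggplot2::labs(x = "tree size (leaves)",
                  y = "cross-validation relative error") +
    ggplot2::theme_minimal()
}
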