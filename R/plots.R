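# Diagnostic figures: decay curves with fitted lines, Arrhenius plot,
# log D (or log t_R) vs temperature.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Decay curves with the accepted model overlaid
#'
#' Residual-activity observations per temperature with the accepted
#' model's fitted curve.
#'
#' @param object An `inactivation_report`.
#' @param data The activity table the report was fitted to (tibble with
#'   `temperature_C`, `time_min`, `activity`); required because the report
#'   stores fits, not raw observations.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.inactivation_report <- function(object, data, ...) {
  stopifnot(is.data.frame(data))
  acc <- object$accepted_model
  pred <- NULL
  if (!is.na(acc)) {
    acc_fits <- dplyr::filter(object$fits, .data$model_id == acc)
    grid <- seq(0, max(data$time_min), length.out = 120)
    pred <- purrr::pmap_dfr(
      list(acc_fits$temperature_C, acc_fits$estimates),
      function(tc, est) {
        tibble::tibble(temperature_C = tc, time_min = grid,
                       activity = evaluate_model(acc, est, grid))
      })
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$time_min, y = .data$activity,
    colour = factor(.data$temperature_C))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Time (min)", y = expression(A / A[0]),
                  colour = "Temperature (°C)",
                  title = object$label,
                  subtitle = if (!is.na(acc)) paste("accepted model:", acc) else
                    "no model accepted")
  if (!is.null(pred)) p <- p + ggplot2::geom_line(data = pred)
  p
}

#' Arrhenius plot of a thermodynamic summary
#'
#' ln(rate) against 1/T with the fitted regression line.
#'
#' @param object A `thermo_summary`.
#' @param rate Rates used in the fit, min^-1 (same order as the summary's
#'   temperatures); recomputed positions only, the line comes from the
#'   stored regression.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thermo_summary <- function(object, rate, ...) {
  per <- object$per_temperature
  df <- tibble::tibble(invT = 1 / per$temperature_K, lnk = log(rate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$invT, y = .data$lnk)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = expression(1 / T ~ (K^-1)), y = "ln(rate)",
                  title = sprintf("Arrhenius plot (Ea = %.1f kJ/mol)", object$Ea))
}

#' Temperature dependence of the decimal reduction time or reliable life
#'
#' log10(D) (first-order) or log(t_R) (Weibull, in the summary's z' base)
#' against temperature with the regression line whose slope defines z or
#' z'.
#'
#' @param object A `kinetic_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetic_summary <- function(object, ...) {
  per <- object$per_temperature
  if (object$model_id == "weibull") {
    base <- object$z_prime$log_base
    y <- if (identical(base, "ln")) log(per$t_R) else log10(per$t_R)
    lab <- if (identical(base, "ln")) "ln(t_R)" else "log10(t_R)"
    ttl <- sprintf("z' = %.1f °C", object$z_prime$z_prime)
  } else {
    y <- log10(per$D)
    lab <- "log10(D)"
    ttl <- sprintf("z = %.1f °C", object$z$z)
  }
  df <- tibble::tibble(temperature_C = per$temperature_C, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature_C, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "Temperature (°C)", y = lab, title = ttl)
}
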