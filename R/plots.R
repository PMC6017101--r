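#' Median-effect plot of a fit
#'
#' The linearized diagnostic plot: `log10(fa/fu)` against `log10(D)` with
#' the fitted line. Points excluded by the usability band are not shown
#' (they have no finite transform).
#'
#' @param object An [me_fit] with data (fits built by [me_fit()] from bare
#'   parameters draw only the line over `dose_range`).
#' @param dose_range Dose range for parameter-only fits.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.me_fit <- function(object, dose_range = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::labs(
      x = expression(log[10] ~ "dose (mg/mL)"),
      y = expression(log[10] ~ (f[a] / f[u])),
      title = sprintf("Median-effect plot: %s", object$agent_id),
      subtitle = sprintf(
        "Dm = %.4g mg/mL, m = %.3g%s", object$dm, object$m,
        if (!is.na(object$r)) sprintf(", r = %.4f", object$r) else ""
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$points)) {
    p <- p + ggplot2::geom_point(
      data = object$points,
      ggplot2::aes(x = .data$x, y = .data$y)
    )
    dose_range <- range(object$points$dose)
  } else if (is.null(dose_range)) {
    dose_range <- object$dm * c(1 / 50, 50)
  }
  xr <- log10(dose_range)
  p + ggplot2::geom_abline(
    slope = object$m, intercept = object$intercept,
    colour = "steelblue"
  ) +
    ggplot2::coord_cartesian(xlim = xr)
}

#' Fa-CI plot
#'
#' Combination index against fraction affected across the effect range,
#' with the CI = 1 Loewe-additivity reference line. Points below the line
#' are synergistic, above antagonistic.
#'
#' @param object A `ci_profile` from [compute_ci()] or
#'   [compute_ci_pointwise()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ci_profile <- function(object, ...) {
  ids <- attr(object, "agent_ids")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fa, y = .data$ci)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 1) +
    ggplot2::scale_colour_manual(values = c(
      synergism = "#2c7fb8", additive = "grey40", antagonism = "#d95f02"
    )) +
    ggplot2::labs(
      x = expression("fraction affected" ~ (f[a])),
      y = "combination index (CI)",
      colour = NULL,
      title = if (!is.null(ids)) sprintf("Fa-CI plot: %s + %s", ids[1], ids[2]) else "Fa-CI plot"
    ) +
    ggplot2::theme_minimal()
}

#' Dose-effect curves for one or more agents
#'
#' Observed fractions affected against dose on a log-dose axis, optionally
#' overlaid with fitted median-effect curves.
#'
#' @param data A dose-effect tibble (`agent_id`, `dose`,
#'   `fraction_affected`).
#' @param fits Optional named list of [me_fit] objects to overlay.
#' @return A ggplot object.
#' @export
plot_dose_effect <- function(data, fits = NULL) {
  require_columns(data, c("agent_id", "dose", "fraction_affected"), "plot_dose_effect")
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$dose, y = .data$fraction_affected, colour = .data$agent_id)
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "dose (mg/mL)", y = expression("fraction affected" ~ (f[a])),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    dr <- range(data$dose)
    curves <- purrr::map_dfr(fits, function(f) {
      d <- 10^seq(log10(dr[1]), log10(dr[2]), length.out = 120)
      tibble::tibble(agent_id = f$agent_id, dose = d, fraction_affected = predict_fa(f, d))
    })
    p <- p + ggplot2::geom_line(data = curves)
  }
  p
}
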