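# ggplot2 figures for each result type.

#' Plot a body-angle trace with detected events
#'
#' Signed body angle against time (left-directed excursions above the
#' resting line, right-directed below, matching the field's plotting
#' convention), with the rest band shaded and detected events colored by
#' class.
#'
#' @param trace An `angle_trace` from [compute_body_angle()].
#' @param events Optional `movement_events` from [detect_events()].
#' @param rest_band Rest-band half-width used for shading, degrees.
#' @return A ggplot object.
#' @export
plot_angle_trace <- function(trace, events = NULL, rest_band = 5) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$signed_theta)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -rest_band, ymax = rest_band,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "signed body angle excursion (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   fill = .data$event_class),
      ymin = -Inf, ymax = Inf, alpha = 0.2, inherit.aes = FALSE
    ) +
      ggplot2::labs(fill = "class")
  }
  p
}

#' @rdname plot_angle_trace
#' @param object An `angle_trace`.
#' @param ... Passed to [plot_angle_trace()].
#' @method autoplot angle_trace
#' @export
autoplot.angle_trace <- function(object, ...) plot_angle_trace(object, ...)

#' Cumulative distribution of LAM durations across groups
#'
#' Right-continuous empirical CDFs of LAM durations, one curve per group;
#' the standard way to compare duration distributions between phenotypes.
#'
#' @param durations Named list: group label -> numeric durations (s), or a
#'   tibble with `group` and `value` columns (values in seconds).
#' @return A ggplot object.
#' @export
plot_lam_ecdf <- function(durations) {
  if (is.list(durations) && !is.data.frame(durations)) {
    durations <- map_dfr(names(durations), function(g) {
      tibble(group = g, value = durations[[g]])
    })
  }
  ggplot2::ggplot(durations,
                  ggplot2::aes(x = .data$value * 1000, color = .data$group)) +
    ggplot2::stat_ecdf(geom = "step", pad = FALSE) +
    ggplot2::labs(x = "LAM duration (ms)", y = "cumulative probability",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose-survival table with its LC50
#'
#' Survival fraction against dose on a log axis, with the 50% line and,
#' when a fit is supplied, the estimated LC50 (and the fitted logistic
#' curve for the logistic method).
#'
#' @param data A `dose_survival` tibble.
#' @param fit Optional `lc50_fit` from [lc50_estimate()].
#' @return A ggplot object.
#' @export
plot_dose_survival <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$dose, y = .data$fraction)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (mM)", y = "surviving fraction") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    if (fit$method == "logistic" && !is.null(fit$fit)) {
      grid <- tibble(dose = exp(seq(log(min(data$dose[data$dose > 0])),
                                    log(max(data$dose)), length.out = 100)))
      grid$fraction <- stats::predict(fit$fit, newdata = grid, type = "response")
      p <- p + ggplot2::geom_line(data = grid, color = "steelblue")
    }
    p <- p + ggplot2::geom_vline(xintercept = fit$lc50, color = "firebrick",
                                 linetype = 3)
  }
  p
}

#' @rdname plot_dose_survival
#' @param object A `dose_survival`.
#' @param ... Passed to [plot_dose_survival()].
#' @method autoplot dose_survival
#' @export
autoplot.dose_survival <- function(object, ...) plot_dose_survival(object, ...)

#' Plot burst metrics by group
#'
#' Mean +/- s.e.m. bar plots for the four motor-pattern metrics across
#' groups (one `burst_metrics` per group).
#'
#' @param metrics Named list: group label -> `burst_metrics`.
#' @return A ggplot object faceted by metric.
#' @export
plot_burst_metrics <- function(metrics) {
  df <- map_dfr(names(metrics), function(g) {
    mutate(metrics[[g]]$summary, group = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± s.e.m.") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
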