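#' Plot a simulation trace
#'
#' Faceted time course of TAN activity, the sAHP and h currents and the
#' dopamine concentration; stimulus intervals are shaded.
#'
#' @param object A `tan_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tan_trace
#' @export
autoplot.tan_trace <- function(object, ...) {
  long <- tidy.tan_trace(object) |>
    dplyr::mutate(variable = factor(.data$variable,
                                    c("v_tan", "i_sahp", "i_h", "da")))
  stim <- attr(object, "stimulus")$intervals
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$value))
  if (nrow(stim) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = stim,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms),
      ymin = -Inf, ymax = Inf, fill = "grey85",
      inherit.aes = FALSE)
  }
  gg +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = "TAN-dopamine simulation trace") +
    ggplot2::theme_minimal()
}

#' Plot a pause-duration sweep
#'
#' @param object A `tan_sweep`.
#' @param ... Unused.
#' @return A ggplot object: pause duration against the swept axis, one
#'   line per reward prediction error level.
#' @method autoplot tan_sweep
#' @export
autoplot.tan_sweep <- function(object, ...) {
  axis_name <- attr(object, "axis_name") %||% object$axis_name[1]
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$axis_value, .data$tp_ms,
                               colour = factor(.data$rpe))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = axis_name, y = "TAN pause duration (ms)",
                  colour = "RPE") +
    ggplot2::theme_minimal()
}

#' Plot the adaptation experiment error course
#'
#' Mean absolute endpoint error per trial index across sessions with a
#' standard-error ribbon; phase boundaries are marked.
#'
#' @param object A `tan_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tan_experiment
#' @export
autoplot.tan_experiment <- function(object, ...) {
  s <- attr(object, "summary")
  cfg <- attr(object, "config")
  bounds <- cumsum(cfg$trials_per_phase[c("baseline", "perturbation")])
  ggplot2::ggplot(s, ggplot2::aes(.data$trial, .data$mean_abs_error)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_abs_error - .data$se_abs_error,
                   ymax = .data$mean_abs_error + .data$se_abs_error),
      fill = "grey80") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = bounds + 0.5, linetype = 2) +
    ggplot2::labs(
      x = "trial", y = "mean |error| across sessions",
      title = sprintf("adaptation (alpha = %g, ldopa = %g)",
                      cfg$alpha, cfg$ldopa)) +
    ggplot2::theme_minimal()
}

#' @export
plot.tan_trace <- function(x, ...) print(autoplot.tan_trace(x, ...))

#' @export
plot.tan_sweep <- function(x, ...) print(autoplot.tan_sweep(x, ...))

#' @export
plot.tan_experiment <- function(x, ...) {
  print(autoplot.tan_experiment(x, ...))
}
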