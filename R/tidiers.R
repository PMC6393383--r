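#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation trace into long format
#'
#' @param x A `tan_trace`.
#' @param ... Unused.
#' @return A tibble with columns `t_ms`, `variable`
#'   (`v_tan`/`i_sahp`/`i_h`/`da`) and `value`.
#' @method tidy tan_trace
#' @export
tidy.tan_trace <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"t_ms", names_to = "variable",
                        values_to = "value")
}

#' One-row summary of a simulation trace
#'
#' @param x A `tan_trace`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, step, horizon, TAN activity and
#'   dopamine ranges, pause duration and phasic dopamine integral.
#' @method glance tan_trace
#' @export
glance.tan_trace <- function(x, ...) {
  p <- detect_pause(x)
  tibble::tibble(
    n = nrow(x), dt = attr(x, "dt"),
    horizon_ms = max(x$t_ms),
    v_min = min(x$v_tan), v_max = max(x$v_tan),
    da_min = min(x$da), da_max = max(x$da),
    tp_ms = p$duration_ms,
    da_integral = phasic_da_integral(x))
}

#' Tidy pause metrics
#'
#' @param x A `tan_pause`.
#' @param ... Unused.
#' @return A one-row tibble with the pause boundaries, duration,
#'   dopamine extrema, censoring flag and threshold used.
#' @method tidy tan_pause
#' @export
tidy.tan_pause <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a sweep table
#'
#' @param x A `tan_sweep`.
#' @param ... Unused.
#' @return The underlying tibble (`axis_name`, `axis_value`, `rpe`,
#'   `tp_ms`).
#' @method tidy tan_sweep
#' @export
tidy.tan_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy corticostriatal weights into long format
#'
#' @param x A `tan_weights`.
#' @param ... Unused.
#' @return A tibble with columns `pathway` (`direct`/`indirect`),
#'   `i` (action/MSN column), `j` (cue row) and `value`.
#' @method tidy tan_weights
#' @export
tidy.tan_weights <- function(x, ...) {
  long <- function(m, lab) {
    tibble::tibble(
      pathway = lab,
      i = rep(seq_len(ncol(m)), each = nrow(m)),
      j = rep(seq_len(nrow(m)), times = ncol(m)),
      value = as.vector(m))
  }
  dplyr::bind_rows(long(x$w1, "direct"), long(x$w2, "indirect"))
}

#' Per-trial summary of an adaptation experiment
#'
#' @param x A `tan_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per trial index: `trial`, `phase`,
#'   `mean_abs_error` and `se_abs_error` across sessions.
#' @method tidy tan_experiment
#' @export
tidy.tan_experiment <- function(x, ...) {
  attr(x, "summary")
}

#' One-row summary of an adaptation experiment
#'
#' @param x A `tan_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: context, session count, and the mean
#'   absolute error over the first and last five trials of each phase's
#'   perturbation window.
#' @method glance tan_experiment
#' @export
glance.tan_experiment <- function(x, ...) {
  cfg <- attr(x, "config")
  s <- attr(x, "summary")
  pe <- s[s$phase == "perturbation", ]
  pe <- pe[order(pe$trial), ]
  tibble::tibble(
    n_sessions = cfg$n_sessions,
    alpha = cfg$alpha, ldopa = cfg$ldopa, seed = cfg$seed,
    early_perturb_error = mean(utils::head(pe$mean_abs_error, 5)),
    late_perturb_error = mean(utils::tail(pe$mean_abs_error, 5)),
    mean_abs_da_integral = mean(abs(x$da_integral)))
}
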