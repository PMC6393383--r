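#' Model parameters for the TAN-dopamine rate model
#'
#' Bundles every constant of the coupled cholinergic-interneuron (TAN) /
#' striatal dopamine rate model. Defaults are the published calibration
#' against thalamic-stimulation slice recordings; all values are
#' dimensionless except the time constants (milliseconds).
#'
#' @param tau_tan Time constant of TAN population activity, ms.
#' @param w_thal Synaptic weight of the binary thalamic input.
#' @param drv_tan Constant drive setting the tonic firing level.
#' @param tau_sahp Time constant of the slow after-hyperpolarization
#'   (sAHP) potassium current, ms.
#' @param g_sahp sAHP activation gain.
#' @param theta_sahp sAHP activation threshold on TAN activity.
#' @param tau_h Time constant of the hyperpolarization-activated
#'   (h-) current, ms.
#' @param g_h h-current activation gain.
#' @param theta_h h-current activation threshold on TAN activity.
#' @param w_da Dopamine weight on the h-current (D2-receptor coupling);
#'   the h-current drive is scaled by `exp(-w_da * da)`.
#' @param tau_da Dopamine concentration time constant, ms.
#' @param theta_da Nicotinic-receptor threshold on TAN activity below
#'   which dopamine release escapes cholinergic control.
#' @param da0 Baseline (tonic) dopamine concentration, normalized units.
#'
#' @return An object of class `tan_params`: a named list of the thirteen
#'   constants.
#' @examples
#' p <- model_params()
#' p$tau_tan
#' model_params(g_h = 0) # h-current blockade
#' @export
model_params <- function(tau_tan = 20, w_thal = 4, drv_tan = 0.3,
                         tau_sahp = 700, g_sahp = 5, theta_sahp = 0.3,
                         tau_h = 700, g_h = 20, theta_h = 0.2,
                         w_da = 1, tau_da = 20, theta_da = 0.01,
                         da0 = 1) {
  p <- list(
    tau_tan = tau_tan, w_thal = w_thal, drv_tan = drv_tan,
    tau_sahp = tau_sahp, g_sahp = g_sahp, theta_sahp = theta_sahp,
    tau_h = tau_h, g_h = g_h, theta_h = theta_h,
    w_da = w_da, tau_da = tau_da, theta_da = theta_da, da0 = da0
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
    p[[nm]] <- as.double(v)
  }
  for (nm in c("tau_tan", "tau_sahp", "tau_h", "tau_da")) {
    if (p[[nm]] <= 0) {
      stop("time constant '", nm, "' must be strictly positive",
           call. = FALSE)
    }
  }
  for (nm in c("g_sahp", "theta_sahp", "g_h", "theta_h",
               "theta_da", "da0")) {
    if (p[[nm]] < 0) {
      stop("'", nm, "' must be non-negative", call. = FALSE)
    }
  }
  if (!(p$theta_da > 0 && p$theta_da < p$theta_h &&
        p$theta_h < p$theta_sahp)) {
    warning("thresholds violate the default regime ",
            "0 < theta_da < theta_h < theta_sahp; ",
            "the burst-pause response may be qualitatively different",
            call. = FALSE)
  }
  structure(p, class = "tan_params")
}

#' @export
print.tan_params <- function(x, ...) {
  cat("<tan_params>\n")
  cat(paste0("  ", names(x), " = ", unlist(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Scenario context: reward prediction error, deficiency and levodopa
#'
#' Describes the experimental condition a simulation is run under:
#' the reward prediction error carried by the dopaminergic input, the
#' dopamine-deficiency coefficient modelling nigrostriatal degeneration,
#' and the levodopa term that raises the baseline dopamine concentration
#' without affecting phasic release.
#'
#' @param rpe Reward prediction error in `[-1, 1]`; values outside the
#'   interval are clamped with a warning.
#' @param alpha Deficiency coefficient in `[0, 1]`; 1 is healthy, 0 is
#'   complete loss of dopamine production. Scales both the baseline and
#'   the phasic dopamine terms.
#' @param ldopa Additive levodopa constant (normalized dopamine units,
#'   `>= 0`) applied to the baseline only.
#'
#' @return An object of class `tan_context`.
#' @examples
#' scenario_context(rpe = 1)
#' scenario_context(rpe = -1, alpha = 0.5, ldopa = 0.5)
#' @export
scenario_context <- function(rpe = 0, alpha = 1, ldopa = 0) {
  stopifnot(is.numeric(rpe), length(rpe) == 1L, is.finite(rpe),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(ldopa), length(ldopa) == 1L, is.finite(ldopa))
  if (rpe < -1 || rpe > 1) {
    warning("rpe clamped to [-1, 1]", call. = FALSE)
    rpe <- min(1, max(-1, rpe))
  }
  if (alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (ldopa < 0) stop("ldopa must be non-negative", call. = FALSE)
  structure(list(rpe = rpe, alpha = alpha, ldopa = ldopa),
            class = "tan_context")
}

#' @export
print.tan_context <- function(x, ...) {
  cat(sprintf("<tan_context> rpe = %g, alpha = %g, ldopa = %g\n",
              x$rpe, x$alpha, x$ldopa))
  invisible(x)
}

#' Effective baseline dopamine concentration of a context
#'
#' Under deficiency and/or levodopa the tonic dopamine level is
#' `alpha * da0 + ldopa` rather than `da0`; phasic deviations are
#' measured from this effective baseline.
#'
#' @param context A [scenario_context()].
#' @param params A [model_params()].
#' @return A single number, the effective baseline concentration.
#' @export
effective_baseline <- function(context, params = model_params()) {
  stopifnot(inherits(context, "tan_context"), inherits(params, "tan_params"))
  context$alpha * params$da0 + context$ldopa
}

#' Stimulus protocols: binary thalamic input
#'
#' A stimulus protocol is an ordered set of half-open intervals
#' `[start, end)` (ms) during which the binary thalamic input equals 1;
#' it is 0 elsewhere. `stimulus_protocol()` is the low-level constructor;
#' `stim_block()` builds a single block (the 300 ms block used for the
#' pause-vs-RPE simulations), `stim_pulse_train()` a periodic train
#' (e.g. 50 Hz x 10 pulses as in the slice-recording protocol) and
#' `stim_none()` an empty protocol.
#'
#' @param intervals A two-column matrix or data frame of
#'   `(start_ms, end_ms)` rows, non-overlapping, sorted, contained in
#'   `[0, total_duration_ms)`.
#' @param total_duration_ms Simulation horizon, ms.
#' @return An object of class `tan_stimulus` with elements `intervals`
#'   (a tibble with columns `start_ms`, `end_ms`) and
#'   `total_duration_ms`.
#' @examples
#' stim_block(300)
#' stim_pulse_train(freq_hz = 50, n_pulses = 10)
#' @export
stimulus_protocol <- function(intervals, total_duration_ms) {
  stopifnot(is.numeric(total_duration_ms), length(total_duration_ms) == 1L,
            is.finite(total_duration_ms), total_duration_ms > 0)
  iv <- as.data.frame(intervals)
  if (nrow(iv) > 0) {
    names(iv) <- c("start_ms", "end_ms")
    if (any(!is.finite(as.matrix(iv)))) {
      stop("stimulus intervals must be finite", call. = FALSE)
    }
    if (any(iv$end_ms <= iv$start_ms)) {
      stop("each stimulus interval must have end_ms > start_ms",
           call. = FALSE)
    }
    if (is.unsorted(iv$start_ms, strictly = TRUE) && nrow(iv) > 1) {
      stop("stimulus intervals must be sorted by start time",
           call. = FALSE)
    }
    if (nrow(iv) > 1 &&
        any(iv$start_ms[-1] < iv$end_ms[-nrow(iv)])) {
      stop("stimulus intervals must not overlap", call. = FALSE)
    }
    if (iv$start_ms[1] < 0 ||
        iv$end_ms[nrow(iv)] > total_duration_ms) {
      stop("stimulus intervals must be contained in [0, total_duration_ms)",
           call. = FALSE)
    }
  } else {
    iv <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  }
  structure(list(intervals = tibble::as_tibble(iv),
                 total_duration_ms = total_duration_ms),
            class = "tan_stimulus")
}

#' @rdname stimulus_protocol
#' @param duration_ms Block length, ms.
#' @param onset_ms Block onset, ms.
#' @export
stim_block <- function(duration_ms = 300, onset_ms = 0,
                       total_duration_ms = onset_ms + duration_ms + 3000) {
  stimulus_protocol(cbind(onset_ms, onset_ms + duration_ms),
                    total_duration_ms)
}

#' @rdname stimulus_protocol
#' @param freq_hz Pulse frequency, Hz.
#' @param n_pulses Number of pulses.
#' @param width_ms Width of each on-pulse, ms; must be smaller than the
#'   period `1000 / freq_hz`.
#' @export
stim_pulse_train <- function(freq_hz = 50, n_pulses = 10, width_ms = 10,
                             onset_ms = 0,
                             total_duration_ms = NULL) {
  stopifnot(freq_hz > 0, n_pulses >= 1, width_ms > 0)
  period <- 1000 / freq_hz
  if (width_ms >= period) {
    stop("pulse width (", width_ms, " ms) must be smaller than the period (",
         period, " ms); pulses would overlap", call. = FALSE)
  }
  starts <- onset_ms + period * (seq_len(n_pulses) - 1)
  if (is.null(total_duration_ms)) {
    total_duration_ms <- max(starts) + width_ms + 3000
  }
  stimulus_protocol(cbind(starts, starts + width_ms), total_duration_ms)
}

#' @rdname stimulus_protocol
#' @export
stim_none <- function(total_duration_ms = 2000) {
  stimulus_protocol(matrix(numeric(0), ncol = 2), total_duration_ms)
}

#' @export
print.tan_stimulus <- function(x, ...) {
  cat(sprintf("<tan_stimulus> %d interval(s), horizon %g ms\n",
              nrow(x$intervals), x$total_duration_ms))
  if (nrow(x$intervals) > 0) print(x$intervals, n = 5)
  invisible(x)
}

# binary thalamic input sampled on a time grid
stimulus_on_grid <- function(stimulus, t) {
  on <- logical(length(t))
  iv <- stimulus$intervals
  for (k in seq_len(nrow(iv))) {
    on <- on | (t >= iv$start_ms[k] & t < iv$end_ms[k])
  }
  as.numeric(on)
}
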