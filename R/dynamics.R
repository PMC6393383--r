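#' Gated hyperbolic-tangent transfer function
#'
#' The TAN population transfer function `sigma(x) = Theta(x) * tanh(x)`:
#' zero for non-positive input (taking `Theta(0) = 0`), `tanh(x)`
#' otherwise, so the output lies in `[0, 1)`.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of the same length.
#' @examples
#' sigma_gate(c(-1, 0, 0.3))
#' @export
sigma_gate <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("sigma_gate() requires finite numeric input", call. = FALSE)
  }
  ifelse(x > 0, tanh(x), 0)
}

# relaxation targets of the four state variables; `s` is the binary
# thalamic input at the current instant. Each ODE has the form
# tau * dx/dt + x = target(x, ...), i.e. dx/dt = (target - x) / tau.
state_targets <- function(v, da, s, p, ctx) {
  sahp_t <- if (v > p$theta_sahp) -p$g_sahp * (v - p$theta_sahp) else 0
  h_t <- if (v < p$theta_h) {
    -p$g_h * exp(-p$w_da * da) * (v - p$theta_h)
  } else 0
  phasic <- if (v < p$theta_da) ctx$rpe * (1 - v / p$theta_da) else 0
  da_t <- ctx$alpha * (phasic + p$da0) + ctx$ldopa
  list(sahp = sahp_t, h = h_t, da = da_t)
}

#' Time derivatives of the coupled TAN-dopamine system
#'
#' Evaluates the right-hand side of the four first-order rate equations:
#' TAN activity relaxes toward `sigma(w_thal * v_thal + drv_tan +
#' i_sahp + i_h)`; the sAHP current activates above `theta_sahp`; the
#' h-current activates below `theta_h` with gain suppressed by dopamine
#' through `exp(-w_da * da)`; dopamine relaxes toward
#' `alpha * (rpe * (1 - v/theta_da) * Theta(theta_da - v) + da0) + ldopa`.
#'
#' @param state Named numeric vector or one-row data frame with entries
#'   `v_tan`, `i_sahp`, `i_h`, `da`.
#' @param t Time, ms (determines the binary thalamic input).
#' @param params A [model_params()].
#' @param stimulus A [stimulus_protocol()].
#' @param context A [scenario_context()].
#' @return Named numeric vector `c(v_tan, i_sahp, i_h, da)` of time
#'   derivatives (per ms).
#' @examples
#' rest <- steady_state()
#' derivatives(rest, t = 0, stimulus = stim_none())
#' @export
derivatives <- function(state, t, params = model_params(),
                        stimulus = stim_none(),
                        context = scenario_context()) {
  stopifnot(inherits(params, "tan_params"),
            inherits(stimulus, "tan_stimulus"),
            inherits(context, "tan_context"))
  st <- as.list(state)
  v <- st$v_tan; isahp <- st$i_sahp; ih <- st$i_h; da <- st$da
  s <- stimulus_on_grid(stimulus, t)
  tg <- state_targets(v, da, s, params, context)
  v_target <- sigma_gate(params$w_thal * s + params$drv_tan + isahp + ih)
  c(v_tan = (v_target - v) / params$tau_tan,
    i_sahp = (tg$sahp - isahp) / params$tau_sahp,
    i_h = (tg$h - ih) / params$tau_h,
    da = (tg$da - da) / params$tau_da)
}

#' No-stimulus fixed point of the TAN-dopamine system
#'
#' Solves the resting state self-consistently by fixed-point iteration:
#' dopamine settles at `alpha * da0 + ldopa` whenever the resting TAN
#' activity exceeds the nicotinic threshold, and the resting activity
#' solves `v = sigma(drv_tan + i_sahp(v) + i_h(v, da))`. At the default
#' parameters both current targets vanish at rest and the fixed point
#' reduces to `v = tanh(drv_tan)`, `da = alpha * da0 + ldopa`.
#'
#' @inheritParams derivatives
#' @param max_iter Maximum fixed-point iterations before giving up.
#' @param tol Convergence tolerance on the state (absolute).
#' @return A one-row tibble of class `tan_state` with columns `v_tan`,
#'   `i_sahp`, `i_h`, `da`.
#' @examples
#' steady_state()
#' steady_state(context = scenario_context(alpha = 0.5, ldopa = 0.5))
#' @export
steady_state <- function(params = model_params(),
                         context = scenario_context(),
                         max_iter = 1000, tol = 1e-12) {
  stopifnot(inherits(params, "tan_params"),
            inherits(context, "tan_context"))
  v <- sigma_gate(params$drv_tan)
  da <- max(0, context$alpha * params$da0 + context$ldopa)
  for (i in seq_len(max_iter)) {
    tg <- state_targets(v, da, 0, params, context)
    v_new <- sigma_gate(params$drv_tan + tg$sahp + tg$h)
    da_new <- max(0, tg$da)
    if (abs(v_new - v) < tol && abs(da_new - da) < tol) {
      tg <- state_targets(v_new, da_new, 0, params, context)
      out <- tibble::tibble(v_tan = v_new, i_sahp = tg$sahp,
                            i_h = tg$h, da = da_new)
      class(out) <- c("tan_state", class(out))
      return(out)
    }
    v <- v_new; da <- da_new
  }
  stop("steady_state() failed to converge in ", max_iter,
       " fixed-point iterations", call. = FALSE)
}

#' Integrate the TAN-dopamine system on a uniform time grid
#'
#' Forward-Euler integration of the coupled rate equations under a
#' binary thalamic stimulus protocol and a scenario context. The
#' dopamine concentration is clipped at zero from below. The default
#' step of 1 ms is comfortably stable given that every time constant is
#' at least 20 ms; a step-halving check is part of the test suite.
#'
#' @inheritParams derivatives
#' @param dt Integration step, ms.
#' @param init Initial state: the string `"rest"` (the fixed point from
#'   [steady_state()]) or a `tan_state` / named one-row data frame.
#' @return A tibble of class `tan_trace` with columns `t_ms`, `v_tan`,
#'   `i_sahp`, `i_h`, `da`, one row per grid point, and attributes
#'   `params`, `stimulus`, `context`, `dt`.
#' @examples
#' tr <- simulate_tan(stimulus = stim_block(300),
#'                    context = scenario_context(rpe = 1))
#' detect_pause(tr)
#' @export
simulate_tan <- function(params = model_params(),
                         stimulus = stim_block(300),
                         context = scenario_context(),
                         dt = 1, init = "rest") {
  stopifnot(inherits(params, "tan_params"),
            inherits(stimulus, "tan_stimulus"),
            inherits(context, "tan_context"),
            is.numeric(dt), length(dt) == 1L, dt > 0)
  t <- seq(0, stimulus$total_duration_ms, by = dt)
  n <- length(t)
  if (identical(init, "rest")) {
    init <- steady_state(params, context)
  }
  init <- as.list(init)
  stopifnot(all(c("v_tan", "i_sahp", "i_h", "da") %in% names(init)))

  s <- stimulus_on_grid(stimulus, t)
  v <- isahp <- ih <- da <- numeric(n)
  v[1] <- init$v_tan[[1]]; isahp[1] <- init$i_sahp[[1]]
  ih[1] <- init$i_h[[1]]; da[1] <- max(0, init$da[[1]])

  p <- params; ctx <- context
  rtan <- dt / p$tau_tan; rsahp <- dt / p$tau_sahp
  rh <- dt / p$tau_h; rda <- dt / p$tau_da
  for (k in seq_len(n - 1)) {
    vk <- v[k]; dak <- da[k]
    v_target <- p$w_thal * s[k] + p$drv_tan + isahp[k] + ih[k]
    v_target <- if (v_target > 0) tanh(v_target) else 0
    sahp_t <- if (vk > p$theta_sahp) -p$g_sahp * (vk - p$theta_sahp) else 0
    h_t <- if (vk < p$theta_h) {
      -p$g_h * exp(-p$w_da * dak) * (vk - p$theta_h)
    } else 0
    phasic <- if (vk < p$theta_da) ctx$rpe * (1 - vk / p$theta_da) else 0
    da_t <- ctx$alpha * (phasic + p$da0) + ctx$ldopa

    v[k + 1] <- vk + rtan * (v_target - vk)
    isahp[k + 1] <- isahp[k] + rsahp * (sahp_t - isahp[k])
    ih[k + 1] <- ih[k] + rh * (h_t - ih[k])
    da[k + 1] <- max(0, dak + rda * (da_t - dak))
    if (v[k + 1] < 0 || v[k + 1] >= 1) {
      stop("TAN activity left [0, 1) at t = ", t[k + 1],
           " ms; the Euler step dt = ", dt,
           " ms is too large for these parameters - use a smaller dt",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(t_ms = t, v_tan = v, i_sahp = isahp,
                        i_h = ih, da = da)
  attr(out, "params") <- params
  attr(out, "stimulus") <- stimulus
  attr(out, "context") <- context
  attr(out, "dt") <- dt
  class(out) <- c("tan_trace", class(out))
  out
}

#' Detect the TAN pause in a simulated trace
#'
#' The pause is measured from the last stimulus offset: onset is the
#' first grid time at or after that offset where TAN activity drops
#' below the threshold, offset the first subsequent grid time where it
#' recovers to the threshold, and duration their difference. The
#' default `"auto"` threshold is 0.9 times the resting activity of the
#' same parameters and context. A pause that has not recovered by the
#' end of the trace is reported as censored (duration measured to the
#' horizon) with a warning.
#'
#' @param trace A `tan_trace` from [simulate_tan()].
#' @param threshold Numeric threshold on TAN activity, or `"auto"`.
#' @return An object of class `tan_pause`: a list with `onset_ms`,
#'   `offset_ms`, `duration_ms`, `min_da`, `max_da`, `censored`,
#'   `threshold`. When no pause occurs, onset and offset are `NA` and
#'   the duration is 0.
#' @export
detect_pause <- function(trace, threshold = "auto") {
  stopifnot(inherits(trace, "tan_trace"))
  params <- attr(trace, "params")
  context <- attr(trace, "context")
  stimulus <- attr(trace, "stimulus")
  if (identical(threshold, "auto")) {
    threshold <- 0.9 * steady_state(params, context)$v_tan
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)

  no_pause <- structure(
    list(onset_ms = NA_real_, offset_ms = NA_real_, duration_ms = 0,
         min_da = NA_real_, max_da = NA_real_, censored = FALSE,
         threshold = threshold),
    class = "tan_pause")
  if (nrow(stimulus$intervals) == 0) return(no_pause)

  stim_off <- max(stimulus$intervals$end_ms)
  idx <- which(trace$t_ms >= stim_off)
  below <- idx[trace$v_tan[idx] < threshold]
  if (length(below) == 0) return(no_pause)
  onset_i <- below[1]
  rec <- which(trace$t_ms > trace$t_ms[onset_i] &
                 trace$v_tan >= threshold &
                 seq_len(nrow(trace)) > onset_i)
  censored <- length(rec) == 0
  offset_i <- if (censored) nrow(trace) else rec[1]
  if (censored) {
    warning("TAN activity did not recover within the horizon; ",
            "pause duration is censored at ",
            trace$t_ms[offset_i] - trace$t_ms[onset_i], " ms",
            call. = FALSE)
  }
  span <- onset_i:offset_i
  structure(
    list(onset_ms = trace$t_ms[onset_i],
         offset_ms = trace$t_ms[offset_i],
         duration_ms = trace$t_ms[offset_i] - trace$t_ms[onset_i],
         min_da = min(trace$da[span]),
         max_da = max(trace$da[span]),
         censored = censored,
         threshold = threshold),
    class = "tan_pause")
}

#' @export
print.tan_pause <- function(x, ...) {
  if (is.na(x$onset_ms)) {
    cat("<tan_pause> no pause detected\n")
  } else {
    cat(sprintf(
      "<tan_pause> %g ms (%g-%g ms)%s; da in [%.4g, %.4g]\n",
      x$duration_ms, x$onset_ms, x$offset_ms,
      if (x$censored) " [censored]" else "", x$min_da, x$max_da))
  }
  invisible(x)
}

#' Time-integral of phasic dopamine over a trace
#'
#' Trapezoidal integral of the deviation of the dopamine concentration
#' from the context's effective baseline `alpha * da0 + ldopa`, over the
#' whole trace window. Outside the TAN pause the deviation is
#' essentially zero, so the window choice is immaterial; this is the
#' learning signal that scales the corticostriatal weight updates.
#'
#' @param trace A `tan_trace` from [simulate_tan()].
#' @return A single number, concentration x ms.
#' @export
phasic_da_integral <- function(trace) {
  stopifnot(inherits(trace, "tan_trace"))
  base <- effective_baseline(attr(trace, "context"), attr(trace, "params"))
  dev <- trace$da - base
  dt <- attr(trace, "dt")
  dt * (sum(dev) - 0.5 * (dev[1] + dev[length(dev)]))
}

#' @export
print.tan_trace <- function(x, ...) {
  ctx <- attr(x, "context")
  cat(sprintf(
    "<tan_trace> %d points, dt = %g ms, rpe = %g, alpha = %g, ldopa = %g\n",
    nrow(x), attr(x, "dt"), ctx$rpe, ctx$alpha, ctx$ldopa))
  NextMethod()
}
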