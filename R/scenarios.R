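#' Named pharmacological conditions
#'
#' Encodes the slice-experiment conditions as parameter overrides:
#' `sulpiride` (D2-receptor blockade, `w_da = 0`, maximal h-current),
#' `cocaine` (dopamine-reuptake blockade, baseline dopamine tripled,
#' `da0 = 3`), `h_block` (hypothetical h-current blockade, `g_h = 0`)
#' and `control` (no overrides).
#'
#' @param name One of `"control"`, `"sulpiride"`, `"cocaine"`,
#'   `"h_block"`.
#' @return An object of class `tan_condition` with elements `name` and
#'   `overrides` (a named list touching only `w_da`, `da0`, `g_h`).
#' @examples
#' pharmacology_condition("sulpiride")
#' @export
pharmacology_condition <- function(name) {
  presets <- list(
    control = list(),
    sulpiride = list(w_da = 0),
    cocaine = list(da0 = 3),
    h_block = list(g_h = 0)
  )
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(presets)) {
    stop("unknown condition '", paste(name, collapse = ", "),
         "'; valid conditions: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, overrides = presets[[name]]),
            class = "tan_condition")
}

#' @export
print.tan_condition <- function(x, ...) {
  ov <- if (length(x$overrides) == 0) "none" else {
    paste(names(x$overrides), unlist(x$overrides),
          sep = " = ", collapse = ", ")
  }
  cat(sprintf("<tan_condition> %s (overrides: %s)\n", x$name, ov))
  invisible(x)
}

# apply condition overrides to a parameter set without mutating it
apply_condition <- function(params, cond) {
  p <- unclass(params)
  for (nm in names(cond$overrides)) p[[nm]] <- cond$overrides[[nm]]
  do.call(model_params, p)
}

#' Simulate a pharmacological condition
#'
#' Applies a condition's parameter overrides, integrates the model
#' under the given stimulus and context, and measures the TAN pause.
#'
#' @param condition A [pharmacology_condition()] or a condition name.
#' @param stimulus A [stimulus_protocol()].
#' @param context A [scenario_context()].
#' @param params Base parameters the overrides are applied to.
#' @param dt Integration step, ms.
#' @return A list of class `tan_run` with elements `trace`
#'   (a `tan_trace`), `pause` (a `tan_pause`) and `condition`.
#' @examples
#' run <- run_condition("sulpiride", stim_pulse_train())
#' run$pause
#' @export
run_condition <- function(condition, stimulus = stim_block(300),
                          context = scenario_context(),
                          params = model_params(), dt = 1) {
  if (is.character(condition)) {
    condition <- pharmacology_condition(condition)
  }
  stopifnot(inherits(condition, "tan_condition"))
  if (condition$name == "cocaine" && context$alpha < 1) {
    warning("combining the cocaine preset (da0 scaled to 3) with ",
            "dopamine deficiency composes multiplicatively: the ",
            "effective baseline is alpha * 3 + ldopa", call. = FALSE)
  }
  p <- apply_condition(params, condition)
  trace <- simulate_tan(p, stimulus, context, dt = dt)
  structure(list(trace = trace, pause = detect_pause(trace),
                 condition = condition),
            class = "tan_run")
}

#' @export
print.tan_run <- function(x, ...) {
  cat(sprintf("<tan_run> condition = %s\n", x$condition$name))
  print(x$pause)
  invisible(x)
}

new_sweep <- function(df, axis_name) {
  out <- tibble::as_tibble(df)
  attr(out, "axis_name") <- axis_name
  class(out) <- c("tan_sweep", class(out))
  out
}

sweep_row <- function(axis_name, axis_value, rpe, pause) {
  tibble::tibble(axis_name = axis_name, axis_value = axis_value,
                 rpe = rpe, tp_ms = pause$duration_ms)
}

#' Sweep the TAN pause duration over stimulus duration
#'
#' Runs the model at each combination of thalamic block duration and
#' reward prediction error and tabulates the pause duration. Defaults
#' follow the published sweep range (100-400 ms blocks; RPE -1, 0, 1).
#'
#' @param durations_ms Block durations to simulate, ms.
#' @param rpe_levels Reward prediction errors to simulate.
#' @param alpha,ldopa Scenario context shared by all cells.
#' @param params Base [model_params()].
#' @param dt Integration step, ms.
#' @param post_ms Simulated time after stimulus offset (must exceed the
#'   longest pause so no cell is censored).
#' @return A tibble of class `tan_sweep` with columns `axis_name`,
#'   `axis_value`, `rpe`, `tp_ms`; one row per cell, no missing cells.
#' @examples
#' \donttest{
#' sweep_stim_duration(c(100, 300), rpe_levels = c(0, 1))
#' }
#' @export
sweep_stim_duration <- function(durations_ms = c(100, 200, 300, 400),
                                rpe_levels = c(-1, 0, 1),
                                alpha = 1, ldopa = 0,
                                params = model_params(), dt = 1,
                                post_ms = 4000) {
  stopifnot(all(durations_ms > 0))
  grid <- tidyr::expand_grid(duration = durations_ms, rpe = rpe_levels)
  rows <- purrr::pmap(grid, function(duration, rpe) {
    stim <- stim_block(duration, total_duration_ms = duration + post_ms)
    ctx <- scenario_context(rpe = rpe, alpha = alpha, ldopa = ldopa)
    run <- run_condition("control", stim, ctx, params, dt)
    sweep_row("stim_duration_ms", duration, rpe, run$pause)
  })
  new_sweep(dplyr::bind_rows(rows), "stim_duration_ms")
}

#' Sweep the TAN pause duration over dopamine deficiency
#'
#' Tabulates the pause duration against the percentage of dopamine
#' deficiency `100 * (1 - alpha)` for each reward prediction error.
#' Default grid: 0-90% deficiency in 10% steps.
#'
#' @param alphas Deficiency coefficients in `[0, 1]` (1 = healthy).
#' @param stimulus Stimulus protocol shared by all cells.
#' @inheritParams sweep_stim_duration
#' @return A tibble of class `tan_sweep` with axis `deficiency_pct`.
#' @export
sweep_deficiency <- function(alphas = seq(1, 0.1, by = -0.1),
                             rpe_levels = c(-1, 0, 1),
                             stimulus = stim_block(300),
                             ldopa = 0,
                             params = model_params(), dt = 1) {
  grid <- tidyr::expand_grid(alpha = alphas, rpe = rpe_levels)
  rows <- purrr::pmap(grid, function(alpha, rpe) {
    ctx <- scenario_context(rpe = rpe, alpha = alpha, ldopa = ldopa)
    run <- run_condition("control", stimulus, ctx, params, dt)
    sweep_row("deficiency_pct", 100 * (1 - alpha), rpe, run$pause)
  })
  new_sweep(dplyr::bind_rows(rows), "deficiency_pct")
}

#' Sweep the TAN pause duration over levodopa dose
#'
#' Tabulates the pause duration against the levodopa additive constant
#' at a fixed deficiency level (default 50%, the parkinsonian condition
#' levodopa is simulated on top of).
#'
#' @param ldopa_values Levodopa constants, normalized dopamine units.
#' @param alpha Fixed deficiency coefficient.
#' @inheritParams sweep_deficiency
#' @return A tibble of class `tan_sweep` with axis `ldopa`.
#' @export
sweep_ldopa <- function(ldopa_values = seq(0, 1, by = 0.2),
                        alpha = 0.5,
                        rpe_levels = c(-1, 0, 1),
                        stimulus = stim_block(300),
                        params = model_params(), dt = 1) {
  grid <- tidyr::expand_grid(ldopa = ldopa_values, rpe = rpe_levels)
  rows <- purrr::pmap(grid, function(ldopa, rpe) {
    ctx <- scenario_context(rpe = rpe, alpha = alpha, ldopa = ldopa)
    run <- run_condition("control", stimulus, ctx, params, dt)
    sweep_row("ldopa", ldopa, rpe, run$pause)
  })
  new_sweep(dplyr::bind_rows(rows), "ldopa")
}
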