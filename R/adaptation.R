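#' Configuration of the reduced motor-adaptation task
#'
#' The task mirrors the structure of the prism-perturbation
#' ball-throwing experiment: each session comprises a baseline phase, a
#' perturbation phase in which the horizontally mirrored target must be
#' acquired by reinforcement alone, and an aftereffect phase; per-trial
#' rewards drive a temporal-difference reward prediction error that is
#' fed through the TAN-dopamine model, and the resulting phasic
#' dopamine integral updates the corticostriatal weights. The full
#' two-pathway network, spinal circuit and biomechanical arm of the
#' original reaching model are collapsed to a one-dimensional endpoint
#' abstraction that preserves the causal chain.
#'
#' @param n_actions Number of discrete candidate motor programs
#'   (endpoints evenly spaced over `action_span`).
#' @param target_position Target position on the 1-D axis.
#' @param trials_per_phase Named vector of trial counts for the
#'   `baseline`, `perturbation` and `aftereffect` phases.
#' @param n_sessions Number of sessions averaged.
#' @param noise_sd Standard deviation of the exploration noise added to
#'   the D1/D2 activations.
#' @param seed Random seed for the whole experiment.
#' @param alpha,ldopa Scenario context (deficiency, levodopa) shared by
#'   every trial.
#' @param stim_duration_ms Thalamic block duration per trial, ms.
#' @param horizon_ms Per-trial simulation horizon, ms (must cover the
#'   pause).
#' @param dt Integration step, ms.
#' @param action_span Range `c(min, max)` of the action endpoints; its
#'   width is the `error_max` of the reward function.
#' @param lambda1,lambda2,dw,init_weight Plasticity settings: base
#'   learning rates, per-trial degradation, and the uniform initial
#'   weight of both pathways.
#' @return An object of class `tan_task_config`.
#' @export
task_config <- function(n_actions = 9, target_position = 0.5,
                        trials_per_phase = c(baseline = 25,
                                             perturbation = 25,
                                             aftereffect = 25),
                        n_sessions = 8, noise_sd = 0.1, seed = 1,
                        alpha = 1, ldopa = 0,
                        stim_duration_ms = 300, horizon_ms = 2500,
                        dt = 1, action_span = c(-1, 1),
                        lambda1 = 0.4, lambda2 = 0.4, dw = 0.02,
                        init_weight = 0.5) {
  stopifnot(n_actions >= 2,
            all(c("baseline", "perturbation", "aftereffect") %in%
                  names(trials_per_phase)),
            all(trials_per_phase > 0),
            n_sessions >= 1, noise_sd >= 0,
            length(action_span) == 2, diff(action_span) > 0,
            horizon_ms > stim_duration_ms)
  structure(list(
    n_actions = n_actions, target_position = target_position,
    trials_per_phase = trials_per_phase, n_sessions = n_sessions,
    noise_sd = noise_sd, seed = seed, alpha = alpha, ldopa = ldopa,
    stim_duration_ms = stim_duration_ms, horizon_ms = horizon_ms,
    dt = dt, action_span = action_span,
    lambda1 = lambda1, lambda2 = lambda2, dw = dw,
    init_weight = init_weight
  ), class = "tan_task_config")
}

#' @export
print.tan_task_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<tan_task_config> %d actions on [%g, %g], target %g\n",
    "  %d sessions x %d trials (%s), alpha = %g, ldopa = %g, seed = %d\n"),
    x$n_actions, x$action_span[1], x$action_span[2], x$target_position,
    x$n_sessions, sum(x$trials_per_phase),
    paste(x$trials_per_phase, collapse = "/"), x$alpha, x$ldopa,
    x$seed))
  invisible(x)
}

#' Endpoints of the candidate motor programs
#' @param config A [task_config()].
#' @return Numeric vector of length `n_actions`.
#' @export
action_endpoints <- function(config) {
  seq(config$action_span[1], config$action_span[2],
      length.out = config$n_actions)
}

#' Select a movement endpoint from the learned weights
#'
#' D1 rates are the rectified cue-weighted direct-pathway input plus
#' exploration noise; D2 rates likewise for the indirect pathway; the
#' thalamocortical relay activation of each action is the rectified
#' difference `D1 - D2`, normalized to sum to one, and the executed
#' endpoint is the corresponding convex combination of action
#' endpoints. If every relay activation is zero (as at the symmetric
#' initial weights with no noise) the gate falls back to a uniform
#' combination.
#'
#' Uses R's global random number stream for the noise draws.
#'
#' @param weights A [weight_state()].
#' @param cue Cortical cue firing rates (length = rows of the weight
#'   matrices), non-negative.
#' @param endpoints Action endpoints (length = columns).
#' @param noise_sd Exploration noise standard deviation.
#' @return A list with `relay` (normalized activations), `endpoint`,
#'   `d1`, `d2`, and `fallback` (logical: uniform gate used).
#' @export
select_action <- function(weights, cue, endpoints, noise_sd = 0) {
  stopifnot(inherits(weights, "tan_weights"), all(cue >= 0),
            length(cue) == nrow(weights$w1),
            length(endpoints) == ncol(weights$w1))
  n <- length(endpoints)
  d1 <- pmax(0, as.vector(crossprod(weights$w1, cue)) +
               stats::rnorm(n, 0, noise_sd))
  d2 <- pmax(0, as.vector(crossprod(weights$w2, cue)) +
               stats::rnorm(n, 0, noise_sd))
  relay <- pmax(0, d1 - d2)
  fallback <- sum(relay) <= 0
  relay <- if (fallback) rep(1 / n, n) else relay / sum(relay)
  list(relay = relay, endpoint = sum(relay * endpoints),
       d1 = d1, d2 = d2, fallback = fallback)
}

#' Reward and temporal-difference reward prediction error
#'
#' During the perturbation phase the prism mirrors the task: the
#' rewarded target position flips sign about the starting axis, so the
#' action set that earns reward changes mid-experiment and error-based
#' correction is useless. The reward falls linearly from 1 (direct
#' hit) to 0 at `error_max` distance, and the reward prediction error
#' is the temporal difference between the current and previous reward,
#' clamped to `[-1, 1]`; the first trial of a session (no previous
#' reward) has zero prediction error.
#'
#' @param endpoint Executed movement endpoint.
#' @param target Configured (unperturbed) target position.
#' @param phase `"baseline"`, `"perturbation"` or `"aftereffect"`.
#' @param prev_reward Previous trial's reward in `[0, 1]`, or `NULL`
#'   on the first trial.
#' @param error_max Distance at which the reward reaches 0.
#' @return A list with `reward`, `rpe`, `actual_error` (signed distance
#'   to the effective target, which determines the reward) and
#'   `perceived_error` (sign-flipped during perturbation).
#' @examples
#' reward_and_rpe(0.5, 0.5, "baseline", prev_reward = 0.75)
#' @export
reward_and_rpe <- function(endpoint, target, phase, prev_reward = NULL,
                           error_max = 2) {
  phase <- match.arg(phase,
                     c("baseline", "perturbation", "aftereffect"))
  eff_target <- if (phase == "perturbation") -target else target
  actual_error <- endpoint - eff_target
  perceived_error <- if (phase == "perturbation") -actual_error else
    actual_error
  reward <- max(0, 1 - abs(actual_error) / error_max)
  rpe <- if (is.null(prev_reward)) 0 else
    min(1, max(-1, reward - prev_reward))
  list(reward = reward, rpe = rpe, actual_error = actual_error,
       perceived_error = perceived_error)
}

# one trial: action selection -> reward/RPE -> TAN-DA simulation ->
# pause-gated weight update; returns the updated weights and a record
run_trial <- function(weights, config, phase, prev_reward,
                      endpoints, params, cue) {
  sel <- select_action(weights, cue, endpoints, config$noise_sd)
  rr <- reward_and_rpe(sel$endpoint, config$target_position, phase,
                       prev_reward, error_max = diff(config$action_span))
  ctx <- scenario_context(rpe = rr$rpe, alpha = config$alpha,
                          ldopa = config$ldopa)
  stim <- stim_block(config$stim_duration_ms,
                     total_duration_ms = config$horizon_ms)
  trace <- simulate_tan(params, stim, ctx, dt = config$dt)
  pause <- detect_pause(trace)
  integral <- phasic_da_integral(trace)
  # post-competition MSN rates: the lateral inhibition of the full
  # two-pathway loop concentrates activity on the gated channels, so
  # plasticity credit follows the relay activations
  weights <- update_weights(weights,
                            population_rates(cue, sel$relay, sel$relay),
                            integral)
  record <- tibble::tibble(
    phase = phase, endpoint = sel$endpoint,
    actual_error = rr$actual_error,
    perceived_error = rr$perceived_error,
    reward = rr$reward, rpe = rr$rpe,
    tp_ms = pause$duration_ms, da_integral = integral,
    fallback = sel$fallback)
  list(weights = weights, record = record, reward = rr$reward)
}

run_session <- function(config, params, cue, endpoints) {
  n <- config$n_actions
  weights <- weight_state(
    matrix(config$init_weight, length(cue), n),
    matrix(config$init_weight, length(cue), n),
    lambda1 = config$lambda1, lambda2 = config$lambda2,
    dw = config$dw)
  prev_reward <- NULL
  phases <- rep(c("baseline", "perturbation", "aftereffect"),
                times = config$trials_per_phase[
                  c("baseline", "perturbation", "aftereffect")])
  records <- vector("list", length(phases))
  for (i in seq_along(phases)) {
    out <- run_trial(weights, config, phases[i], prev_reward,
                     endpoints, params, cue)
    weights <- out$weights
    prev_reward <- out$reward
    records[[i]] <- out$record
  }
  dplyr::bind_rows(records) |>
    dplyr::mutate(trial = dplyr::row_number(), .before = 1)
}

#' Run the seeded motor-adaptation experiment
#'
#' Runs `n_sessions` independent sessions (fresh weights each, one
#' shared random stream seeded once from `config$seed`) of the
#' three-phase task and returns every trial record. The per-trial-index
#' mean and standard error of the absolute error across sessions is
#' attached as the experiment summary (see [tidy.tan_experiment()]).
#'
#' @param config A [task_config()].
#' @param params A [model_params()] handed to the per-trial
#'   TAN-dopamine simulation.
#' @return A tibble of class `tan_experiment` with one row per trial:
#'   `session`, `trial`, `phase`, `endpoint`, `actual_error`,
#'   `perceived_error`, `reward`, `rpe`, `tp_ms`, `da_integral`,
#'   `fallback`; attributes `summary` and `config`.
#' @examples
#' \donttest{
#' ex <- run_experiment(task_config(n_sessions = 2, seed = 7))
#' tidy(ex)
#' }
#' @export
run_experiment <- function(config = task_config(),
                           params = model_params()) {
  stopifnot(inherits(config, "tan_task_config"))
  set.seed(config$seed)
  cue <- 1
  endpoints <- action_endpoints(config)
  sessions <- purrr::map(seq_len(config$n_sessions), function(s) {
    run_session(config, params, cue, endpoints) |>
      dplyr::mutate(session = s, .before = 1)
  })
  out <- dplyr::bind_rows(sessions)
  summ <- out |>
    dplyr::group_by(.data$trial, .data$phase) |>
    dplyr::summarise(
      mean_abs_error = mean(abs(.data$actual_error)),
      se_abs_error = stats::sd(abs(.data$actual_error)) /
        sqrt(dplyr::n()),
      .groups = "drop")
  attr(out, "summary") <- summ
  attr(out, "config") <- config
  class(out) <- c("tan_experiment", class(out))
  out
}

#' @export
print.tan_experiment <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<tan_experiment> %d sessions x %d trials, alpha = %g, ldopa = %g\n",
    cfg$n_sessions, sum(cfg$trials_per_phase), cfg$alpha, cfg$ldopa))
  NextMethod()
}
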