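test_that("transfer function gates at zero and follows tanh above", {
  expect_identical(sigma_gate(0), 0)
  expect_identical(sigma_gate(-1), 0)
  # (exp(2x)-1)/(exp(2x)+1) evaluated independently for x = 0.3
  expect_equal(sigma_gate(0.3), 0.2913126124515909, tolerance = 1e-12)
  expect_equal(sigma_gate(c(-2, 0, 1)), c(0, 0, tanh(1)))
  expect_error(sigma_gate(NaN), "finite")
  expect_error(sigma_gate(Inf), "finite")
})

test_that("derivatives vanish at the healthy rest point", {
  rest <- steady_state()
  # tanh(0.3) sits strictly between the h-current and sAHP thresholds,
  # so both current targets are zero and the point is self-consistent
  expect_gt(rest$v_tan, model_params()$theta_h)
  expect_lt(rest$v_tan, model_params()$theta_sahp)
  d <- derivatives(rest, t = 0, stimulus = stim_none())
  expect_true(all(abs(d) < 1e-12))
})

test_that("dopamine derivative follows the scenario algebra during a pause", {
  p <- model_params()
  paused <- tibble::tibble(v_tan = 0, i_sahp = -1, i_h = 0.5, da = 1)
  d_pos <- derivatives(paused, 0, p, stim_none(),
                       scenario_context(rpe = 1))
  expect_equal(d_pos[["da"]], (2 - 1) / p$tau_da)
  # 50% deficiency with maximally negative RPE drives dopamine to zero
  d_neg <- derivatives(paused, 0, p, stim_none(),
                       scenario_context(rpe = -1, alpha = 0.5))
  expect_equal(d_neg[["da"]], (0 - 1) / p$tau_da)
})

test_that("steady-state dopamine composes deficiency and levodopa", {
  expect_equal(steady_state()$da, 1)
  expect_equal(steady_state(context = scenario_context(alpha = 0.5))$da,
               0.5)
  expect_equal(
    steady_state(context = scenario_context(alpha = 0.5, ldopa = 0.5))$da,
    1)
  # the resting activity is rpe-independent (above nicotinic threshold)
  expect_equal(steady_state(context = scenario_context(rpe = 1))$da, 1)
  expect_equal(steady_state()$v_tan, tanh(0.3))
})

test_that("unstimulated integration stays pinned at the fixed point", {
  tr <- simulate_tan(stimulus = stim_none(2000))
  expect_lt(max(abs(tr$v_tan - tanh(0.3))), 1e-9)
  expect_lt(max(abs(tr$da - 1)), 1e-9)
  expect_lt(max(abs(tr$i_sahp)), 1e-9)
  expect_lt(max(abs(tr$i_h)), 1e-9)
})

test_that("zero reward prediction error leaves dopamine at baseline", {
  tr <- simulate_tan(stimulus = stim_block(300),
                     context = scenario_context(rpe = 0))
  expect_lt(max(abs(tr$da - 1)), 1e-6)
  tr2 <- simulate_tan(stimulus = stim_pulse_train(),
                      context = scenario_context(rpe = 0))
  expect_lt(max(abs(tr2$da - 1)), 1e-6)
})

test_that("activity stays in [0, 1) across scenario presets", {
  grid <- expand.grid(rpe = c(-1, 0, 1), alpha = c(1, 0.5),
                      ldopa = c(0, 0.5))
  for (i in seq_len(nrow(grid))) {
    tr <- simulate_tan(
      stimulus = stim_block(300, total_duration_ms = 2500),
      context = scenario_context(grid$rpe[i], grid$alpha[i],
                                 grid$ldopa[i]))
    expect_true(all(tr$v_tan >= 0 & tr$v_tan < 1))
    expect_true(all(tr$da >= 0))
  }
})

test_that("an unstable step size is rejected with advice", {
  expect_error(
    simulate_tan(stimulus = stim_block(300, total_duration_ms = 2000),
                 dt = 300),
    "smaller dt")
})

test_that("pause detector measures a synthetic square pause exactly", {
  t <- seq(0, 2000, by = 1)
  v <- ifelse(t >= 500 & t < 900, 0, 0.29)
  p <- detect_pause(synthetic_trace(t, v), threshold = 0.26)
  expect_equal(p$duration_ms, 400)
  expect_equal(p$onset_ms, 500)
  expect_equal(p$offset_ms, 900)
  expect_false(p$censored)
})

test_that("a flat resting trace has no pause", {
  t <- seq(0, 1000, by = 1)
  p <- detect_pause(synthetic_trace(t, rep(tanh(0.3), length(t))))
  expect_equal(p$duration_ms, 0)
  expect_true(is.na(p$onset_ms))
})

test_that("a non-recovering pause is censored with a warning", {
  t <- seq(0, 1000, by = 1)
  v <- ifelse(t >= 400, 0, 0.29)
  expect_warning(
    p <- detect_pause(synthetic_trace(t, v), threshold = 0.26),
    "censored")
  expect_true(p$censored)
  expect_equal(p$duration_ms, 600)
})

test_that("pause duration increases with reward prediction error", {
  tp <- vapply(c(-1, 0, 1), function(r) {
    tr <- simulate_tan(stimulus = stim_block(300),
                       context = scenario_context(rpe = r))
    detect_pause(tr)$duration_ms
  }, numeric(1))
  expect_lt(tp[1], tp[2])
  expect_lt(tp[2], tp[3])
})

test_that("dopamine approaches baseline + RPE during a long pause", {
  tr <- simulate_tan(stimulus = stim_block(300),
                     context = scenario_context(rpe = 1))
  p <- detect_pause(tr)
  expect_gt(p$max_da, 2 * 0.99)
  expect_lte(p$max_da, 2)
})

test_that("phasic dopamine integral has the sign and order of the RPE", {
  tr <- function(r) simulate_tan(stimulus = stim_block(300),
                                 context = scenario_context(rpe = r))
  i0 <- phasic_da_integral(tr(0))
  ip <- phasic_da_integral(tr(1))
  im <- phasic_da_integral(tr(-1))
  expect_lt(abs(i0), 1e-3)
  expect_gt(ip, 0)
  expect_lt(im, 0)
  # the positive excursion lasts longer (longer pause), so it dominates
  expect_gt(abs(ip), abs(im))
})

test_that("halving the step changes the pause duration by under 2%", {
  for (r in c(-1, 0, 1)) {
    ctx <- scenario_context(rpe = r)
    tp1 <- detect_pause(simulate_tan(stimulus = stim_block(300),
                                     context = ctx, dt = 1))$duration_ms
    tp05 <- detect_pause(simulate_tan(stimulus = stim_block(300),
                                      context = ctx,
                                      dt = 0.5))$duration_ms
    expect_lt(abs(tp1 - tp05) / tp05, 0.02)
  }
})

test_that("Euler trace agrees with the adaptive-step oracle", {
  skip_if_not_installed("deSolve")
  params <- model_params()
  stim <- stim_block(300, total_duration_ms = 4000)
  ctx <- scenario_context(rpe = 1)
  euler <- simulate_tan(params, stim, ctx, dt = 0.01)
  ref <- oracle_trace(params, stim, ctx, dt_out = 0.5)
  tp_euler <- detect_pause(euler)$duration_ms
  tp_ref <- detect_pause(ref)$duration_ms
  expect_lt(abs(tp_euler - tp_ref) / tp_ref, 0.005)
  # pointwise agreement of the dopamine trace on the shared grid
  shared <- euler$t_ms %in% ref$t_ms
  expect_lt(max(abs(euler$da[shared] - ref$da[ref$t_ms %in% euler$t_ms])),
            0.01)
})

test_that("invalid parameters and contexts are rejected", {
  expect_error(model_params(tau_tan = 0), "strictly positive")
  expect_error(model_params(g_h = -1), "non-negative")
  expect_warning(model_params(theta_da = 0.25), "regime")
  expect_warning(scenario_context(rpe = 2), "clamped")
  expect_error(scenario_context(alpha = 1.5), "0, 1")
  expect_error(scenario_context(ldopa = -0.1), "non-negative")
  expect_error(stimulus_protocol(cbind(c(0, 100), c(150, 200)), 500),
               "overlap")
  expect_error(stimulus_protocol(cbind(0, 600), 500), "contained")
})
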