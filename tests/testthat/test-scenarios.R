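test_that("condition presets carry the published overrides", {
  expect_identical(pharmacology_condition("control")$overrides,
                   list())
  expect_identical(pharmacology_condition("sulpiride")$overrides,
                   list(w_da = 0))
  expect_identical(pharmacology_condition("cocaine")$overrides,
                   list(da0 = 3))
  expect_identical(pharmacology_condition("h_block")$overrides,
                   list(g_h = 0))
  expect_error(pharmacology_condition("reserpine"),
               "control, sulpiride, cocaine, h_block")
})

test_that("presets never mutate the caller's parameters", {
  params <- model_params()
  before <- unclass(params)
  invisible(run_condition("sulpiride",
                          stim_block(100, total_duration_ms = 1500),
                          params = params))
  expect_identical(unclass(params), before)
})

test_that("pharmacology orders the pause as in the slice experiments", {
  pt <- stim_pulse_train(total_duration_ms = 6000)
  tp <- vapply(c("sulpiride", "control", "cocaine", "h_block"),
               function(cn) run_condition(cn, pt)$pause$duration_ms,
               numeric(1))
  # D2 blockade maximizes the h-current and shortens the pause;
  # raised tonic dopamine suppresses it; h-current blockade removes
  # the recovery drive entirely
  expect_lt(tp[["sulpiride"]], tp[["control"]])
  expect_lt(tp[["control"]], tp[["cocaine"]])
  expect_lt(tp[["cocaine"]], tp[["h_block"]])
})

test_that("cocaine on top of deficiency warns about composition", {
  expect_warning(
    run_condition("cocaine", stim_block(100, total_duration_ms = 6000),
                  context = scenario_context(alpha = 0.5)),
    "multiplicatively")
})

test_that("a single-cell sweep equals the direct run", {
  sw <- sweep_stim_duration(300, rpe_levels = 1)
  expect_equal(nrow(sw), 1L)
  direct <- run_condition("control",
                          stim_block(300, total_duration_ms = 4300),
                          scenario_context(rpe = 1))
  expect_equal(sw$tp_ms, direct$pause$duration_ms)
})

test_that("pause duration grows with stimulus duration", {
  sw <- sweep_stim_duration(c(100, 250, 400), rpe_levels = c(-1, 1))
  for (r in c(-1, 1)) {
    tp <- sw$tp_ms[sw$rpe == r]
    expect_true(all(diff(tp) >= 0))
  }
  tp_by <- tidyr::pivot_wider(tidy(sw), names_from = "rpe",
                              values_from = "tp_ms")
  expect_true(all(diff(tp_by$`1` - tp_by$`-1`) > 0))
})

test_that("the healthy column of the deficiency sweep matches control", {
  sw <- sweep_deficiency(alphas = c(1, 0.5), rpe_levels = 1)
  healthy <- run_condition("control", stim_block(300),
                           scenario_context(rpe = 1))
  expect_equal(sw$tp_ms[sw$axis_value == 0],
               healthy$pause$duration_ms)
  expect_lt(sw$tp_ms[sw$axis_value == 50],
            sw$tp_ms[sw$axis_value == 0])
})

test_that("levodopa lengthens the pause and composes with deficiency", {
  sw <- sweep_ldopa(c(0, 0.5), alpha = 0.5, rpe_levels = c(-1, 1))
  for (r in c(-1, 1)) {
    tp <- sw$tp_ms[sw$rpe == r]
    expect_lt(tp[1], tp[2])
  }
  only_def <- sweep_deficiency(alphas = 0.5, rpe_levels = c(-1, 1))
  expect_equal(sw$tp_ms[sw$axis_value == 0], only_def$tp_ms)
})

test_that("steady-state dopamine is alpha * da0 + ldopa on a grid", {
  grid <- expand.grid(alpha = c(0, 0.3, 0.7, 1), ldopa = c(0, 0.4, 1))
  for (i in seq_len(nrow(grid))) {
    ctx <- scenario_context(alpha = grid$alpha[i],
                            ldopa = grid$ldopa[i])
    expect_equal(steady_state(context = ctx)$da,
                 grid$alpha[i] * 1 + grid$ldopa[i])
  }
})

test_that("sweep tables serialize losslessly", {
  sw <- sweep_stim_duration(c(150, 300), rpe_levels = c(0, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, path)
  back <- read_sweep(path)
  expect_identical(back$tp_ms, sw$tp_ms)
  expect_identical(back$axis_value, sw$axis_value)
})
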