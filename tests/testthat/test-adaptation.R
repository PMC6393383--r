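small_config <- function(...) {
  task_config(trials_per_phase = c(baseline = 4, perturbation = 4,
                                   aftereffect = 4),
              n_sessions = 2, horizon_ms = 2500, ...)
}

test_that("symmetric weights with no noise fall back to a uniform gate", {
  w <- weight_state(matrix(0.5, 1, 5), matrix(0.5, 1, 5))
  eps <- seq(-1, 1, length.out = 5)
  sel <- select_action(w, cue = 1, endpoints = eps, noise_sd = 0)
  expect_true(sel$fallback)
  expect_equal(sel$relay, rep(0.2, 5))
  expect_equal(sel$endpoint, mean(eps))
})

test_that("a dominant direct-pathway column wins the gate outright", {
  w1 <- matrix(0, 1, 5); w1[1, 4] <- 1
  w <- weight_state(w1, matrix(0, 1, 5))
  eps <- seq(-1, 1, length.out = 5)
  sel <- select_action(w, cue = 1, endpoints = eps, noise_sd = 0)
  expect_false(sel$fallback)
  expect_equal(sel$endpoint, eps[4])
})

test_that("reward falls linearly with distance and RPE is a clamped difference", {
  hit <- reward_and_rpe(0.5, 0.5, "baseline", prev_reward = 1)
  expect_equal(hit$reward, 1)
  expect_equal(hit$rpe, 0)
  step <- reward_and_rpe(0.1, 0.5, "baseline", prev_reward = 0.3,
                         error_max = 2)
  expect_equal(step$reward, 0.8)
  expect_equal(step$rpe, 0.5)
  crash <- reward_and_rpe(2.5, 0.5, "baseline", prev_reward = 1,
                          error_max = 2)
  expect_equal(crash$reward, 0)
  expect_equal(crash$rpe, -1)
  first <- reward_and_rpe(0.2, 0.5, "baseline", prev_reward = NULL)
  expect_equal(first$rpe, 0)
})

test_that("the perturbation mirrors the rewarded target and the percept", {
  rr <- reward_and_rpe(0.5, 0.5, "perturbation", prev_reward = NULL,
                       error_max = 2)
  # endpoint at the old target is now a full target-width off
  expect_equal(rr$actual_error, 1)
  expect_equal(rr$perceived_error, -1)
  expect_equal(rr$reward, 0.5)
  hit <- reward_and_rpe(-0.5, 0.5, "perturbation", prev_reward = NULL)
  expect_equal(hit$reward, 1)
})

test_that("an experiment is reproducible bit-for-bit under its seed", {
  a <- run_experiment(small_config(seed = 11))
  b <- run_experiment(small_config(seed = 11))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- run_experiment(small_config(seed = 12))
  expect_false(identical(a$endpoint, c$endpoint))
})

test_that("phase bookkeeping yields the configured trial counts", {
  ex <- run_experiment(small_config(seed = 3))
  counts <- table(ex$session, ex$phase)
  expect_true(all(counts == 4))
  expect_equal(nrow(ex), 2 * 12)
  expect_true(all(ex$rpe >= -1 & ex$rpe <= 1))
  # first trial of each session has no previous reward
  firsts <- ex[ex$trial == 1, ]
  expect_true(all(firsts$rpe == 0))
})

test_that("per-trial records carry the pause-gated dopamine signal", {
  ex <- run_experiment(small_config(seed = 5))
  expect_true(all(ex$tp_ms > 0))
  pos <- ex$rpe > 0.01
  neg <- ex$rpe < -0.01
  expect_true(all(ex$da_integral[pos] > 0))
  expect_true(all(ex$da_integral[neg] < 0))
  expect_lt(max(abs(ex$da_integral[ex$rpe == 0])), 1e-6)
})

test_that("tidy and glance summarise an experiment", {
  ex <- run_experiment(small_config(seed = 2))
  td <- tidy(ex)
  expect_equal(nrow(td), 12)
  expect_named(td, c("trial", "phase", "mean_abs_error",
                     "se_abs_error"))
  gl <- glance(ex)
  expect_equal(gl$n_sessions, 2)
  expect_equal(gl$alpha, 1)
})
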