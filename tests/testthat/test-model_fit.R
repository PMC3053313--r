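inert_params <- function() {
  list(retention = 0.99, process_noise_var = 0.01,
       observation_noise_var = 1, actor_lr = 0, critic_lr = 0,
       discount = 0.9, motor_cost_scale = 0)
}

test_that("an inert model leaves everything in the residual", {
  sim <- quick_sim("RWD", seed = 1)
  ff <- forward_filter(sim$trials, inert_params(), "RWD")
  expect_true(all(ff$x_p == 0))
  expect_true(all(ff$x_r == 0))
  expect_equal(ff$eta, sim$trials$reach_deg)
  expect_equal(ff$sse, sum(sim$trials$reach_deg^2))
})

test_that("the sensory channel is clamped off for reward-only fits", {
  sim <- quick_sim("RWD", seed = 2)
  params <- inert_params()
  params$actor_lr <- 0.1; params$critic_lr <- 0.1
  params$observation_noise_var <- 0.001  # would give gain ~1 if honoured
  ff <- forward_filter(sim$trials, params, "RWD")
  expect_true(all(ff$x_p == 0))
})

test_that("filter input validation catches malformed series", {
  sim <- quick_sim("ERR", seed = 1)
  expect_error(forward_filter(sim$trials[, c("trial", "reach_deg")],
                              inert_params(), "ERR"), "missing columns")
  expect_error(fit_subject(sim$trials[1:30, ], "ERR"), "fewer than 50")
})

test_that("filtering a noiseless-execution run recovers the generating trajectories", {
  cond <- feedback_condition("ERR", observation_noise_sd = 0)
  params <- learner_params(cond, motor_noise_sd = 0, search_noise_sd = 1,
                           observation_noise_var = 1)
  sim <- run_condition(params, build_schedule("EXP1"), cond,
                       reward_geometry(), seed = 5)
  ff <- forward_filter(sim$trials, params, cond)
  expect_equal(ff$x_p, -sim$trials$p_hat_pre_deg, tolerance = 1e-12)
  expect_equal(ff$x_r, sim$trials$x_r_pre_deg, tolerance = 1e-12)
  expect_equal(ff$eta, sim$trials$eta_deg, tolerance = 1e-12)
})

test_that("refitting a noiseless forward simulation attains near-zero error", {
  cond <- feedback_condition("ERR", observation_noise_sd = 0)
  params <- learner_params(cond, motor_noise_sd = 0, search_noise_sd = 0,
                           observation_noise_var = 1)
  sim <- run_condition(params, build_schedule("EXP1"), cond,
                       reward_geometry(), seed = 5)
  fit <- fit_subject(sim$trials, cond, n_starts = 8, seed = 2)
  expect_lt(fit$sse, 1e-6)
})

test_that("the objective equals the summed squared residuals", {
  sim <- quick_sim("EPE", seed = 3)
  fit <- fit_subject(sim$trials, "EPE", n_starts = 4, seed = 1)
  expect_equal(fit$sse, sum(residuals(fit)^2), tolerance = 1e-9)
  expect_equal(fit$search_noise_var_hat, fit$sse / nrow(sim$trials))
  expect_equal(fitted(fit) + residuals(fit), sim$trials$reach_deg,
               tolerance = 1e-9)
})

test_that("fits are deterministic given the seed", {
  sim <- quick_sim("RWD", seed = 4)
  f1 <- fit_subject(sim$trials, "RWD", n_starts = 4, seed = 9)
  f2 <- fit_subject(sim$trials, "RWD", n_starts = 4, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$sse, f2$sse)
})

test_that("reward-learning rate is recoverable to within half its value", {
  errs <- vapply(1:20, function(s) {
    sim <- quick_sim("RWD", seed = s)
    fit <- fit_subject(sim$trials, "RWD", n_starts = 6, seed = 1)
    abs(coef(fit)[["actor_lr"]] - 0.15) / 0.15
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("decompose reports terminal memory means and residual variance", {
  sim <- quick_sim("RWD", seed = 1)
  ffit <- fit_subject(sim$trials, "RWD", n_starts = 4, seed = 1)
  d <- decompose(ffit, window = 80)
  expect_equal(d$x_p_final, 0)
  expect_equal(d$search_noise_var, ffit$sse / nrow(sim$trials))
  expect_error(decompose(ffit, window = 10000), "window")

  # alternative third-parameter mapping is a configuration switch
  sim2 <- quick_sim("EPE", seed = 2)
  f3 <- fit_subject(sim2$trials, "EPE", n_starts = 4, seed = 1,
                    config = fit_config(third = "critic_lr"))
  expect_setequal(names(coef(f3)), c("sigma_y2", "actor_lr", "critic_lr"))
})

test_that("simulate() regenerates series with the fitted statistics", {
  sim <- quick_sim("RWD", seed = 6)
  fit <- fit_subject(sim$trials, "RWD", n_starts = 4, seed = 1)
  new <- simulate(fit, nsim = 2, seed = 3)
  expect_length(new, 2)
  expect_equal(nrow(new[[1]]), nrow(sim$trials))
  expect_equal(new[[1]]$rotation_deg, sim$trials$rotation_deg)
  expect_false(identical(new[[1]]$reach_deg, new[[2]]$reach_deg))
})
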