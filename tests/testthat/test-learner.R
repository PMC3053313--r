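test_that("action selection sums target compensation, policy memory and search noise", {
  p0 <- learner_params(search_noise_sd = 0)
  st <- init_learner_state()
  expect_equal(select_action(st, p0, target = 0)$motor_command, 0)
  st$p_hat <- 8
  expect_equal(select_action(st, p0, target = 0)$motor_command, -8)
  st$p_hat <- 0; st$x_r <- -8
  expect_equal(select_action(st, p0, target = 0)$motor_command, -8)
  # same command from two different memories: the model's central dissociation
  st$p_hat <- 8; st$x_r <- 0
  a <- select_action(st, p0, target = 0)
  st$p_hat <- 0; st$x_r <- -8
  b <- select_action(st, p0, target = 0)
  expect_equal(a$motor_command, b$motor_command)
})

test_that("Kalman gain is the uncertainty ratio, in [0,1], monotone in noise", {
  expect_equal(kalman_gain(1, 1), 0.5)
  expect_equal(kalman_gain(1, Inf), 0)
  expect_equal(kalman_gain(1, 0), 1)
  expect_error(kalman_gain(0, 0))
  s2 <- c(0.1, 1, 10, 100, 1e4)
  gains <- vapply(s2, function(s) kalman_gain(2, s), numeric(1))
  expect_true(all(diff(gains) < 0))
  expect_true(all(gains >= 0 & gains <= 1))
})

test_that("estimator performs exact one-step credit and ignores absent observations", {
  params <- learner_params(retention = 1, process_noise_var = 0,
                           observation_noise_var = 0)
  st <- init_learner_state(p_hat = 0, est_uncertainty = 1)
  st <- estimator_step(st, params, motor_command = 0, observed_cursor = 8)
  expect_equal(st$p_hat, 8)

  params_na <- learner_params(observation_noise_var = NA)
  st <- init_learner_state()
  for (k in 1:50) {
    st <- estimator_step(st, params_na, motor_command = -3,
                         observed_cursor = NA)
  }
  expect_identical(st$p_hat, 0)
  expect_error(estimator_step(st, params, 0, Inf))
})

test_that("estimator converges to a constant discrepancy at steady state", {
  # constant y - u = 8 over 400 steps
  z <- rep(8, 400)
  got <- run_estimator(z, A = 1, q = 0.01, s2 = 1)
  expect_lt(abs(got$m[400] - 8), 0.5)
  want <- oracle_gaussian_filter(z, A = 1, q = 0.01, s2 = 1)
  expect_equal(got$m, want$m, tolerance = 1e-12)
})

test_that("Kalman recursion matches an independent Gaussian-posterior filter", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(20:50, 1)
    A <- runif(1, 0.8, 1)
    q <- runif(1, 0, 0.5)
    s2 <- runif(1, 0.05, 20)
    z <- rnorm(n, mean = runif(1, -8, 8), sd = 2)
    z[runif(n) < 0.2] <- NA  # intermittent feedback
    got <- run_estimator(z, A, q, s2)
    want <- oracle_gaussian_filter(z, A, q, s2)
    expect_equal(got$m, want$m, tolerance = 1e-9)
    expect_equal(got$P, want$P, tolerance = 1e-9)
  }
})

test_that("temporal-difference step reinforces the explored direction", {
  params <- learner_params(actor_lr = 0.1, critic_lr = 0.1, discount = 0)
  st <- init_learner_state()
  st$v <- 1; st$last_search_noise <- 2
  st2 <- td_step(st, params, reward_received = 1)  # delta = 1 - 1 = 0
  expect_equal(st2$x_r, st$x_r)
  expect_equal(st2$v, st$v)

  st <- init_learner_state()
  st$last_search_noise <- 1
  st2 <- td_step(st, params, reward_received = 1)  # delta = 1
  expect_equal(st2$x_r, 0.1)
  expect_equal(st2$v, 0.1)
})

test_that("actor-critic climbs onto a gradually displaced reward zone", {
  # zone centre moves from 0 to -8 in unit steps, then holds: the policy
  # memory alone (no estimator) must end inside the final zone [-11, -5]
  params <- learner_params(search_noise_sd = 1, actor_lr = 0.15,
                           critic_lr = 0.15, discount = 0,
                           motor_cost_scale = 0)
  set.seed(9)
  st <- init_learner_state()
  centres <- c(rep(0, 200), rep(-(1:8), each = 100), rep(-8, 1000))
  u_hist <- numeric(length(centres))
  for (k in seq_along(centres)) {
    act <- select_action(st, params, target = 0)
    st <- act$state
    u_hist[k] <- act$motor_command
    r <- as.numeric(abs(act$motor_command - centres[k]) <= 3)
    st <- td_step(st, params, r)
  }
  final_mean <- mean(u_hist[(length(centres) - 199):length(centres)])
  expect_gte(final_mean, -11)
  expect_lte(final_mean, -5)
})

test_that("a full trial composes the task and both updates", {
  geom <- reward_geometry(motor_cost_scale = 0)
  cond0 <- feedback_condition("ERR", observation_noise_sd = 0)
  params0 <- learner_params(cond0, motor_noise_sd = 0, search_noise_sd = 0,
                            observation_noise_var = 0)
  set.seed(1)
  out <- learner_trial(init_learner_state(), params0, cond0, geom,
                       rotation = 0)
  expect_equal(out$record$reach_deg, 0)
  expect_equal(out$record$rewarded, 1L)
  expect_equal(out$state$p_hat, 0)
  expect_equal(out$state$x_r, 0)
  expect_true(out$state$v != 0)  # critic drifts toward the reward

  # single-step full credit under perfect vision
  out2 <- learner_trial(init_learner_state(), params0, cond0, geom,
                        rotation = 8)
  expect_equal(out2$state$p_hat, 8)

  # reward-only trial: no observation, no estimator update
  condr <- feedback_condition("RWD")
  paramsr <- learner_params(condr)
  set.seed(2)
  out3 <- learner_trial(init_learner_state(), paramsr, condr, geom,
                        rotation = 8)
  expect_true(is.na(out3$record$observed_deg))
  expect_identical(out3$state$p_hat, 0)
})

test_that("commands stay bounded under every default configuration", {
  for (lab in c("ERR", "EPE", "RWD")) {
    for (seed in 1:3) {
      sim <- quick_sim(lab, seed)
      expect_true(all(abs(sim$trials$command_deg) <= 45))
    }
  }
})
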