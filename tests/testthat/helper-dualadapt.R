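# Independently coded scalar Gaussian-posterior filter: conjugate
# precision-weighted updates, no Kalman-gain algebra. z is the sequence of
# direct (noisy) perturbation observations (NA = no observation).
oracle_gaussian_filter <- function(z, A, q, s2, m0 = 0, P0 = 1) {
  m <- m0
  P <- P0
  ms <- numeric(length(z))
  Ps <- numeric(length(z))
  for (k in seq_along(z)) {
    m_pred <- A * m
    P_pred <- A^2 * P + q
    if (is.na(z[k])) {
      m <- m_pred
      P <- P_pred
    } else {
      P <- 1 / (1 / P_pred + 1 / s2)
      m <- P * (m_pred / P_pred + z[k] / s2)
    }
    ms[k] <- m
    Ps[k] <- P
  }
  list(m = ms, P = Ps)
}

# Run the package estimator over the same observation sequence.
run_estimator <- function(z, A, q, s2, m0 = 0, P0 = 1) {
  params <- learner_params(retention = A, process_noise_var = q,
                           observation_noise_var = s2)
  state <- init_learner_state(p_hat = m0, est_uncertainty = P0)
  ms <- numeric(length(z))
  Ps <- numeric(length(z))
  for (k in seq_along(z)) {
    # feed z as an observed cursor with motor command 0 (y - u = z)
    state <- estimator_step(state, params, motor_command = 0,
                            observed_cursor = z[k])
    ms[k] <- state$p_hat
    Ps[k] <- state$est_uncertainty
  }
  list(m = ms, P = Ps)
}

quick_sim <- function(label, seed, experiment = "EXP1", params = NULL, ...) {
  cond <- feedback_condition(label, ...)
  if (is.null(params)) params <- learner_params(cond)
  run_condition(params, build_schedule(experiment), cond, reward_geometry(),
                seed = seed)
}

# Minimal adapt_sim wrapper around a hand-built trial table.
fake_sim <- function(reach, phase, rewarded = rep(1L, length(reach)),
                     p_hat = rep(0, length(reach))) {
  structure(
    list(trials = data.frame(
      trial = seq_along(reach), phase = phase, reach_deg = reach,
      rewarded = rewarded, p_hat_deg = p_hat
    )),
    class = "adapt_sim"
  )
}
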