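#' Parameters of the dual-error learner
#'
#' Collects every constant of the model: the perturbation prior (retention
#' \code{A} and process noise \code{q}), the assumed observation noise of
#' the visual channel, the passive motor noise, the active search noise of
#' the policy, the actor/critic learning rates, the reward discount and the
#' motor-cost scale.
#'
#' When a [feedback_condition()] is supplied, the observation-noise variance
#' is taken from it and the search-noise SD defaults to a condition-typical
#' magnitude (0.5 for ERR, 1 for EPE, 1.5 for RWD): with poorer visual
#' feedback the learner must lean on reward and explores more. All values
#' are overridable.
#'
#' @param condition optional [feedback_condition()] supplying
#'   condition-typical defaults.
#' @param retention retention factor \code{A} of the perturbation prior,
#'   in (0, 1].
#' @param process_noise_var variance, deg^2, of the trial-to-trial drift the
#'   learner attributes to the perturbation.
#' @param observation_noise_var variance, deg^2, of the visual observation;
#'   \code{NA} when there is no observation channel (RWD).
#' @param motor_noise_sd SD, degrees, of passive execution noise on the hand.
#' @param search_noise_sd SD, degrees, of the active search noise added to
#'   the command to explore for reward.
#' @param actor_lr,critic_lr actor and critic learning rates in [0, 1].
#' @param discount temporal-difference reward discount in [0, 1).
#' @param motor_cost_scale motor cost scale used in the reward the learner
#'   optimizes (kept equal to the task's [reward_geometry()] scale).
#' @return object of class \code{"learner_params"}.
#' @examples
#' learner_params(feedback_condition("RWD"))
#' @export
learner_params <- function(condition = NULL,
                           retention = 0.99,
                           process_noise_var = 0.01,
                           observation_noise_var = NULL,
                           motor_noise_sd = 1,
                           search_noise_sd = NULL,
                           actor_lr = 0.15,
                           critic_lr = 0.15,
                           discount = 0.9,
                           motor_cost_scale = 0.001) {
  if (!is.null(condition)) {
    stopifnot(inherits(condition, "feedback_condition"))
    if (is.null(observation_noise_var)) {
      observation_noise_var <- if (condition$label == "RWD") NA_real_ else
        condition$observation_noise_sd^2
    }
    if (is.null(search_noise_sd)) {
      search_noise_sd <- switch(condition$label,
                                ERR = 0.5, EPE = 1, RWD = 1.5)
    }
  }
  if (is.null(observation_noise_var)) observation_noise_var <- 1
  if (is.null(search_noise_sd)) search_noise_sd <- 0.5
  stopifnot(
    retention > 0, retention <= 1,
    process_noise_var >= 0,
    is.na(observation_noise_var) || observation_noise_var >= 0,
    motor_noise_sd >= 0, search_noise_sd >= 0,
    actor_lr >= 0, actor_lr <= 1,
    critic_lr >= 0, critic_lr <= 1,
    discount >= 0, discount < 1,
    motor_cost_scale >= 0
  )
  structure(
    list(
      retention = retention,
      process_noise_var = process_noise_var,
      observation_noise_var = observation_noise_var,
      motor_noise_sd = motor_noise_sd,
      search_noise_sd = search_noise_sd,
      actor_lr = actor_lr,
      critic_lr = critic_lr,
      discount = discount,
      motor_cost_scale = motor_cost_scale
    ),
    class = "learner_params"
  )
}

#' @export
print.learner_params <- function(x, ...) {
  cat("Dual-error learner parameters\n")
  cat(sprintf("  perturbation prior: A = %g, q = %g deg^2\n",
              x$retention, x$process_noise_var))
  cat(sprintf("  observation noise var: %s deg^2\n",
              if (is.na(x$observation_noise_var)) "absent (gain 0)"
              else format(x$observation_noise_var)))
  cat(sprintf("  motor noise SD: %g deg, search noise SD: %g deg\n",
              x$motor_noise_sd, x$search_noise_sd))
  cat(sprintf("  actor lr: %g, critic lr: %g, discount: %g, motor cost: %g\n",
              x$actor_lr, x$critic_lr, x$discount, x$motor_cost_scale))
  invisible(x)
}

#' Initial state of the learner
#'
#' The learner starts naive: perturbation estimate 0, estimation uncertainty
#' 1 deg^2, reward-driven policy memory 0, critic value 0.
#'
#' @param p_hat initial perturbation estimate, degrees.
#' @param est_uncertainty initial estimation variance, deg^2.
#' @param x_r initial reward-driven policy offset, degrees.
#' @param v initial critic value.
#' @return object of class \code{"learner_state"}; also carries
#'   \code{last_search_noise} and \code{h_hat} (estimated hand position).
#' @export
init_learner_state <- function(p_hat = 0, est_uncertainty = 1, x_r = 0,
                               v = 0) {
  stopifnot(est_uncertainty >= 0)
  structure(
    list(
      p_hat = p_hat,
      est_uncertainty = est_uncertainty,
      x_r = x_r,
      v = v,
      last_search_noise = 0,
      h_hat = 0
    ),
    class = "learner_state"
  )
}

#' Select a motor command
#'
#' The command aims at the target, compensates the estimated perturbation,
#' adds the reward-driven policy offset and a Gaussian active search noise:
#' \deqn{u = (t - \hat p) + x_r + \eta,\quad \eta \sim N(0, \sigma_\eta^2).}
#' The realized search noise is stored in the returned state for the
#' subsequent temporal-difference update.
#'
#' @param state a \code{"learner_state"}.
#' @param params a [learner_params()].
#' @param target target direction, degrees.
#' @return list with \code{motor_command}, \code{eta} and the updated
#'   \code{state}.
#' @export
select_action <- function(state, params, target = 0) {
  eta <- stats::rnorm(1, sd = params$search_noise_sd)
  u <- (target - state$p_hat) + state$x_r + eta
  state$last_search_noise <- eta
  list(motor_command = u, eta = eta, state = state)
}

#' Kalman gain of the perturbation estimator
#'
#' \deqn{K = P^- / (P^- + \sigma_y^2)} where \eqn{P^-} is the prior
#' estimation uncertainty and \eqn{\sigma_y^2} the observation-noise
#' variance. The gain lies in [0, 1] and decreases as the observation
#' becomes less reliable.
#'
#' @param est_uncertainty_prior prior estimation variance, deg^2.
#' @param observation_noise_var observation-noise variance, deg^2; may be
#'   \code{Inf} (gain 0).
#' @return the gain, dimensionless in [0, 1].
#' @export
kalman_gain <- function(est_uncertainty_prior, observation_noise_var) {
  stopifnot(est_uncertainty_prior >= 0, observation_noise_var >= 0)
  if (est_uncertainty_prior == 0 && observation_noise_var == 0) {
    stop("degenerate input: prior uncertainty and observation noise both 0")
  }
  if (is.infinite(observation_noise_var)) return(0)
  est_uncertainty_prior / (est_uncertainty_prior + observation_noise_var)
}

#' One estimator step (forward model + Kalman filter)
#'
#' Time update of the perturbation estimate under the prior
#' (\eqn{\hat p^- = A \hat p}, \eqn{P^- = A^2 P + q}), followed, when an
#' observation is present, by a measurement update using the sensory
#' prediction error \eqn{e = y - (u + \hat p^-)} (observed cursor minus the
#' cursor predicted from the efference copy):
#' \deqn{\hat p \gets \hat p^- + K e, \qquad P \gets (1 - K) P^-.}
#' With no observation (RWD) the gain is zero and the estimate is propagated
#' unchanged. The estimated hand position is \eqn{\hat h = y - \hat p} when
#' a cursor was seen (the percept is drawn toward the cursor by exactly the
#' discrepancy not yet credited to the perturbation), else the efference
#' copy \eqn{\hat h = u}.
#'
#' @param state a \code{"learner_state"}.
#' @param params a [learner_params()].
#' @param motor_command the command \code{u} just executed, degrees.
#' @param observed_cursor observed cursor angle, degrees, or \code{NA} when
#'   no observation was delivered.
#' @return the updated \code{"learner_state"}.
#' @export
estimator_step <- function(state, params, motor_command, observed_cursor) {
  if (!is.na(observed_cursor) && !is.finite(observed_cursor)) {
    stop("observed_cursor must be finite or NA")
  }
  A <- params$retention
  p_prior <- A * state$p_hat
  P_prior <- A^2 * state$est_uncertainty + params$process_noise_var
  if (is.na(observed_cursor) || is.na(params$observation_noise_var)) {
    state$p_hat <- p_prior
    state$est_uncertainty <- P_prior
    state$h_hat <- motor_command
  } else {
    K <- kalman_gain(P_prior, params$observation_noise_var)
    e <- observed_cursor - (motor_command + p_prior)
    state$p_hat <- p_prior + K * e
    state$est_uncertainty <- (1 - K) * P_prior
    state$h_hat <- observed_cursor - state$p_hat
  }
  state
}

#' One temporal-difference step of the actor-critic
#'
#' The trial is a single decision, so the successor value is the current
#' critic value and the reward prediction error is
#' \deqn{\delta = r + \gamma v - v.}
#' The critic moves toward the observed return, and the actor reinforces
#' the executed search direction in proportion to the surprise:
#' \deqn{v \gets v + \alpha_c \delta, \qquad
#'       x_r \gets x_r + \alpha_a \delta \eta.}
#'
#' @param state a \code{"learner_state"} whose \code{last_search_noise} was
#'   recorded from the action that produced the reward.
#' @param params a [learner_params()].
#' @param reward_received scalar reward of the trial.
#' @return the updated \code{"learner_state"}; the TD error is attached as
#'   field \code{last_td_error}.
#' @export
td_step <- function(state, params, reward_received) {
  delta <- reward_received + params$discount * state$v - state$v
  state$x_r <- state$x_r + params$actor_lr * delta * state$last_search_noise
  state$v <- state$v + params$critic_lr * delta
  state$last_td_error <- delta
  state
}

#' Run one complete trial of the learner
#'
#' Composes action selection, motor execution with passive noise, the
#' cursor rotation, the feedback-condition observation, the reward, the
#' estimator step and the temporal-difference step.
#'
#' @param state a \code{"learner_state"}.
#' @param params a [learner_params()].
#' @param condition a [feedback_condition()].
#' @param geometry a [reward_geometry()].
#' @param rotation imposed rotation on this trial, degrees.
#' @param target target direction, degrees.
#' @return list with the updated \code{state} and a one-row data frame
#'   \code{record} holding the trial's inputs, outcomes and logged noise
#'   realizations.
#' @export
learner_trial <- function(state, params, condition, geometry, rotation,
                          target = 0) {
  p_hat_pre <- state$p_hat
  x_r_pre <- state$x_r
  act <- select_action(state, params, target)
  state <- act$state
  u <- act$motor_command
  motor_noise <- stats::rnorm(1, sd = params$motor_noise_sd)
  hand <- u + motor_noise
  cursor <- cursor_from_hand(hand, rotation)
  y <- observe_cursor(cursor, condition)
  rw <- reward(cursor, u, geometry)
  state <- estimator_step(state, params, u, y)
  state <- td_step(state, params, rw$value)
  record <- data.frame(
    target_deg = target,
    rotation_deg = rotation,
    command_deg = u,
    reach_deg = hand,
    cursor_deg = cursor,
    observed_deg = y,
    rewarded = rw$hit,
    cursor_shown = condition$label != "RWD",
    p_hat_pre_deg = p_hat_pre,
    x_r_pre_deg = x_r_pre,
    eta_deg = act$eta,
    motor_noise_deg = motor_noise,
    p_hat_deg = state$p_hat,
    h_hat_deg = state$h_hat,
    stringsAsFactors = FALSE
  )
  list(state = state, record = record)
}
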