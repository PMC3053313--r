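#' Feedback condition of the adaptation paradigm
#'
#' The three feedback regimes differ only in what the learner can observe
#' about the cursor: \code{"ERR"} shows the cursor continuously, \code{"EPE"}
#' flashes it at the movement endpoint only, and \code{"RWD"} never shows it
#' (only the binary success signal is available). The observation channel is
#' absent in RWD — the estimator's gain is forced to zero — rather than
#' merely noisy.
#'
#' @param label one of \code{"ERR"}, \code{"EPE"}, \code{"RWD"}.
#' @param observation_noise_sd standard deviation, in degrees, of the
#'   perceptual noise on the observed cursor angle. Defaults: 1 for ERR,
#'   \code{sqrt(8)} for EPE (the endpoint flash is treated as roughly eight
#'   times less reliable in variance than continuous vision), \code{NA} for
#'   RWD (no observation channel).
#' @return an object of class \code{"feedback_condition"} with fields
#'   \code{label}, \code{cursor_visibility} and \code{observation_noise_sd}.
#' @examples
#' feedback_condition("ERR")
#' feedback_condition("EPE", observation_noise_sd = 3)
#' @export
feedback_condition <- function(label = c("ERR", "EPE", "RWD"),
                               observation_noise_sd = NULL) {
  label <- match.arg(label)
  visibility <- switch(label,
    ERR = "continuous",
    EPE = "endpoint_only",
    RWD = "none"
  )
  if (is.null(observation_noise_sd)) {
    observation_noise_sd <- switch(label,
      ERR = 1,
      EPE = sqrt(8),
      RWD = NA_real_
    )
  }
  if (label == "RWD") {
    if (!is.na(observation_noise_sd)) {
      stop("RWD has no observation channel; observation_noise_sd must be NA")
    }
  } else {
    if (!is.finite(observation_noise_sd) || observation_noise_sd < 0) {
      stop("observation_noise_sd must be finite and non-negative for ",
           label)
    }
  }
  structure(
    list(
      label = label,
      cursor_visibility = visibility,
      observation_noise_sd = observation_noise_sd
    ),
    class = "feedback_condition"
  )
}

#' @export
print.feedback_condition <- function(x, ...) {
  cat("Feedback condition:", x$label,
      sprintf("(cursor %s)", x$cursor_visibility), "\n")
  if (x$label != "RWD") {
    cat("  observation noise SD:", x$observation_noise_sd, "deg\n")
  } else {
    cat("  no cursor observation (estimator gain forced to zero)\n")
  }
  invisible(x)
}

#' Reward-zone geometry
#'
#' The target is an angular zone centred on the target direction; a reach is
#' rewarded when the cursor crosses within half the target width of the
#' centre (boundary inclusive). An optional quadratic motor cost penalises
#' large commands in the scalar reward signal; the binary hit alone is what
#' is logged as a trial's rewarded flag.
#'
#' @param target_direction target centre, degrees (clockwise positive).
#' @param target_width full angular width of the target, degrees; default 6,
#'   so the rewarded zone is within 3 degrees of the centre.
#' @param motor_cost_scale non-negative scale of the quadratic motor cost.
#' @param target_distance reach amplitude in cm; recorded only, the model's
#'   state is the scalar reach angle.
#' @return object of class \code{"reward_geometry"}.
#' @export
reward_geometry <- function(target_direction = 0, target_width = 6,
                            motor_cost_scale = 0.001, target_distance = 10) {
  stopifnot(is.finite(target_direction), is.finite(target_width),
            target_width > 0)
  if (!is.finite(motor_cost_scale) || motor_cost_scale < 0) {
    stop("motor_cost_scale must be >= 0")
  }
  structure(
    list(
      target_direction = target_direction,
      target_width = target_width,
      motor_cost_scale = motor_cost_scale,
      target_distance = target_distance
    ),
    class = "reward_geometry"
  )
}

#' Build the per-trial perturbation schedule of an experiment
#'
#' All three experiments impose a gradual visuomotor rotation: 40 baseline
#' trials at 0 degrees, then the rotation steps by 1 degree in magnitude
#' every 40 trials up to 8 degrees, is held at 8 degrees for 80 trials, and
#' is then held for an additional post-break block. \code{EXP1} rotates
#' clockwise (+8 degrees, 96 extra trials), \code{EXP2} and \code{EXP3}
#' rotate counter-clockwise (-8 degrees; 144 and 96 extra trials
#' respectively).
#'
#' @param experiment_id one of \code{"EXP1"}, \code{"EXP2"}, \code{"EXP3"}.
#' @return a data frame of class \code{"perturbation_schedule"} with columns
#'   \code{trial}, \code{phase} (\code{baseline}/\code{ramp}/\code{hold}/
#'   \code{extra_hold}) and \code{rotation_deg}, plus attributes
#'   \code{experiment_id} and \code{plateau_deg}.
#' @examples
#' sched <- build_schedule("EXP1")
#' nrow(sched)                       # 496
#' sched$rotation_deg[41]            # first ramp step, 1 degree
#' @export
build_schedule <- function(experiment_id = c("EXP1", "EXP2", "EXP3")) {
  experiment_id <- match.arg(experiment_id)
  sgn <- if (experiment_id == "EXP1") 1L else -1L
  extra <- switch(experiment_id, EXP1 = 96L, EXP2 = 144L, EXP3 = 96L)
  rotation <- c(
    rep(0L, 40L),
    rep(sgn * (1:7), each = 40L),
    rep(sgn * 8L, 80L),
    rep(sgn * 8L, extra)
  )
  phase <- c(
    rep("baseline", 40L),
    rep("ramp", 280L),
    rep("hold", 80L),
    rep("extra_hold", extra)
  )
  out <- data.frame(
    trial = seq_along(rotation),
    phase = phase,
    rotation_deg = rotation,
    stringsAsFactors = FALSE
  )
  attr(out, "experiment_id") <- experiment_id
  attr(out, "plateau_deg") <- sgn * 8L
  class(out) <- c("perturbation_schedule", "data.frame")
  out
}

#' Cursor angle produced by a hand angle under a rotation
#'
#' The displayed cursor is the hand direction plus the imposed rotation.
#'
#' @param hand_angle reach direction of the hand, degrees.
#' @param rotation imposed visuomotor rotation, degrees (clockwise positive).
#' @return cursor angle in degrees.
#' @export
cursor_from_hand <- function(hand_angle, rotation) {
  stopifnot(all(is.finite(hand_angle)), all(is.finite(rotation)))
  hand_angle + rotation
}

#' Observe the cursor under a feedback condition
#'
#' ERR and EPE return the cursor angle corrupted by Gaussian perceptual
#' noise with the condition's observation noise SD; RWD returns \code{NA}
#' (no observation is delivered at all).
#'
#' @param cursor_angle true cursor angle, degrees.
#' @param condition a [feedback_condition()].
#' @return observed cursor angle in degrees, or \code{NA_real_} for RWD.
#' @export
observe_cursor <- function(cursor_angle, condition) {
  stopifnot(inherits(condition, "feedback_condition"))
  if (condition$label == "RWD") return(NA_real_)
  cursor_angle + stats::rnorm(length(cursor_angle),
                              sd = condition$observation_noise_sd)
}

#' Scalar reward of a trial
#'
#' The reward is the binary hit indicator minus a quadratic motor cost:
#' \deqn{r = \mathbf{1}\{|c - t| \le w/2\} - \lambda u^2}
#' where \eqn{c} is the cursor angle, \eqn{t} the target direction, \eqn{w}
#' the target width, \eqn{u} the motor command and \eqn{\lambda} the motor
#' cost scale. The boundary is inclusive.
#'
#' @param cursor_angle cursor angle, degrees.
#' @param motor_command motor command, degrees.
#' @param geometry a [reward_geometry()].
#' @return list with \code{value} (scalar reward) and \code{hit} (0/1 flag
#'   that is logged as the trial's rewarded flag).
#' @export
reward <- function(cursor_angle, motor_command, geometry) {
  stopifnot(inherits(geometry, "reward_geometry"))
  hit <- as.integer(
    abs(cursor_angle - geometry$target_direction) <= geometry$target_width / 2
  )
  list(value = hit - geometry$motor_cost_scale * motor_command^2, hit = hit)
}
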