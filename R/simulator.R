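#' Simulate a learner through a full perturbation schedule
#'
#' Runs the dual-error learner trial by trial over a
#' [build_schedule()] under one feedback condition, logging every command,
#' reach, observation, reward and the noise realizations, so that each
#' trial's decomposition \code{reach = (target - p_hat) + x_r + eta +
#' motor_noise} can be reconstructed exactly from the log.
#'
#' @param params a [learner_params()].
#' @param schedule a \code{"perturbation_schedule"} from [build_schedule()].
#' @param condition a [feedback_condition()].
#' @param geometry a [reward_geometry()].
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @param target target direction for the adaptation block, degrees.
#' @return object of class \code{"adapt_sim"}: a list with \code{trials}
#'   (one row per trial, the full log), \code{p_hat_by_trial} and
#'   \code{h_hat_by_trial} (post-update estimates), \code{final_state},
#'   and the \code{params}, \code{condition}, \code{geometry},
#'   \code{schedule} and \code{seed} that produced it.
#' @examples
#' sim <- run_condition(
#'   learner_params(feedback_condition("ERR")),
#'   build_schedule("EXP1"), feedback_condition("ERR"),
#'   reward_geometry(), seed = 1
#' )
#' summary(sim)
#' @export
run_condition <- function(params, schedule, condition, geometry, seed,
                          target = 0) {
  stopifnot(inherits(schedule, "perturbation_schedule"),
            inherits(params, "learner_params"),
            inherits(condition, "feedback_condition"),
            inherits(geometry, "reward_geometry"))
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  state <- init_learner_state()
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    step <- learner_trial(state, params, condition, geometry,
                          rotation = schedule$rotation_deg[k],
                          target = target)
    state <- step$state
    rows[[k]] <- step$record
  }
  trials <- do.call(rbind, rows)
  trials <- cbind(
    data.frame(trial = schedule$trial, phase = schedule$phase,
               stringsAsFactors = FALSE),
    trials
  )
  out <- structure(
    list(
      trials = trials,
      p_hat_by_trial = trials$p_hat_deg,
      h_hat_by_trial = trials$h_hat_deg,
      final_state = state,
      params = params,
      condition = condition,
      geometry = geometry,
      schedule = schedule,
      seed = as.integer(seed)
    ),
    class = "adapt_sim"
  )
  out$summary <- summarize_condition(out)
  out
}

#' Summary statistics of a simulated (or reconstructed) run
#'
#' Computes the standard condition-level summaries: adaptation (magnitude of
#' the mean reach change from baseline to the final plateau window), reach
#' variability over the final window, fraction of rewarded trials over the
#' adaptation phase (all non-baseline trials), and the terminal remapping
#' (mean perturbation estimate over the final window). Reach variability
#' uses the population SD convention (denominator n).
#'
#' @param result an \code{"adapt_sim"} object.
#' @param final_window number of final trials over which terminal quantities
#'   are measured; default 100.
#' @return a list of class \code{"adapt_summary"} with fields
#'   \code{adaptation}, \code{reach_sd_final}, \code{reward_fraction},
#'   \code{remapping} and \code{final_window}.
#' @export
summarize_condition <- function(result, final_window = 100) {
  stopifnot(inherits(result, "adapt_sim"))
  tr <- result$trials
  n <- nrow(tr)
  if (final_window > n) stop("final_window exceeds series length")
  idx_final <- (n - final_window + 1):n
  baseline <- tr$reach_deg[tr$phase == "baseline"]
  adapt_phase <- tr$phase != "baseline"
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(
    list(
      adaptation = abs(mean(tr$reach_deg[idx_final]) - mean(baseline)),
      reach_sd_final = pop_sd(tr$reach_deg[idx_final]),
      reward_fraction = mean(tr$rewarded[adapt_phase]),
      remapping = mean(tr$p_hat_deg[idx_final]),
      final_window = final_window
    ),
    class = "adapt_summary"
  )
}

#' @export
print.adapt_summary <- function(x, ...) {
  cat(sprintf("adaptation: %.2f deg | reach SD (final %d): %.2f deg\n",
              x$adaptation, x$final_window, x$reach_sd_final))
  cat(sprintf("reward fraction (adaptation phase): %.3f | remapping: %.2f deg\n",
              x$reward_fraction, x$remapping))
  invisible(x)
}

#' @export
print.adapt_sim <- function(x, ...) {
  cat(sprintf("Simulated %s run, %s schedule, %d trials (seed %d)\n",
              x$condition$label, attr(x$schedule, "experiment_id"),
              nrow(x$trials), x$seed))
  print(x$summary)
  invisible(x)
}

#' @export
summary.adapt_sim <- function(object, final_window = 100, ...) {
  summarize_condition(object, final_window)
}

#' @export
plot.adapt_sim <- function(x, ...) {
  tr <- x$trials
  graphics::plot(tr$trial, tr$reach_deg, type = "p", pch = 16, cex = 0.3,
                 col = "grey50", xlab = "trial", ylab = "degrees",
                 main = sprintf("%s: reach, ideal and perturbation estimate",
                                x$condition$label), ...)
  graphics::lines(tr$trial, -tr$rotation_deg, col = "goldenrod", lwd = 2)
  graphics::lines(tr$trial, tr$p_hat_deg, col = "firebrick", lwd = 2)
  graphics::legend("bottomleft",
                   legend = c("reach", "ideal (-rotation)", "p-hat"),
                   col = c("grey50", "goldenrod", "firebrick"),
                   pch = c(16, NA, NA), lty = c(NA, 1, 1), bty = "n")
  invisible(x)
}

#' Sweep the observation-noise variance
#'
#' Re-runs the ERR-style simulation over a grid of observation-noise
#' variances, averaging terminal remapping, adaptation and reward fraction
#' over seeds. As the visual feedback degrades the Kalman gain falls, so the
#' remapping column decreases toward zero while the reward-driven policy
#' absorbs the compensation and the adaptation column stays near the plateau
#' magnitude.
#'
#' @param params_base a [learner_params()] whose observation-noise variance
#'   is overridden cell by cell (its search-noise SD should be large enough
#'   for reward learning to operate in the high-noise limit; default 1.5).
#' @param sigma_grid vector of observation-noise variances, deg^2.
#' @param n_seeds seeds per grid cell; seeds used are \code{seed_base +
#'   1:n_seeds}.
#' @param schedule,geometry paradigm pieces; defaults EXP1 and the standard
#'   6-degree target.
#' @param seed_base integer offset for the per-cell seed list.
#' @param final_window window for terminal quantities.
#' @return a data frame sorted by \code{sigma_y2} with columns
#'   \code{sigma_y2}, \code{remapping}, \code{adaptation},
#'   \code{reward_fraction}; the seed list is attached as attribute
#'   \code{"seeds"}.
#' @export
uncertainty_sweep <- function(params_base = learner_params(search_noise_sd = 1.5),
                              sigma_grid = c(0.01, 1, 8, 100, 1e6),
                              n_seeds = 20,
                              schedule = build_schedule("EXP1"),
                              geometry = reward_geometry(),
                              seed_base = 0,
                              final_window = 100) {
  stopifnot(length(sigma_grid) >= 1, n_seeds >= 1)
  sigma_grid <- sort(sigma_grid)
  seeds <- seed_base + seq_len(n_seeds)
  rows <- lapply(sigma_grid, function(s2) {
    cond <- feedback_condition("ERR", observation_noise_sd = sqrt(s2))
    p <- params_base
    p$observation_noise_var <- s2
    sums <- lapply(seeds, function(sd_i) {
      summarize_condition(
        run_condition(p, schedule, cond, geometry, seed = sd_i),
        final_window
      )
    })
    data.frame(
      sigma_y2 = s2,
      remapping = mean(vapply(sums, `[[`, numeric(1), "remapping")),
      adaptation = mean(vapply(sums, `[[`, numeric(1), "adaptation")),
      reward_fraction = mean(vapply(sums, `[[`, numeric(1),
                                    "reward_fraction"))
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- seeds
  out
}
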