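#' Configuration of the dual-memory fit
#'
#' Fixed quantities and the free-parameter mapping of [fit_subject()]. For
#' the visual conditions (ERR/EPE) three parameters are free; the first two
#' are always the observation-noise variance and the actor learning rate,
#' and \code{third} selects the identity of the third:
#' \code{"process_var"} (default) frees the process-noise variance of the
#' perturbation prior, \code{"critic_lr"} frees the critic rate instead
#' (process noise then stays at its fixed value). For RWD the observation
#' channel is absent and the two free parameters are the actor and critic
#' rates. Unless \code{third = "critic_lr"}, the critic is co-updated with
#' the actor's rate.
#'
#' @param third identity of the third free parameter for ERR/EPE fits.
#' @param retention fixed retention factor of the perturbation prior.
#' @param discount fixed temporal-difference discount.
#' @param process_noise_var process-noise variance used when it is not
#'   free.
#' @param motor_cost_scale motor-cost scale used to reconstruct the scalar
#'   reward from the logged hit flag and observed reach.
#' @param sigma_y2_bounds,lr_bounds,q_bounds box bounds of the free
#'   parameters (the observation-noise variance is searched on a log10
#'   scale between its bounds).
#' @return object of class \code{"fit_config"}.
#' @export
fit_config <- function(third = c("process_var", "critic_lr"),
                       retention = 0.99,
                       discount = 0.9,
                       process_noise_var = 0.01,
                       motor_cost_scale = 0.001,
                       sigma_y2_bounds = c(1e-3, 1e4),
                       lr_bounds = c(0, 1),
                       q_bounds = c(1e-6, 5)) {
  structure(
    list(
      third = match.arg(third),
      retention = retention,
      discount = discount,
      process_noise_var = process_noise_var,
      motor_cost_scale = motor_cost_scale,
      sigma_y2_bounds = sigma_y2_bounds,
      lr_bounds = lr_bounds,
      q_bounds = q_bounds
    ),
    class = "fit_config"
  )
}

#' Constrained forward filter of the dual-memory model
#'
#' Runs the learner forward against a subject's observed reaches, splitting
#' each reach into the sensory-error-driven memory \code{x_p} (minus the
#' perturbation estimate of the Kalman recursion, driven by the
#' experimenter-imposed rotation), the reward-error-driven memory
#' \code{x_r} (actor-critic recursion driven by the subject's logged
#' rewards), and the residual active search noise
#' \code{eta = reach - (x_p + x_r)}. All memories start at zero.
#'
#' For RWD the Kalman gain is forced to zero regardless of the
#' observation-noise parameter, so \code{x_p} is identically zero.
#'
#' @param series data frame with columns \code{rotation_deg},
#'   \code{reach_deg} and \code{rewarded}.
#' @param params a [learner_params()] or plain list with fields
#'   \code{retention}, \code{process_noise_var},
#'   \code{observation_noise_var}, \code{actor_lr}, \code{critic_lr},
#'   \code{discount}, \code{motor_cost_scale}.
#' @param condition a [feedback_condition()] or condition label.
#' @return list with per-trial vectors \code{x_p}, \code{x_r}, \code{eta},
#'   \code{v} and the scalar \code{sse}.
#' @export
forward_filter <- function(series, params, condition) {
  if (is.character(condition)) condition <- feedback_condition(condition)
  need <- c("rotation_deg", "reach_deg", "rewarded")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols) > 0) {
    stop("series is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  reach <- series$reach_deg
  if (!all(is.finite(reach))) stop("reach_deg must be finite")
  rotation <- series$rotation_deg
  rewarded <- series$rewarded
  n <- length(reach)
  A <- params$retention
  q <- params$process_noise_var
  s2 <- params$observation_noise_var
  aa <- params$actor_lr
  ac <- params$critic_lr
  gam <- params$discount
  lam <- params$motor_cost_scale
  rwd_only <- condition$label == "RWD"
  x_p <- numeric(n); x_rv <- numeric(n); eta <- numeric(n); vv <- numeric(n)
  p_hat <- 0; P <- 1; x_r <- 0; v <- 0
  for (k in seq_len(n)) {
    x_p[k] <- -p_hat
    x_rv[k] <- x_r
    eta[k] <- reach[k] - (x_p[k] + x_r)
    r_k <- rewarded[k] - lam * reach[k]^2
    delta <- r_k + gam * v - v
    x_r <- x_r + aa * delta * eta[k]
    v <- v + ac * delta
    vv[k] <- v
    p_prior <- A * p_hat
    P_prior <- A^2 * P + q
    K <- if (rwd_only) 0 else P_prior / (P_prior + s2)
    p_hat <- p_prior + K * (rotation[k] - p_prior)
    P <- (1 - K) * P_prior
  }
  list(x_p = x_p, x_r = x_rv, eta = eta, v = vv, sse = sum(eta^2))
}

fit_par_info <- function(condition_label, config) {
  if (condition_label == "RWD") {
    list(names = c("actor_lr", "critic_lr"),
         lower = rep(config$lr_bounds[1], 2),
         upper = rep(config$lr_bounds[2], 2),
         log_scale = c(FALSE, FALSE))
  } else if (config$third == "process_var") {
    list(names = c("sigma_y2", "actor_lr", "process_var"),
         lower = c(log10(config$sigma_y2_bounds[1]), config$lr_bounds[1],
                   config$q_bounds[1]),
         upper = c(log10(config$sigma_y2_bounds[2]), config$lr_bounds[2],
                   config$q_bounds[2]),
         log_scale = c(TRUE, FALSE, FALSE))
  } else {
    list(names = c("sigma_y2", "actor_lr", "critic_lr"),
         lower = c(log10(config$sigma_y2_bounds[1]), config$lr_bounds[1],
                   config$lr_bounds[1]),
         upper = c(log10(config$sigma_y2_bounds[2]), config$lr_bounds[2],
                   config$lr_bounds[2]),
         log_scale = c(TRUE, FALSE, FALSE))
  }
}

fit_par_to_params <- function(par, condition_label, config) {
  if (condition_label == "RWD") {
    list(retention = config$retention,
         process_noise_var = config$process_noise_var,
         observation_noise_var = NA_real_,
         actor_lr = par[1], critic_lr = par[2],
         discount = config$discount,
         motor_cost_scale = config$motor_cost_scale)
  } else if (config$third == "process_var") {
    list(retention = config$retention,
         process_noise_var = par[3],
         observation_noise_var = 10^par[1],
         actor_lr = par[2], critic_lr = par[2],
         discount = config$discount,
         motor_cost_scale = config$motor_cost_scale)
  } else {
    list(retention = config$retention,
         process_noise_var = config$process_noise_var,
         observation_noise_var = 10^par[1],
         actor_lr = par[2], critic_lr = par[3],
         discount = config$discount,
         motor_cost_scale = config$motor_cost_scale)
  }
}

#' Fit the dual-memory model to one subject's reach series
#'
#' Bounded multi-start nonlinear least squares: the residual of a parameter
#' vector is the per-trial search-noise sequence of [forward_filter()], so
#' the objective is the summed squared search noise — equivalently the
#' squared difference between the observed reaches and the reaches the
#' dual-memory model predicts. Starts are a Latin hypercube over the box
#' bounds (observation-noise variance on a log scale); the best start is
#' returned.
#'
#' @param series data frame with columns \code{rotation_deg},
#'   \code{reach_deg}, \code{rewarded}; at least 50 trials (shorter series
#'   leave the parameters unidentifiable).
#' @param condition a [feedback_condition()] or condition label; RWD fits
#'   two parameters (actor/critic rates), ERR/EPE three (see
#'   [fit_config()]).
#' @param n_starts number of Latin-hypercube starts.
#' @param seed integer seed for the start design (the fit is deterministic
#'   given seed).
#' @param config a [fit_config()].
#' @return object of class \code{"adapt_fit"} with components
#'   \code{params_hat} (named vector, natural scale), \code{x_p_by_trial},
#'   \code{x_r_by_trial}, \code{eta_by_trial}, \code{sse},
#'   \code{search_noise_var_hat} (\code{sse/n}), \code{converged},
#'   \code{n_starts}, per-start records in \code{starts}, and the inputs.
#' @seealso [decompose()], [forward_filter()]; methods
#'   \code{print}, \code{summary}, \code{coef}, \code{residuals},
#'   \code{fitted}, \code{predict}, \code{plot}, \code{simulate}.
#' @export
fit_subject <- function(series, condition, n_starts = 10, seed = 1,
                        config = fit_config()) {
  if (is.character(condition)) condition <- feedback_condition(condition)
  stopifnot(inherits(condition, "feedback_condition"),
            inherits(config, "fit_config"))
  if (nrow(series) < 50) {
    stop("series has fewer than 50 trials; the dual-memory parameters are ",
         "not identifiable on such short series")
  }
  info <- fit_par_info(condition$label, config)
  npar <- length(info$names)
  resid_fun <- function(par) {
    forward_filter(series, fit_par_to_params(par, condition$label, config),
                   condition)$eta
  }
  set.seed(as.integer(seed))
  design <- lhs::randomLHS(n_starts, npar)
  starts <- lapply(seq_len(n_starts), function(i) {
    par0 <- info$lower + design[i, ] * (info$upper - info$lower)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = info$lower, upper = info$upper, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      list(ok = FALSE, message = conditionMessage(res), par0 = par0)
    } else {
      list(ok = TRUE, par = res$par, sse = res$deviance, info = res$info,
           message = res$message, par0 = par0)
    }
  })
  ok <- vapply(starts, `[[`, logical(1), "ok")
  if (!any(ok)) {
    stop("optimizer failed on all ", n_starts, " starts: ",
         paste(unique(vapply(starts[!ok], `[[`, character(1), "message")),
               collapse = "; "))
  }
  sses <- vapply(starts, function(s) if (s$ok) s$sse else Inf, numeric(1))
  best <- starts[[which.min(sses)]]
  params <- fit_par_to_params(best$par, condition$label, config)
  ff <- forward_filter(series, params, condition)
  par_nat <- best$par
  par_nat[info$log_scale] <- 10^par_nat[info$log_scale]
  names(par_nat) <- info$names
  structure(
    list(
      params_hat = par_nat,
      params_full = params,
      x_p_by_trial = ff$x_p,
      x_r_by_trial = ff$x_r,
      eta_by_trial = ff$eta,
      v_by_trial = ff$v,
      sse = ff$sse,
      search_noise_var_hat = ff$sse / nrow(series),
      converged = best$info %in% 1:3,
      optimizer_info = best$info,
      n_starts = n_starts,
      starts = data.frame(
        start = seq_len(n_starts),
        sse = sses,
        converged = vapply(starts, function(s) isTRUE(s$ok) &&
                             s$info %in% 1:3, logical(1))
      ),
      series = series,
      condition = condition,
      config = config,
      seed = as.integer(seed)
    ),
    class = "adapt_fit"
  )
}

#' Terminal decomposition of a fitted subject
#'
#' Means of the sensory-driven and reward-driven memories over the final
#' window of the series, plus the residual search-noise variance — the
#' per-subject split of the total adaptation into its two sources.
#'
#' @param fit an \code{"adapt_fit"}.
#' @param window number of final trials; default 80 (the terminal plateau).
#' @return list with \code{x_p_final}, \code{x_r_final} (degrees) and
#'   \code{search_noise_var} (deg^2).
#' @export
decompose <- function(fit, window = 80) {
  stopifnot(inherits(fit, "adapt_fit"))
  n <- length(fit$x_p_by_trial)
  if (window > n) stop("window exceeds series length")
  idx <- (n - window + 1):n
  list(
    x_p_final = mean(fit$x_p_by_trial[idx]),
    x_r_final = mean(fit$x_r_by_trial[idx]),
    search_noise_var = fit$search_noise_var_hat
  )
}

#' @export
print.adapt_fit <- function(x, ...) {
  cat(sprintf("Dual-memory fit (%s condition, %d trials, %d starts%s)\n",
              x$condition$label, nrow(x$series), x$n_starts,
              if (x$converged) ", converged" else ", NOT converged"))
  cat("  parameters:\n")
  for (nm in names(x$params_hat)) {
    cat(sprintf("    %-12s %.4g\n", nm, x$params_hat[[nm]]))
  }
  cat(sprintf("  sse: %.4g deg^2, search-noise variance: %.4g deg^2\n",
              x$sse, x$search_noise_var_hat))
  invisible(x)
}

#' @export
summary.adapt_fit <- function(object, window = 80, ...) {
  dec <- decompose(object, window)
  out <- list(fit = object, decomposition = dec, window = window)
  class(out) <- "summary.adapt_fit"
  out
}

#' @export
print.summary.adapt_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  terminal split (final %d trials): x_p = %.2f deg, x_r = %.2f deg\n",
              x$window, x$decomposition$x_p_final, x$decomposition$x_r_final))
  invisible(x)
}

#' @export
coef.adapt_fit <- function(object, ...) object$params_hat

#' @export
residuals.adapt_fit <- function(object, ...) object$eta_by_trial

#' @export
fitted.adapt_fit <- function(object, ...) {
  object$x_p_by_trial + object$x_r_by_trial
}

#' Model-predicted reach series of a fitted subject
#'
#' The reach sequence the dual-memory model predicts: the sum of the two
#' reconstructed memories on each trial (the observed reach minus the
#' residual search noise). With \code{newdata} (a series with
#' \code{rotation_deg}, \code{reach_deg}, \code{rewarded}) the fitted
#' parameters are filtered through that series instead.
#'
#' @param object an \code{"adapt_fit"}.
#' @param newdata optional replacement trial series.
#' @param ... unused.
#' @return numeric vector of predicted reach angles, degrees.
#' @export
predict.adapt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  ff <- forward_filter(newdata, object$params_full, object$condition)
  ff$x_p + ff$x_r
}

#' @export
plot.adapt_fit <- function(x, ...) {
  n <- nrow(x$series)
  graphics::plot(seq_len(n), x$series$reach_deg, pch = 16, cex = 0.3,
                 col = "grey60", xlab = "trial", ylab = "degrees",
                 main = sprintf("Dual-memory decomposition (%s)",
                                x$condition$label), ...)
  graphics::lines(seq_len(n), fitted(x), col = "purple", lwd = 2)
  graphics::lines(seq_len(n), x$x_p_by_trial, col = "firebrick", lwd = 2)
  graphics::lines(seq_len(n), x$x_r_by_trial, col = "steelblue", lwd = 2)
  graphics::legend("bottomleft",
                   legend = c("observed reach", "model reach",
                              "x_p (sensory)", "x_r (reward)"),
                   col = c("grey60", "purple", "firebrick", "steelblue"),
                   pch = c(16, NA, NA, NA), lty = c(NA, 1, 1, 1), bty = "n")
  invisible(x)
}

#' Simulate new reach series from a fitted model
#'
#' Generates synthetic reach series from the fitted parameters: the
#' dual-memory learner is driven generatively over the fitted series'
#' rotation schedule, drawing fresh search noise with SD equal to the
#' fitted residual SD and re-deriving rewards from the reward zone.
#'
#' @param object an \code{"adapt_fit"}.
#' @param nsim number of series.
#' @param seed integer seed.
#' @param geometry a [reward_geometry()] for re-deriving rewards.
#' @param ... unused.
#' @return a list of \code{nsim} data frames with columns
#'   \code{rotation_deg}, \code{reach_deg}, \code{rewarded}.
#' @export
simulate.adapt_fit <- function(object, nsim = 1, seed = 1,
                               geometry = reward_geometry(), ...) {
  set.seed(as.integer(seed))
  pars <- object$params_full
  rotation <- object$series$rotation_deg
  n <- length(rotation)
  eta_sd <- sqrt(object$search_noise_var_hat)
  rwd_only <- object$condition$label == "RWD"
  lapply(seq_len(nsim), function(s) {
    p_hat <- 0; P <- 1; x_r <- 0; v <- 0
    reach <- numeric(n); rewarded <- integer(n)
    for (k in seq_len(n)) {
      eta <- stats::rnorm(1, sd = eta_sd)
      reach[k] <- -p_hat + x_r + eta
      rw <- reward(reach[k] + rotation[k], reach[k], geometry)
      rewarded[k] <- rw$hit
      delta <- rw$value + pars$discount * v - v
      x_r <- x_r + pars$actor_lr * delta * eta
      v <- v + pars$critic_lr * delta
      p_prior <- pars$retention * p_hat
      P_prior <- pars$retention^2 * P + pars$process_noise_var
      K <- if (rwd_only) 0 else
        P_prior / (P_prior + pars$observation_noise_var)
      p_hat <- p_prior + K * (rotation[k] - p_prior)
      P <- (1 - K) * P_prior
    }
    data.frame(rotation_deg = rotation, reach_deg = reach,
               rewarded = rewarded)
  })
}
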