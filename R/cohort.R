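#' Configuration of one synthetic subject
#'
#' Bundles the feedback condition, learner parameters and the
#' phenomenological probe parameters of a simulated subject. The remap
#' fraction \code{rho} is the fraction of the terminal perturbation
#' estimate expressed as a localization shift, and
#' \code{generalization_width} is the SD, in degrees of target direction,
#' of the transfer curve of adaptation to untrained directions. Both are
#' phenomenological: the learner itself does not produce a generalization
#' width, so the generator imposes one.
#'
#' @param condition a [feedback_condition()] or a condition label.
#' @param learner_params a [learner_params()]; defaults to the
#'   condition-typical parameters.
#' @param experiment schedule to train on; defaults to \code{"EXP1"} for
#'   ERR/RWD and \code{"EXP3"} for EPE.
#' @param remap_fraction fraction in [0, 1] of the terminal perturbation
#'   estimate expressed in the localization probes.
#' @param generalization_width width of the transfer curve, degrees (> 0).
#' @param generalization_shape \code{"gaussian"} (default) or
#'   \code{"cosine"} transfer curve.
#' @param localization_noise_sd SD, degrees, of the left-hand pointing
#'   response noise.
#' @param seed integer seed for everything this subject generates.
#' @return object of class \code{"subject_config"}.
#' @export
subject_config <- function(condition, learner_params = NULL,
                           experiment = NULL,
                           remap_fraction = 1,
                           generalization_width = 15,
                           generalization_shape = c("gaussian", "cosine"),
                           localization_noise_sd = 2,
                           seed = 1) {
  if (is.character(condition)) condition <- feedback_condition(condition)
  stopifnot(inherits(condition, "feedback_condition"))
  if (is.null(learner_params)) learner_params <- learner_params(condition)
  if (is.null(experiment)) {
    experiment <- if (condition$label == "EPE") "EXP3" else "EXP1"
  }
  generalization_shape <- match.arg(generalization_shape)
  if (remap_fraction < 0 || remap_fraction > 1) {
    stop("remap_fraction must lie in [0, 1]")
  }
  if (!is.finite(generalization_width) || generalization_width <= 0) {
    stop("generalization_width must be positive")
  }
  if (localization_noise_sd < 0) stop("localization_noise_sd must be >= 0")
  structure(
    list(
      condition = condition,
      learner_params = learner_params,
      experiment = experiment,
      remap_fraction = remap_fraction,
      generalization_width = generalization_width,
      generalization_shape = generalization_shape,
      localization_noise_sd = localization_noise_sd,
      seed = as.integer(seed)
    ),
    class = "subject_config"
  )
}

#' Target multiset of one generalization baseline block
#'
#' Eighty trials over the seven probe directions \code{-30, -20, ..., 30}:
#' 32 at the trained centre (0 degrees) and 8 at each of the six peripheral
#' directions, in a seed-determined shuffled order.
#'
#' @param seed integer seed determining the order.
#' @return integer vector of 80 target directions, degrees.
#' @export
generate_baseline_block <- function(seed) {
  targets <- c(rep(0L, 32L),
               rep(c(-30L, -20L, -10L, 10L, 20L, 30L), each = 8L))
  set.seed(as.integer(seed))
  sample(targets)
}

transfer_curve <- function(theta, width, shape) {
  switch(shape,
    gaussian = exp(-theta^2 / (2 * width^2)),
    cosine = ifelse(abs(theta) >= 2 * width, 0,
                    0.5 * (1 + cos(pi * theta / (2 * width))))
  )
}

#' Generate one synthetic subject
#'
#' Simulates the adaptation series with [run_condition()], then adds the
#' two probe blocks of the behavioral protocol:
#' \itemize{
#'   \item Localization (10 PRE + 10 POST probes, one per
#'     four-shooting-plus-one-probe micro-block): pointing responses are
#'     recorded relative to the actual hand crossing, so PRE responses are
#'     centred on zero and POST responses are displaced toward the cursor by
#'     \code{remap_fraction} times the terminal perturbation estimate, plus
#'     pointing noise.
#'   \item Generalization (80-trial PRE and POST blocks from
#'     [generate_baseline_block()]): each probe reach is the aimed direction
#'     plus, in POST, the signed adaptation scaled by the transfer curve at
#'     that direction, plus motor noise.
#' }
#'
#' @param config a [subject_config()].
#' @return object of class \code{"subject_dataset"}: the adaptation trial
#'   log, \code{localization_pre}/\code{localization_post} (length-10
#'   vectors), \code{generalization_pre}/\code{generalization_post}
#'   (data frames with \code{direction_deg}, \code{reach_deg}), and
#'   \code{truth} (the generating config plus realized terminal remap and
#'   signed adaptation).
#' @export
generate_subject <- function(config) {
  stopifnot(inherits(config, "subject_config"))
  schedule <- build_schedule(config$experiment)
  geometry <- reward_geometry(
    motor_cost_scale = config$learner_params$motor_cost_scale
  )
  sim <- run_condition(config$learner_params, schedule, config$condition,
                       geometry, seed = config$seed)
  tr <- sim$trials
  n <- nrow(tr)
  fw <- sim$summary$final_window
  remap_term <- sim$summary$remapping
  adaptation_signed <- mean(tr$reach_deg[(n - fw + 1):n]) -
    mean(tr$reach_deg[tr$phase == "baseline"])
  # probe RNG continues deterministically from the simulation's stream
  loc_pre <- stats::rnorm(10, mean = 0, sd = config$localization_noise_sd)
  loc_post <- stats::rnorm(10,
                           mean = config$remap_fraction * remap_term,
                           sd = config$localization_noise_sd)
  dirs_pre <- generate_baseline_block(config$seed)
  dirs_post <- generate_baseline_block(config$seed + 1L)
  msd <- config$learner_params$motor_noise_sd
  set.seed(config$seed + 2L)
  gen_pre <- data.frame(
    direction_deg = dirs_pre,
    reach_deg = dirs_pre + stats::rnorm(length(dirs_pre), sd = msd)
  )
  gain <- transfer_curve(dirs_post, config$generalization_width,
                         config$generalization_shape)
  gen_post <- data.frame(
    direction_deg = dirs_post,
    reach_deg = dirs_post + adaptation_signed * gain +
      stats::rnorm(length(dirs_post), sd = msd)
  )
  structure(
    list(
      adaptation_series = tr,
      summary = sim$summary,
      localization_pre = loc_pre,
      localization_post = loc_post,
      localization_blocks = data.frame(
        phase = rep(c("PRE", "POST"), each = 10L),
        micro_block = rep(1:10, 2L),
        shooting_trials = 4L,
        pointing_deg = c(loc_pre, loc_post)
      ),
      generalization_pre = gen_pre,
      generalization_post = gen_post,
      truth = c(config,
                list(terminal_remap = remap_term,
                     adaptation_signed = adaptation_signed))
    ),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Synthetic %s subject (%s, seed %d): %d adaptation trials\n",
              x$truth$condition$label, x$truth$experiment, x$truth$seed,
              nrow(x$adaptation_series)))
  cat(sprintf("  terminal remap %.2f deg, signed adaptation %.2f deg\n",
              x$truth$terminal_remap, x$truth$adaptation_signed))
  cat(sprintf("  remap fraction %.2f, generalization width %.1f deg\n",
              x$truth$remap_fraction, x$truth$generalization_width))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' @param n_subjects number of subjects (>= 2 for any downstream
#'   correlation).
#' @param config_sampler function \code{(i, seed)} returning a
#'   [subject_config()] for subject \code{i}; see [cohort_sampler()].
#' @param seed integer; subject \code{i} receives seed
#'   \code{seed * 1000 + i}.
#' @return list of \code{"subject_dataset"} objects.
#' @export
generate_cohort <- function(n_subjects, config_sampler, seed = 1) {
  stopifnot(n_subjects >= 1, is.function(config_sampler))
  lapply(seq_len(n_subjects), function(i) {
    generate_subject(config_sampler(i, as.integer(seed) * 1000L + i))
  })
}

#' Cohort samplers coupling remapping and generalization
#'
#' Returns a \code{(i, seed)} sampler of [subject_config()]s in which a
#' subject-level latent "reliance on vision" variable drives both the remap
#' fraction and the generalization width. With \code{coupling = 1} the two
#' are driven by the same latent (subjects who remap more also generalize
#' more broadly); with \code{coupling = 0} they are independent, giving a
#' null cohort.
#'
#' @param condition condition label or [feedback_condition()] for every
#'   subject; default \code{"EPE"}.
#' @param coupling mixing weight in [0, 1] between the shared latent and an
#'   independent draw for the generalization width.
#' @param rho_range range of remap fractions across the cohort.
#' @param width_range range of generalization widths, degrees.
#' @param ... further arguments passed to [subject_config()].
#' @return a function \code{(i, seed) -> subject_config}.
#' @export
cohort_sampler <- function(condition = "EPE", coupling = 0.8,
                           rho_range = c(0.15, 0.95),
                           width_range = c(5, 30), ...) {
  stopifnot(coupling >= 0, coupling <= 1)
  function(i, seed) {
    set.seed(as.integer(seed) + 500000L)
    z <- stats::runif(1)
    u <- stats::runif(1)
    z_w <- coupling * z + (1 - coupling) * u
    subject_config(
      condition = condition,
      remap_fraction = rho_range[1] + diff(rho_range) * z,
      generalization_width = width_range[1] + diff(width_range) * z_w,
      seed = seed,
      ...
    )
  }
}
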