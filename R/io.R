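#' Write / read a trial table
#'
#' Trial tables are headered CSV. The standard dialect has columns
#' \code{trial}, \code{phase}, \code{target_deg}, \code{rotation_deg},
#' \code{reach_deg}, \code{cursor_deg}, \code{observed_deg} (blank when no
#' observation was delivered), \code{rewarded}, \code{cursor_shown};
#' simulator logs carry extra columns (noise realizations, memory traces)
#' which round-trip unchanged.
#'
#' @param trials data frame of trials.
#' @param path file path.
#' @return \code{write_trials} returns \code{path} invisibly;
#'   \code{read_trials} returns the data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a paradigm configuration from YAML
#'
#' Keys: \code{experiment} (EXP1/EXP2/EXP3), \code{condition}
#' (ERR/EPE/RWD), \code{seed}, and optional noise overrides
#' (\code{observation_noise_sd}, \code{search_noise_sd},
#' \code{motor_noise_sd}) plus any other [learner_params()] field.
#'
#' @param path YAML file path.
#' @return list with \code{schedule}, \code{condition}, \code{params},
#'   \code{seed}.
#' @export
read_paradigm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment) || is.null(cfg$condition)) {
    stop("config must name an experiment and a condition")
  }
  condition <- if (!is.null(cfg$observation_noise_sd)) {
    feedback_condition(cfg$condition,
                       observation_noise_sd = cfg$observation_noise_sd)
  } else {
    feedback_condition(cfg$condition)
  }
  par_fields <- c("retention", "process_noise_var", "motor_noise_sd",
                  "search_noise_sd", "actor_lr", "critic_lr", "discount",
                  "motor_cost_scale")
  args <- cfg[intersect(names(cfg), par_fields)]
  params <- do.call(learner_params, c(list(condition = condition), args))
  list(
    schedule = build_schedule(cfg$experiment),
    condition = condition,
    params = params,
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  )
}

#' Write / read a synthetic subject dataset
#'
#' One directory per subject: \code{trials.csv} (the adaptation log),
#' \code{localization.json} (PRE/POST pointing responses and micro-block
#' bookkeeping), \code{generalization.csv} (PRE and POST probe reaches with
#' a \code{phase} column) and \code{truth.json} (the generating
#' configuration and realized terminal quantities). All files are plain
#' text and round-trip losslessly to numerical precision.
#'
#' @param dataset a \code{"subject_dataset"}.
#' @param dir output directory (created if needed).
#' @return \code{write_subject_dataset} returns \code{dir} invisibly;
#'   \code{read_subject_dataset} returns a \code{"subject_dataset"}.
#' @export
write_subject_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials(dataset$adaptation_series, file.path(dir, "trials.csv"))
  jsonlite::write_json(
    list(pre = dataset$localization_pre, post = dataset$localization_post,
         blocks = dataset$localization_blocks),
    file.path(dir, "localization.json"), digits = NA
  )
  gen <- rbind(
    cbind(phase = "PRE", dataset$generalization_pre),
    cbind(phase = "POST", dataset$generalization_post)
  )
  utils::write.csv(gen, file.path(dir, "generalization.csv"),
                   row.names = FALSE)
  truth <- dataset$truth
  truth_json <- list(
    condition = truth$condition$label,
    observation_noise_sd = truth$condition$observation_noise_sd,
    experiment = truth$experiment,
    learner_params = unclass(truth$learner_params),
    remap_fraction = truth$remap_fraction,
    generalization_width = truth$generalization_width,
    generalization_shape = truth$generalization_shape,
    localization_noise_sd = truth$localization_noise_sd,
    seed = truth$seed,
    terminal_remap = truth$terminal_remap,
    adaptation_signed = truth$adaptation_signed
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_subject_dataset
#' @export
read_subject_dataset <- function(dir) {
  trials <- read_trials(file.path(dir, "trials.csv"))
  loc <- jsonlite::read_json(file.path(dir, "localization.json"),
                             simplifyVector = TRUE)
  gen <- utils::read.csv(file.path(dir, "generalization.csv"),
                         stringsAsFactors = FALSE)
  truth_json <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  obs_sd <- truth_json$observation_noise_sd
  condition <- feedback_condition(
    truth_json$condition,
    observation_noise_sd = if (truth_json$condition == "RWD") NULL
    else obs_sd
  )
  lp <- do.call(learner_params, truth_json$learner_params)
  truth <- c(
    unclass(subject_config(
      condition = condition, learner_params = lp,
      experiment = truth_json$experiment,
      remap_fraction = truth_json$remap_fraction,
      generalization_width = truth_json$generalization_width,
      generalization_shape = truth_json$generalization_shape,
      localization_noise_sd = truth_json$localization_noise_sd,
      seed = truth_json$seed
    )),
    list(terminal_remap = truth_json$terminal_remap,
         adaptation_signed = truth_json$adaptation_signed)
  )
  structure(
    list(
      adaptation_series = trials,
      localization_pre = loc$pre,
      localization_post = loc$post,
      localization_blocks = loc$blocks,
      generalization_pre = gen[gen$phase == "PRE",
                               c("direction_deg", "reach_deg")],
      generalization_post = gen[gen$phase == "POST",
                                c("direction_deg", "reach_deg")],
      truth = truth
    ),
    class = "subject_dataset"
  )
}
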