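#' Illusion index (PRE-to-POST localization shift)
#'
#' Mean POST localization minus mean PRE localization, signed under the
#' clockwise-positive convention. Localization responses are recorded
#' relative to the actual hand crossing, so the index is the change in the
#' hand-localization bias produced by adaptation.
#'
#' @param localization_pre,localization_post numeric vectors of pointing
#'   responses, degrees.
#' @return signed shift in degrees.
#' @export
illusion_index <- function(localization_pre, localization_post) {
  if (length(localization_pre) == 0 || length(localization_post) == 0) {
    stop("localization sequences must be non-empty")
  }
  mean(localization_post) - mean(localization_pre)
}

#' Generalization index (normalized mean transfer)
#'
#' The PRE-to-POST reach change at each peripheral probe direction,
#' normalized by the change at the trained direction (0 degrees), averaged
#' over the peripheral directions. For a well-behaved transfer curve the
#' index lies in [0, 1]; larger values mean broader generalization.
#'
#' @param probe_table_pre,probe_table_post data frames with columns
#'   \code{direction_deg} and \code{reach_deg} covering the seven probe
#'   directions \code{-30, -20, ..., 30}.
#' @return dimensionless index.
#' @export
generalization_index <- function(probe_table_pre, probe_table_post) {
  dirs <- c(-30, -20, -10, 0, 10, 20, 30)
  for (tab in list(probe_table_pre, probe_table_post)) {
    if (!all(c("direction_deg", "reach_deg") %in% names(tab))) {
      stop("probe tables need columns direction_deg and reach_deg")
    }
    if (!all(dirs %in% tab$direction_deg)) {
      stop("probe tables must cover all seven probe directions")
    }
  }
  change <- vapply(dirs, function(d) {
    mean(probe_table_post$reach_deg[probe_table_post$direction_deg == d]) -
      mean(probe_table_pre$reach_deg[probe_table_pre$direction_deg == d])
  }, numeric(1))
  at0 <- change[dirs == 0]
  if (abs(at0) < 1e-8) {
    stop("no adaptation at the trained direction; index undefined")
  }
  mean(change[dirs != 0] / at0)
}

#' Behavioral indices of one subject dataset
#'
#' @param dataset a \code{"subject_dataset"} from [generate_subject()] (or
#'   any list with the same fields).
#' @param final_window window for terminal quantities, default 100.
#' @return one-row data frame of class \code{"subject_indices"} with
#'   columns \code{condition}, \code{adaptation}, \code{reach_sd_final},
#'   \code{illusion_index}, \code{generalization_index},
#'   \code{reward_fraction}.
#' @export
subject_indices <- function(dataset, final_window = 100) {
  tr <- dataset$adaptation_series
  n <- nrow(tr)
  idx <- (n - final_window + 1):n
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- data.frame(
    condition = dataset$truth$condition$label,
    adaptation = abs(mean(tr$reach_deg[idx]) -
                       mean(tr$reach_deg[tr$phase == "baseline"])),
    reach_sd_final = pop_sd(tr$reach_deg[idx]),
    illusion_index = illusion_index(dataset$localization_pre,
                                    dataset$localization_post),
    generalization_index = generalization_index(dataset$generalization_pre,
                                                dataset$generalization_post),
    reward_fraction = mean(tr$rewarded[tr$phase != "baseline"]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_indices", "data.frame")
  out
}

#' Cross-subject illusion-generalization correlation
#'
#' Pearson correlation, across subjects, of the illusion index against the
#' generalization index. By default the signed illusion index is used:
#' under the clockwise-positive convention with a negative imposed
#' rotation, larger illusions are more negative, so a cohort in which
#' vision-reliant subjects both remap more and generalize more broadly
#' shows a negative correlation. \code{signed = FALSE} correlates the
#' illusion magnitude instead (flipping the expected sign).
#'
#' @param indices a data frame (rows = subjects) with columns
#'   \code{illusion_index} and \code{generalization_index}, e.g.
#'   \code{do.call(rbind, lapply(cohort, subject_indices))}.
#' @param signed use the signed illusion index (default) or its magnitude.
#' @return list with \code{R}, \code{n} and a descriptive \code{p_value}.
#' @export
cohort_correlation <- function(indices, signed = TRUE) {
  if (nrow(indices) < 3) stop("need at least 3 subjects")
  ill <- indices$illusion_index
  if (!signed) ill <- abs(ill)
  gen <- indices$generalization_index
  if (stats::sd(ill) == 0 || stats::sd(gen) == 0) {
    stop("a column is constant; correlation undefined")
  }
  ct <- stats::cor.test(ill, gen)
  list(R = unname(ct$estimate), n = nrow(indices),
       p_value = ct$p.value)
}

#' Group-level report across conditions
#'
#' Per-condition means and standard errors of every index, descriptive
#' pairwise Welch t-tests on each index (labelled descriptive: no
#' multiple-testing correction is applied), and a flag for whether reach
#' variability follows the ERR < EPE < RWD ordering. Illusion indices are
#' reported as magnitudes in the group table (per-subject records keep the
#' sign).
#'
#' @param cohorts named list mapping condition label to a data frame of
#'   [subject_indices()] rows (at least 2 conditions).
#' @param final_window unused placeholder for compatibility.
#' @return list of class \code{"group_report"} with \code{table} (one row
#'   per condition: mean and SE of each index; SE is \code{NA} for
#'   single-subject cohorts), \code{comparisons} (descriptive pairwise
#'   t-tests) and \code{variability_ordered} (logical or NA).
#' @export
group_report <- function(cohorts, final_window = 100) {
  if (length(cohorts) < 2) stop("need at least 2 conditions")
  metrics <- c("adaptation", "reach_sd_final", "illusion_index",
               "generalization_index", "reward_fraction")
  tab <- do.call(rbind, lapply(names(cohorts), function(cond) {
    df <- cohorts[[cond]]
    row <- data.frame(condition = cond, n = nrow(df),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      x <- df[[m]]
      if (m == "illusion_index") x <- abs(x)
      row[[paste0(m, "_mean")]] <- mean(x)
      row[[paste0(m, "_se")]] <- if (length(x) > 1)
        stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    row
  }))
  pairs <- utils::combn(names(cohorts), 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(metrics, function(m) {
      a <- cohorts[[pr[1]]][[m]]; b <- cohorts[[pr[2]]][[m]]
      if (m == "illusion_index") { a <- abs(a); b <- abs(b) }
      p <- if (length(a) > 1 && length(b) > 1 &&
               (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      } else NA_real_
      data.frame(pair = paste(pr, collapse = " vs "), metric = m,
                 difference = mean(a) - mean(b), p_descriptive = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  ordered <- NA
  if (all(c("ERR", "EPE", "RWD") %in% names(cohorts))) {
    sds <- vapply(c("ERR", "EPE", "RWD"),
                  function(cc) mean(cohorts[[cc]]$reach_sd_final),
                  numeric(1))
    ordered <- sds[1] < sds[2] && sds[2] < sds[3]
  }
  structure(
    list(table = tab, comparisons = comparisons,
         variability_ordered = ordered),
    class = "group_report"
  )
}

#' @export
print.group_report <- function(x, ...) {
  cat("Group report (descriptive statistics)\n")
  print(x$table, digits = 3, row.names = FALSE)
  if (!is.na(x$variability_ordered)) {
    cat("reach variability ordered ERR < EPE < RWD:",
        x$variability_ordered, "\n")
  }
  invisible(x)
}
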