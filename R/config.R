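#' Study configuration
#'
#' Central container for every tunable constant in the pipeline: the
#' adherence scoring windows, the screening cutoff, the reminder-escalation
#' offsets, the BP-measurement cadence, safety thresholds, hypertension
#' staging cutpoints and the statistical settings. Defaults reproduce the
#' study protocol: a 3-hour full-credit window (+/-90 min) inside a 6-hour
#' half-credit window (+/-180 min), a 0.85 screening cutoff, an escalation
#' ladder at 0/30/60/90 minutes, and a BP reminder every 3 days.
#'
#' @param full_window_min Half-width (minutes) of the full-credit dosing
#'   window. A dose opened within `full_window_min` of its scheduled time
#'   scores 1.0. Default 90 (the "3-hour window centered on the prescribed
#'   dosing time").
#' @param half_window_min Half-width (minutes) of the half-credit window;
#'   must exceed `full_window_min`. Openings beyond it never attach to a
#'   dose. Default 180.
#' @param eligibility_cutoff Screening-month adherence score below which a
#'   patient is classified non-adherent and trial-eligible. Strict: a score
#'   exactly at the cutoff is adherent. Default 0.85.
#' @param escalation_offsets_min Minutes after the scheduled dose time at
#'   which the four escalation events fire (compartment light, chime,
#'   patient message, coordinator alert). Must start at 0 and be strictly
#'   increasing. Default `c(0, 30, 60, 90)`.
#' @param bp_cadence_days Days between BP-measurement reminders. Default 3.
#' @param persistence_n Consecutive out-of-range BP sessions that count as
#'   "persistently" unsafe and trigger a physician alert. Default 2.
#' @param sbp_safe_range,dbp_safe_range Length-2 numeric, inclusive safe
#'   range in mmHg. Placeholders for the physician-set per-patient
#'   thresholds; override per patient in practice. Defaults `c(90, 180)`
#'   and `c(50, 110)`.
#' @param stage_thresholds Named list of lower cutpoints (mmHg) for the
#'   JNC 7 hypertension stages, each `c(sbp, dbp)`: readings at or above a
#'   cutpoint on either pressure reach that stage. Defaults: prehypertension
#'   120/80, stage 1 140/90, stage 2 160/100.
#' @param alpha Two-sided significance level for all tests and intervals.
#'   Default 0.05.
#' @param n_timepoints Number of evaluation timepoints in the trial design
#'   (also the default Bonferroni `k`). Default 4.
#' @param week_start Weekday anchoring report weeks, `"Monday"` or
#'   `"Sunday"`. Default Monday.
#' @param sphericity_correction Apply a Greenhouse-Geisser adjustment to
#'   within-subject p-values in [rm_anova()]? Default `FALSE` (uncorrected
#'   integer dfs).
#' @param rng_seed Optional integer seed recorded for provenance; the
#'   simulation functions take explicit `seed` arguments.
#'
#' @return A list of class `"study_config"`.
#' @examples
#' cfg <- study_config()
#' cfg$full_window_min
#' score_dose(150, cfg) # late-window half credit
#' @export
study_config <- function(full_window_min = 90,
                         half_window_min = 180,
                         eligibility_cutoff = 0.85,
                         escalation_offsets_min = c(0, 30, 60, 90),
                         bp_cadence_days = 3,
                         persistence_n = 2,
                         sbp_safe_range = c(90, 180),
                         dbp_safe_range = c(50, 110),
                         stage_thresholds = list(PREHTN = c(120, 80),
                                                 STAGE1 = c(140, 90),
                                                 STAGE2 = c(160, 100)),
                         alpha = 0.05,
                         n_timepoints = 4,
                         week_start = c("Monday", "Sunday"),
                         sphericity_correction = FALSE,
                         rng_seed = NULL) {
  week_start <- match.arg(week_start)
  stopifnot(
    full_window_min > 0,
    half_window_min > full_window_min,
    eligibility_cutoff > 0, eligibility_cutoff <= 1,
    length(escalation_offsets_min) >= 1,
    escalation_offsets_min[1] == 0,
    !is.unsorted(escalation_offsets_min, strictly = TRUE),
    bp_cadence_days >= 1,
    persistence_n >= 1,
    length(sbp_safe_range) == 2, sbp_safe_range[1] < sbp_safe_range[2],
    length(dbp_safe_range) == 2, dbp_safe_range[1] < dbp_safe_range[2],
    alpha > 0, alpha < 1,
    n_timepoints >= 2
  )
  structure(
    list(
      full_window_min = full_window_min,
      half_window_min = half_window_min,
      eligibility_cutoff = eligibility_cutoff,
      escalation_offsets_min = escalation_offsets_min,
      bp_cadence_days = bp_cadence_days,
      persistence_n = persistence_n,
      sbp_safe_range = sbp_safe_range,
      dbp_safe_range = dbp_safe_range,
      stage_thresholds = stage_thresholds,
      alpha = alpha,
      n_timepoints = n_timepoints,
      week_start = week_start,
      sphericity_correction = sphericity_correction,
      rng_seed = rng_seed
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  dosing windows : +/-%d min full, +/-%d min half credit\n",
              x$full_window_min, x$half_window_min))
  cat(sprintf("  eligibility    : adherence < %.2f\n", x$eligibility_cutoff))
  cat(sprintf("  escalation     : %s min\n",
              paste(x$escalation_offsets_min, collapse = "/")))
  cat(sprintf("  BP cadence     : every %d days; persistence n = %d\n",
              x$bp_cadence_days, x$persistence_n))
  cat(sprintf("  safe ranges    : SBP [%d, %d], DBP [%d, %d] mmHg\n",
              x$sbp_safe_range[1], x$sbp_safe_range[2],
              x$dbp_safe_range[1], x$dbp_safe_range[2]))
  cat(sprintf("  alpha = %.3f, %d timepoints, weeks start %s\n",
              x$alpha, x$n_timepoints, x$week_start))
  invisible(x)
}

# Coerce/verify a study_config argument.
as_study_config <- function(config) {
  if (is.null(config)) return(study_config())
  if (!inherits(config, "study_config")) {
    stop("`config` must be created by study_config()", call. = FALSE)
  }
  config
}

# Arm labels used throughout.
ARM_LEVELS <- c("MHEALTH", "SC")
TIMEPOINT_LEVELS <- c("BASELINE", "M1", "M2", "M3")
STAGE_LEVELS <- c("NORMAL", "PREHTN", "STAGE1", "STAGE2")
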