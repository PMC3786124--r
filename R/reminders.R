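#' @title Reminder escalation and safety alerts
#' @description
#' For the intervention arm the tray runs a fixed escalation ladder per
#' scheduled dose: the compartment light blinks at the dosing time, a loud
#' chime starts if the compartment is still closed after 30 minutes, an
#' automated message (call or text) goes to the patient at 60 minutes, and
#' at 90 minutes the study coordinator is alerted. Opening the compartment
#' resolves the ladder; an event fires only if the compartment is still
#' closed strictly before it (an opening exactly at +30 suppresses the
#' chime). The standard-care arm uses the same tray with every reminder
#' disabled and emits nothing. Home BP measurement is prompted every 3
#' days, and sessions outside the physician-set safe ranges raise alerts,
#' escalating to the treating physician when out-of-range readings
#' persist.
#' @name reminder-escalation
NULL

REMINDER_KINDS <- c("LIGHT_ON", "CHIME_ON", "PATIENT_MESSAGE",
                    "COORDINATOR_ALERT", "RESOLVED")

#' Escalation timeline for one dose
#'
#' @param dose_scheduled `POSIXct` scheduled dose time.
#' @param opened `POSIXct` opening time, or `NULL`/`NA` if the dose was
#'   never taken. Openings earlier than the half-credit window never reach
#'   this function (they are unmatched upstream).
#' @param arm `"MHEALTH"` or `"SC"`; the standard-care arm has reminders
#'   disabled and yields an empty timeline.
#' @param config A [study_config()]; `escalation_offsets_min` gives the
#'   ladder offsets (default 0/30/60/90 minutes).
#' @return A tibble `kind` (factor: `LIGHT_ON`, `CHIME_ON`,
#'   `PATIENT_MESSAGE`, `COORDINATOR_ALERT`, `RESOLVED`), `at` (`POSIXct`),
#'   time-ordered; `RESOLVED`, if present, is last.
#' @examples
#' t0 <- as.POSIXct("2013-02-01 09:00", tz = "UTC")
#' escalation_timeline(t0, NULL, "MHEALTH")          # full ladder
#' escalation_timeline(t0, t0 + 20 * 60, "MHEALTH")  # resolved before chime
#' @export
escalation_timeline <- function(dose_scheduled, opened = NULL,
                                arm = c("MHEALTH", "SC"),
                                config = study_config()) {
  arm <- match.arg(toupper(arm), ARM_LEVELS)
  config <- as_study_config(config)
  empty <- tibble::tibble(kind = factor(character(), REMINDER_KINDS),
                          at = as.POSIXct(numeric(), origin = "1970-01-01",
                                          tz = "UTC"))
  if (arm == "SC") return(empty)
  offsets <- config$escalation_offsets_min
  ladder_kinds <- REMINDER_KINDS[seq_along(offsets)]
  if (is.null(opened) || (length(opened) == 1 && is.na(opened))) {
    return(tibble::tibble(kind = factor(ladder_kinds, REMINDER_KINDS),
                          at = dose_scheduled + offsets * 60))
  }
  delay_min <- as.numeric(difftime(opened, dose_scheduled, units = "mins"))
  fired <- offsets < delay_min
  tibble::tibble(
    kind = factor(c(ladder_kinds[fired], "RESOLVED"), REMINDER_KINDS),
    at = c(dose_scheduled + offsets[fired] * 60, opened)
  )
}

#' BP measurement reminder schedule
#'
#' Dates on which the patient is texted to measure blood pressure: every
#' `bp_cadence_days` days (default 3) from `start_date` through
#' `end_date`.
#'
#' @param start_date,end_date Inclusive `Date` range; `start_date` must
#'   not follow `end_date`.
#' @param config A [study_config()].
#' @return A `Date` vector `start, start + cadence, ...` up to `end_date`.
#' @export
bp_reminder_schedule <- function(start_date, end_date,
                                 config = study_config()) {
  config <- as_study_config(config)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) {
    stop("start_date must not follow end_date", call. = FALSE)
  }
  seq(start_date, end_date, by = config$bp_cadence_days)
}

#' Threshold-based BP safety alerts
#'
#' Emits an `OUT_OF_RANGE` alert for every session whose SBP or DBP falls
#' outside its safe range, and one `PERSISTENT_OUT_OF_RANGE` alert per run
#' of `persistence_n` or more consecutive out-of-range sessions (fired at
#' the session where the run reaches `persistence_n`); persistent
#' violations are reported immediately to the treating physician.
#'
#' @param sessions Session-value tibble (columns `patient_id`,
#'   `session_id`, `at`, `sbp`, `dbp`), time-ordered within patient; one
#'   patient's own threshold settings per call.
#' @param config A [study_config()]; safe ranges default SBP \[90, 180\],
#'   DBP \[50, 110\] mmHg — placeholders for physician-set per-patient
#'   thresholds.
#' @return A tibble `patient_id`, `session_id`, `kind` (factor), `at`.
#' @export
bp_threshold_alerts <- function(sessions, config = study_config()) {
  config <- as_study_config(config)
  kinds <- c("OUT_OF_RANGE", "PERSISTENT_OUT_OF_RANGE")
  empty <- tibble::tibble(patient_id = character(), session_id = character(),
                          kind = factor(character(), kinds),
                          at = as.POSIXct(numeric(), origin = "1970-01-01",
                                          tz = "UTC"))
  if (!nrow(sessions)) return(empty)
  out_rows <- lapply(split(sessions, sessions$patient_id), function(s) {
    s <- s[order(s$at), ]
    out <- s$sbp < config$sbp_safe_range[1] | s$sbp > config$sbp_safe_range[2] |
      s$dbp < config$dbp_safe_range[1] | s$dbp > config$dbp_safe_range[2]
    run <- ifelse(out, sequence(rle(out)$lengths), 0L)
    alerts <- list()
    if (any(out)) {
      alerts$oor <- tibble::tibble(patient_id = s$patient_id[out],
                                   session_id = s$session_id[out],
                                   kind = "OUT_OF_RANGE", at = s$at[out])
    }
    pers <- run == config$persistence_n
    if (any(pers)) {
      alerts$pers <- tibble::tibble(patient_id = s$patient_id[pers],
                                    session_id = s$session_id[pers],
                                    kind = "PERSISTENT_OUT_OF_RANGE",
                                    at = s$at[pers])
    }
    dplyr::bind_rows(alerts)
  })
  out <- dplyr::bind_rows(out_rows)
  if (!nrow(out)) return(empty)
  out$kind <- factor(out$kind, kinds)
  dplyr::arrange(out, .data$patient_id, .data$at, .data$kind)
}
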