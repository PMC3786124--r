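#' @title Resting blood pressure reduction, staging and weekly reports
#' @description
#' The resting protocol takes one immediate acclimation reading, then —
#' after five minutes of rest — two further readings two minutes apart;
#' the session value is the average of the last two readings and the first
#' never contributes. When a protocol measurement is unavailable, a
#' registered-nurse clinic reading from the same day is substituted and
#' flagged. Session values are staged into JNC 7 categories (normal /
#' prehypertension / stage 1 / stage 2 — the paper trail names the stages;
#' the numeric cutpoints are the JNC 7 convention and live in the config)
#' and summarised, together with dose-taking, in the weekly provider
#' report.
#' @name bp-sessions
NULL

#' Reduce one session's raw readings to a session value
#'
#' @param session_rows Raw reading rows of a single session (columns
#'   `patient_id`, `session_id`, `timestamp`, `reading_index`, `sbp`,
#'   `dbp`, `source`): exactly 3 `PROTOCOL` readings in index order, or
#'   exactly 1 `NURSE` reading.
#' @return A one-row tibble `patient_id`, `session_id`, `at` (time of the
#'   first reading), `sbp`, `dbp` (session value, halves allowed),
#'   `source`, `substituted` (`TRUE` for a nurse reading). For a protocol
#'   session the value is the arithmetic mean of readings 1 and 2
#'   (0-based) — the acclimation reading 0 is discarded.
#' @examples
#' rows <- tibble::tibble(
#'   patient_id = "P1", session_id = "S1",
#'   timestamp = as.POSIXct("2013-02-01 08:00", tz = "UTC") + c(0, 420, 540),
#'   reading_index = 0:2, sbp = c(140, 130, 126), dbp = c(92, 84, 80),
#'   source = "PROTOCOL")
#' session_value(rows) # 128/82
#' @export
session_value <- function(session_rows) {
  src <- unique(as.character(session_rows$source))
  if (length(src) != 1) {
    stop("mixed sources within a session", call. = FALSE)
  }
  if (src == "PROTOCOL") {
    if (nrow(session_rows) != 3 ||
        !setequal(session_rows$reading_index, 0:2)) {
      stop("incomplete protocol session: need exactly 3 readings indexed 0..2",
           call. = FALSE)
    }
    last2 <- session_rows[session_rows$reading_index %in% 1:2, ]
    sbp <- mean(last2$sbp)
    dbp <- mean(last2$dbp)
  } else if (src == "NURSE") {
    if (nrow(session_rows) != 1) {
      stop("a nurse-substituted session must have exactly 1 reading",
           call. = FALSE)
    }
    sbp <- session_rows$sbp
    dbp <- session_rows$dbp
  } else {
    stop("unknown source: ", src, call. = FALSE)
  }
  tibble::tibble(
    patient_id = session_rows$patient_id[1],
    session_id = session_rows$session_id[1],
    at = min(session_rows$timestamp),
    sbp = sbp, dbp = dbp,
    source = factor(src, c("PROTOCOL", "NURSE")),
    substituted = src == "NURSE"
  )
}

#' Assemble raw BP rows into session values
#'
#' Applies [session_value()] per session; sessions that do not conform
#' (wrong reading count, mixed sources, bad indices) are quarantined with
#' a reason, never silently dropped.
#'
#' @param raw Raw reading tibble (layout of [read_bp_log()]'s input).
#' @param config A [study_config()] (reserved for per-study options).
#' @return A tibble of session values ordered by patient and time, with
#'   attribute `"quarantined"`: the offending raw rows plus a `reason`
#'   column.
#' @export
bp_sessions <- function(raw, config = study_config()) {
  keys <- unique(raw[c("patient_id", "session_id")])
  good <- list()
  bad <- list()
  for (i in seq_len(nrow(keys))) {
    rows <- raw[raw$patient_id == keys$patient_id[i] &
                  raw$session_id == keys$session_id[i], ]
    res <- tryCatch(session_value(rows), error = function(e) e)
    if (inherits(res, "error")) {
      rows$reason <- conditionMessage(res)
      bad[[length(bad) + 1L]] <- rows
    } else {
      good[[length(good) + 1L]] <- res
    }
  }
  out <- if (length(good)) dplyr::bind_rows(good) else
    tibble::tibble(patient_id = character(), session_id = character(),
                   at = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
                   sbp = numeric(), dbp = numeric(),
                   source = factor(character(), c("PROTOCOL", "NURSE")),
                   substituted = logical())
  out <- dplyr::arrange(out, .data$patient_id, .data$at)
  quarantined <- if (length(bad)) dplyr::bind_rows(bad) else {
    q <- raw[0, ]
    q$reason <- character()
    q
  }
  attr(out, "quarantined") <- quarantined
  out
}

#' Stage a blood pressure value
#'
#' JNC 7 staging: the category is the worse of the SBP-implied and
#' DBP-implied categories. With the default cutpoints: normal when
#' SBP < 120 and DBP < 80; prehypertension at 120-139 or 80-89; stage 1
#' hypertension at 140-159 or 90-99; stage 2 at SBP >= 160 or DBP >= 100.
#' Monotone: raising either pressure never lowers the category.
#'
#' @param sbp,dbp Session values in mmHg (vectorised).
#' @param config A [study_config()]; cutpoints in `stage_thresholds`.
#' @return Ordered factor with levels `NORMAL < PREHTN < STAGE1 < STAGE2`.
#' @examples
#' stage_reading(c(118, 125, 165), c(76, 95, 84))
#' @export
stage_reading <- function(sbp, dbp, config = study_config()) {
  config <- as_study_config(config)
  th <- config$stage_thresholds
  level <- function(v, cut) {
    (v >= cut[["PREHTN"]]) + (v >= cut[["STAGE1"]]) + (v >= cut[["STAGE2"]])
  }
  s_lvl <- level(sbp, lapply(th, `[`, 1))
  d_lvl <- level(dbp, lapply(th, `[`, 2))
  factor(STAGE_LEVELS[pmax(s_lvl, d_lvl) + 1L], STAGE_LEVELS, ordered = TRUE)
}

#' Weekly provider report
#'
#' One patient-week summary as emailed to the treating physician:
#' dose-taking counts and the windowed adherence score, BP-monitoring
#' adherence against the expected every-3-days schedule, mean session
#' SBP/DBP, and the percentage of session values in each hypertension
#' stage. Reducing the delay between non-adherence or uncontrolled BP and
#' a regimen change (clinical inertia) is the report's purpose.
#'
#' @param patient_id Patient identifier.
#' @param week_start First day of the 7-day report window (a `Date`;
#'   reports are conventionally anchored to the configured week start).
#' @param dose_events Dose-event tibble from [match_openings()] (any span;
#'   filtered to the window).
#' @param sessions Session-value tibble from [bp_sessions()] (any span;
#'   filtered to the window).
#' @param config A [study_config()].
#' @return A one-row tibble: `patient_id`, `week_start`, `doses_scheduled`,
#'   `doses_taken_full`, `doses_taken_half`, `doses_missed`,
#'   `med_adherence` (day-averaged window score), `pct_doses_taken`
#'   (raw fraction of doses with any credit — both adherence readings are
#'   emitted), `bp_sessions_done`, `bp_sessions_expected`,
#'   `bp_monitoring_adherence` (done/expected; may exceed 1 when the
#'   patient measured more often than scheduled — cap only for display),
#'   `sbp_mean`, `dbp_mean`, and `pct_normal`, `pct_prehtn`, `pct_stage1`,
#'   `pct_stage2` (percentages of session values per stage, summing to 100
#'   when any session exists, `NA` otherwise). A week with no scheduled
#'   doses leaves the medication fields `NA` but still reports BP.
#' @export
weekly_report <- function(patient_id, week_start, dose_events, sessions,
                          config = study_config()) {
  config <- as_study_config(config)
  week_start <- as.Date(week_start)
  week_end <- week_start + 6L

  de <- dose_events[as.Date(dose_events$scheduled, tz = "UTC") >= week_start &
                      as.Date(dose_events$scheduled, tz = "UTC") <= week_end, ]
  n_sched <- nrow(de)
  if (n_sched) {
    sc <- score_dose(de$delay_min, config)
    n_full <- sum(sc == 1)
    n_half <- sum(sc == 0.5)
    n_miss <- sum(sc == 0)
    med <- period_score(adherence_series(de, config))
    pct_taken <- (n_full + n_half) / n_sched
  } else {
    n_full <- n_half <- n_miss <- NA_integer_
    med <- pct_taken <- NA_real_
  }

  ss <- sessions[as.Date(sessions$at, tz = "UTC") >= week_start &
                   as.Date(sessions$at, tz = "UTC") <= week_end, ]
  expected <- length(bp_reminder_schedule(week_start, week_end, config))
  done <- nrow(ss)
  if (done) {
    stages <- stage_reading(ss$sbp, ss$dbp, config)
    pct <- 100 * as.numeric(table(stages)) / done
    sbp_mean <- mean(ss$sbp)
    dbp_mean <- mean(ss$dbp)
  } else {
    pct <- rep(NA_real_, 4)
    sbp_mean <- dbp_mean <- NA_real_
  }

  tibble::tibble(
    patient_id = patient_id, week_start = week_start,
    doses_scheduled = n_sched,
    doses_taken_full = n_full, doses_taken_half = n_half,
    doses_missed = n_miss,
    med_adherence = med, pct_doses_taken = pct_taken,
    bp_sessions_done = done, bp_sessions_expected = expected,
    bp_monitoring_adherence = done / expected,
    sbp_mean = sbp_mean, dbp_mean = dbp_mean,
    pct_normal = pct[1], pct_prehtn = pct[2],
    pct_stage1 = pct[3], pct_stage2 = pct[4]
  )
}
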