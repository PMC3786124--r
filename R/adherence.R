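#' @title Dose-window adherence scoring
#' @description
#' The adherence score is a windowed credit per scheduled dose, a
#' generalisation of the Russell MEMS score to regimens of 1-4 doses per
#' day: a tray opening within +/-90 minutes of the prescribed time earns
#' full credit (1.0), an opening outside that 3-hour window but within the
#' 6-hour window (+/-180 minutes) earns half credit (0.5), and a missed
#' dose scores 0. Per-dose credits are averaged to a daily score in
#' \[0, 1\] and daily scores are averaged — one day, one vote, regardless
#' of dose count — over a period (the screening "month" is a 30-day block
#' anchored at device activation). Patients scoring below 0.85 over the
#' screening month are classified non-adherent and trial-eligible.
#' @name adherence-scoring
NULL

#' Match tray openings to scheduled doses
#'
#' Greedy chronological assignment mirroring a one-compartment-per-dose
#' tray: openings are processed in time order and each attaches to the
#' earliest still-unmatched dose within the half-credit window
#' (`|delay| <= half_window_min`); each opening is used at most once
#' (first-come — a second opening of an already-served compartment is
#' surplus). Unmatched doses keep `opened = NA`; surplus openings are
#' returned in the `"surplus"` attribute.
#'
#' @param scheduled `POSIXct` vector of scheduled dose times (any span;
#'   sorted internally).
#' @param openings `POSIXct` vector of tray-opening times.
#' @param config A [study_config()].
#' @return A tibble of dose events — `scheduled`, `opened` (`POSIXct` or
#'   `NA`), `delay_min` (signed minutes, `opened - scheduled`, `NA` when
#'   missed) — with attribute `"surplus"` (`POSIXct` of unattached
#'   openings).
#' @examples
#' sched <- as.POSIXct(c("2013-02-01 09:00", "2013-02-01 21:00"), tz = "UTC")
#' open <- as.POSIXct("2013-02-01 09:40", tz = "UTC")
#' match_openings(sched, open)
#' @export
match_openings <- function(scheduled, openings, config = study_config()) {
  config <- as_study_config(config)
  scheduled <- sort(scheduled)
  openings <- sort(openings)
  n <- length(scheduled)
  opened <- rep(NA_real_, n)
  surplus <- logical(length(openings))
  for (j in seq_along(openings)) {
    delay <- as.numeric(difftime(openings[j], scheduled, units = "mins"))
    cand <- which(is.na(opened) & abs(delay) <= config$half_window_min)
    if (length(cand)) {
      opened[cand[1]] <- as.numeric(openings[j])
    } else {
      surplus[j] <- TRUE
    }
  }
  opened <- as.POSIXct(opened, origin = "1970-01-01", tz = "UTC")
  out <- tibble::tibble(
    scheduled = scheduled,
    opened = opened,
    delay_min = as.numeric(difftime(opened, scheduled, units = "mins"))
  )
  attr(out, "surplus") <- openings[surplus]
  out
}

#' Score a dose event
#'
#' Step function of the absolute delay between opening and scheduled time:
#' 1.0 within the full window, 0.5 within the half window, 0 otherwise
#' (including missed doses). Boundaries are inclusive toward the better
#' score — patients were instructed that taking medication within 90
#' minutes on either side of the prescribed time counts as adherent, so a
#' delay of exactly 90 minutes earns full credit and exactly 180 minutes
#' earns half credit.
#'
#' @param delay_min Signed delay in minutes (vectorised); `NA` = missed.
#' @param config A [study_config()].
#' @return Numeric vector of scores in `{0, 0.5, 1}`.
#' @examples
#' score_dose(c(45, 150, NA, 90, 180, 181))
#' @export
score_dose <- function(delay_min, config = study_config()) {
  config <- as_study_config(config)
  d <- abs(delay_min)
  ifelse(is.na(d), 0,
         ifelse(d <= config$full_window_min, 1,
                ifelse(d <= config$half_window_min, 0.5, 0)))
}

#' Daily adherence score
#'
#' Arithmetic mean of the per-dose scores of one calendar day. A day with
#' no scheduled doses has no score (it is excluded from period averages,
#' not scored 0): the function signals that case by returning `NA`.
#'
#' @param events A dose-event tibble (one day) as from [match_openings()].
#' @param config A [study_config()].
#' @return A single score in `[0, 1]`, or `NA` for an empty day.
#' @export
daily_score <- function(events, config = study_config()) {
  if (!nrow(events)) return(NA_real_)
  mean(score_dose(events$delay_min, config))
}

#' Per-day adherence series
#'
#' Collapses a patient's dose events into one score per calendar day
#' (days without scheduled doses are absent, not zero).
#'
#' @param events A dose-event tibble as from [match_openings()].
#' @param config A [study_config()].
#' @return A tibble `date`, `n_doses`, `score` ordered by date.
#' @export
adherence_series <- function(events, config = study_config()) {
  config <- as_study_config(config)
  if (!nrow(events)) {
    return(tibble::tibble(date = as.Date(character()), n_doses = integer(),
                          score = numeric()))
  }
  events$date <- as.Date(events$scheduled, tz = "UTC")
  events$dose_score <- score_dose(events$delay_min, config)
  out <- dplyr::summarise(dplyr::group_by(events, .data$date),
                          n_doses = dplyr::n(),
                          score = mean(.data$dose_score), .groups = "drop")
  dplyr::arrange(out, .data$date)
}

#' Period adherence score
#'
#' Unweighted mean of daily scores over the days present in a window —
#' equal day weighting regardless of how many doses each day carries. The
#' study "month" is a consecutive 30-day block anchored at the patient's
#' device activation date.
#'
#' @param series A daily series from [adherence_series()] (columns `date`,
#'   `score`).
#' @param window Optional `c(start, end)` `Date` pair (inclusive); default
#'   uses every scored day.
#' @return Mean daily score in `[0, 1]`, or `NA` when the window contains
#'   no scored day.
#' @export
period_score <- function(series, window = NULL) {
  daily <- series$score
  if (!is.null(window)) {
    window <- as.Date(window)
    daily <- series$score[series$date >= window[1] & series$date <= window[2]]
  }
  if (!length(daily)) return(NA_real_)
  mean(daily)
}

#' Classify screening eligibility
#'
#' Patients with a screening-month adherence score strictly below the
#' cutoff (default 0.85) are non-adherent and eligible for randomization;
#' a score at or above the cutoff — including exactly at it — is adherent
#' and ineligible.
#'
#' @param period_score Score(s) in `[0, 1]` (vectorised; `NA` passes
#'   through).
#' @param config A [study_config()].
#' @return Factor with levels `NON_ADHERENT_ELIGIBLE`,
#'   `ADHERENT_INELIGIBLE`.
#' @examples
#' classify_eligibility(c(0.57, 0.90, 0.85))
#' @export
classify_eligibility <- function(period_score, config = study_config()) {
  config <- as_study_config(config)
  stopifnot(all(is.na(period_score) | (period_score >= 0 & period_score <= 1)))
  factor(ifelse(period_score < config$eligibility_cutoff,
                "NON_ADHERENT_ELIGIBLE", "ADHERENT_INELIGIBLE"),
         levels = c("NON_ADHERENT_ELIGIBLE", "ADHERENT_INELIGIBLE"))
}

# Expand a regimen into scheduled dose datetimes over a date window,
# clipped to each patient's active range.
scheduled_doses <- function(regimen, window_start, window_days) {
  window_start <- as.Date(window_start)
  days <- seq(window_start, by = "day", length.out = window_days)
  out <- lapply(split(regimen, regimen$patient_id), function(r) {
    d <- days[days >= min(r$start_date) & days <= max(r$end_date)]
    if (!length(d)) return(NULL)
    grid <- expand.grid(date = d, time_of_day = r$time_of_day)
    tibble::tibble(
      patient_id = r$patient_id[1],
      scheduled = as.POSIXct(grid$date, tz = "UTC") + grid$time_of_day * 60
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(patient_id = character(),
                          scheduled = parse_timestamp(character())))
  }
  dplyr::arrange(out, .data$patient_id, .data$scheduled)
}

#' Score every patient over a window
#'
#' End-to-end scoring: expands each patient's regimen into scheduled doses
#' over the window (clipped to the regimen's active range), matches the
#' event log with [match_openings()], averages to daily then period scores,
#' and classifies eligibility against the screening cutoff.
#'
#' @param events An event-log tibble from [read_event_log()] or
#'   [simulate_trial()].
#' @param regimen A regimen tibble from [read_regimen()].
#' @param window_start First date of the scoring window (e.g. device
#'   activation).
#' @param window_days Window length in days (default 30, the screening
#'   month).
#' @param config A [study_config()].
#' @return A tibble with one row per patient in `regimen`: `patient_id`,
#'   `n_days` (scored days), `period_score`, `eligibility`.
#' @export
score_patients <- function(events, regimen, window_start, window_days = 30,
                           config = study_config()) {
  config <- as_study_config(config)
  sched <- scheduled_doses(regimen, window_start, window_days)
  ev_by_pat <- split(events$timestamp, events$patient_id)
  rows <- lapply(split(sched, sched$patient_id), function(s) {
    pid <- s$patient_id[1]
    opens <- ev_by_pat[[pid]] %||% parse_timestamp(character())
    de <- match_openings(s$scheduled, opens, config)
    series <- adherence_series(de, config)
    tibble::tibble(patient_id = pid, n_days = nrow(series),
                   period_score = period_score(series))
  })
  out <- dplyr::bind_rows(rows)
  missing <- setdiff(unique(regimen$patient_id), out$patient_id)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      patient_id = missing, n_days = 0L, period_score = NA_real_))
  }
  out$eligibility <- classify_eligibility(out$period_score, config)
  dplyr::arrange(out, .data$patient_id)
}
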