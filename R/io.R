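#' @title Reading and writing study logs
#' @description
#' The pipeline consumes four comma-separated, UTF-8, headered files:
#'
#' * `events.csv`  — `patient_id,timestamp,compartment`; one tray opening
#'   per row, timestamps ISO 8601 at minute resolution
#'   (`YYYY-MM-DDTHH:MM`, a space separator is also accepted).
#' * `regimen.csv` — `patient_id,arm,dose_label,time_of_day,start_date,
#'   end_date`; one row per prescribed daily dose, `time_of_day` as
#'   `HH:MM`.
#' * `bp.csv`      — `patient_id,session_id,timestamp,reading_index,sbp,
#'   dbp,source`; raw readings, `reading_index` 0..2, `source`
#'   `PROTOCOL` or `NURSE`.
#' * `roster.csv`  — `patient_id,arm,age_years`.
#'
#' All timestamps are naive local civil time (no timezone or DST
#' arithmetic); internally they are held as UTC `POSIXct` so that minute
#' arithmetic is exact.
#' @name study-io
NULL

# ---- timestamp handling -----------------------------------------------

# Strict minute-resolution ISO 8601 parser; returns POSIXct (UTC) or NA.
parse_timestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}(:\\d{2})?$", x)
  # strptime (unlike as.POSIXct) yields NA for impossible dates
  parsed <- strptime(x, "%Y-%m-%d %H:%M", tz = "UTC")
  with_sec <- strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  parsed[is.na(parsed)] <- with_sec[is.na(parsed)]
  out <- as.POSIXct(parsed, tz = "UTC")
  out[!ok] <- NA
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M", tz = "UTC")

parse_time_of_day <- function(x) {
  ok <- grepl("^\\d{1,2}:\\d{2}$", x)
  h <- suppressWarnings(as.integer(sub(":.*", "", x)))
  m <- suppressWarnings(as.integer(sub(".*:", "", x)))
  ok <- ok & !is.na(h) & !is.na(m) & h < 24 & m < 60
  ifelse(ok, h * 60L + m, NA_integer_)
}

format_time_of_day <- function(min) sprintf("%02d:%02d", min %/% 60L, min %% 60L)

read_study_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8", strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Error citing file, data row (header = row 1) and column.
row_error <- function(path, rows, column, what) {
  stop(sprintf("%s: row %s, column '%s': %s", basename(path),
               paste(rows + 1L, collapse = ", "), column, what),
       call. = FALSE)
}

parse_column <- function(df, path, column, parser, what) {
  out <- parser(df[[column]])
  bad <- which(is.na(out))
  if (length(bad)) row_error(path, head(bad, 5L), column, what)
  out
}

# ---- readers ----------------------------------------------------------

#' Read a tray-opening event log
#'
#' Parses `events.csv`, sorts ascending by patient then timestamp, and
#' collapses duplicate rows (same patient and minute — tray hardware can
#' double-report a single opening) to one with a warning. Output order is
#' deterministic regardless of input row order.
#'
#' @param path Path to the events CSV.
#' @return A tibble with columns `patient_id` (character), `timestamp`
#'   (`POSIXct`, minute resolution) and `compartment` (character).
#' @export
read_event_log <- function(path) {
  df <- read_study_csv(path, c("patient_id", "timestamp"))
  if (!nrow(df)) {
    return(tibble::tibble(patient_id = character(), timestamp = parse_timestamp(character()),
                          compartment = character()))
  }
  ts <- parse_column(df, path, "timestamp", parse_timestamp,
                     "unparseable timestamp (expected YYYY-MM-DDTHH:MM)")
  out <- tibble::tibble(
    patient_id = df$patient_id,
    timestamp = ts,
    compartment = if ("compartment" %in% names(df)) df$compartment else NA_character_
  )
  out <- dplyr::arrange(out, .data$patient_id, .data$timestamp)
  dup <- duplicated(out[c("patient_id", "timestamp")])
  if (any(dup)) {
    warning(sprintf("%s: collapsed %d duplicate opening(s) at identical minute",
                    basename(path), sum(dup)), call. = FALSE)
    out <- out[!dup, ]
  }
  out
}

#' Read a medication regimen
#'
#' Parses `regimen.csv` (one row per prescribed daily dose), groups doses
#' per patient sorted by time of day, and parses the trial arm
#' case-insensitively. The tray supports up to 4 doses per day; more is an
#' error, as are duplicate dose times within a patient.
#'
#' @param path Path to the regimen CSV.
#' @return A tibble with one row per (patient, dose): `patient_id`, `arm`
#'   (factor `MHEALTH`/`SC`), `dose_label`, `time_of_day` (integer minutes
#'   from midnight), `start_date`, `end_date` (`Date`, inclusive).
#' @export
read_regimen <- function(path) {
  df <- read_study_csv(path, c("patient_id", "arm", "dose_label",
                               "time_of_day", "start_date", "end_date"))
  if (!nrow(df)) {
    return(tibble::tibble(patient_id = character(),
                          arm = factor(character(), ARM_LEVELS),
                          dose_label = character(), time_of_day = integer(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character())))
  }
  arm_raw <- toupper(trimws(df$arm))
  bad <- which(!arm_raw %in% ARM_LEVELS)
  if (length(bad)) row_error(path, head(bad, 5L), "arm",
                             paste0("unknown arm label '", df$arm[bad[1]],
                                    "' (expected MHEALTH or SC)"))
  tod <- parse_column(df, path, "time_of_day", parse_time_of_day,
                      "unparseable time of day (expected HH:MM)")
  sd <- parse_column(df, path, "start_date",
                     function(x) as.Date(x, optional = TRUE), "unparseable date")
  ed <- parse_column(df, path, "end_date",
                     function(x) as.Date(x, optional = TRUE), "unparseable date")
  out <- tibble::tibble(
    patient_id = df$patient_id,
    arm = factor(arm_raw, ARM_LEVELS),
    dose_label = df$dose_label,
    time_of_day = tod,
    start_date = sd,
    end_date = ed
  )
  out <- dplyr::arrange(out, .data$patient_id, .data$time_of_day)
  per <- table(out$patient_id)
  if (any(per > 4L)) {
    stop(sprintf("%s: patient(s) %s exceed the tray capacity of up to 4 doses per day",
                 basename(path),
                 paste(names(per)[per > 4L], collapse = ", ")), call. = FALSE)
  }
  dup_t <- duplicated(out[c("patient_id", "time_of_day")])
  if (any(dup_t)) {
    stop(sprintf("%s: duplicate dose times within a patient (dose times must be strictly increasing)",
                 basename(path)), call. = FALSE)
  }
  bad_rng <- out$start_date > out$end_date
  if (any(bad_rng)) {
    stop(sprintf("%s: start_date after end_date for patient(s) %s", basename(path),
                 paste(unique(out$patient_id[bad_rng]), collapse = ", ")),
         call. = FALSE)
  }
  multi_arm <- tapply(as.character(out$arm), out$patient_id,
                      function(a) length(unique(a)))
  if (any(multi_arm > 1L)) {
    stop(sprintf("%s: conflicting arm labels within a patient", basename(path)),
         call. = FALSE)
  }
  out
}

#' Read a raw blood-pressure log and assemble sessions
#'
#' Parses `bp.csv`, validates each reading (pressures must satisfy
#' `40 <= dbp < sbp <= 300`, reading indices unique within a session), and
#' reduces sessions via [bp_sessions()]: a session passes with exactly 3
#' `PROTOCOL` readings (value = mean of the last two; the first,
#' acclimation, reading never contributes) or exactly 1 `NURSE` reading
#' (the same-day clinic substitution). Malformed sessions are quarantined
#' with a warning — never silently dropped — and returned in the
#' `"quarantined"` attribute so report counts stay auditable.
#'
#' @param path Path to the BP CSV.
#' @param config A [study_config()].
#' @return A tibble of session values (see [bp_sessions()]) with attribute
#'   `"quarantined"`: a tibble of rejected raw rows with a `reason` column.
#' @export
read_bp_log <- function(path, config = study_config()) {
  df <- read_study_csv(path, c("patient_id", "session_id", "timestamp",
                               "reading_index", "sbp", "dbp", "source"))
  raw <- if (nrow(df)) {
    ts <- parse_column(df, path, "timestamp", parse_timestamp,
                       "unparseable timestamp (expected YYYY-MM-DDTHH:MM)")
    idx <- parse_column(df, path, "reading_index",
                        function(x) suppressWarnings(as.integer(x)),
                        "unparseable reading index")
    sbp <- parse_column(df, path, "sbp",
                        function(x) suppressWarnings(as.numeric(x)),
                        "unparseable systolic pressure")
    dbp <- parse_column(df, path, "dbp",
                        function(x) suppressWarnings(as.numeric(x)),
                        "unparseable diastolic pressure")
    src <- toupper(trimws(df$source))
    bad_src <- which(!src %in% c("PROTOCOL", "NURSE"))
    if (length(bad_src)) row_error(path, head(bad_src, 5L), "source",
                                   "source must be PROTOCOL or NURSE")
    bad_bp <- which(!(dbp >= 40 & dbp < sbp & sbp <= 300))
    if (length(bad_bp)) {
      row_error(path, head(bad_bp, 5L), "sbp/dbp",
                "implausible pressures (need 40 <= dbp < sbp <= 300)")
    }
    tibble::tibble(patient_id = df$patient_id, session_id = df$session_id,
                   timestamp = ts, reading_index = idx, sbp = sbp, dbp = dbp,
                   source = factor(src, c("PROTOCOL", "NURSE")))
  } else {
    tibble::tibble(patient_id = character(), session_id = character(),
                   timestamp = parse_timestamp(character()),
                   reading_index = integer(), sbp = numeric(), dbp = numeric(),
                   source = factor(character(), c("PROTOCOL", "NURSE")))
  }
  dup_idx <- duplicated(raw[c("patient_id", "session_id", "reading_index")])
  if (any(dup_idx)) {
    row_error(path, head(which(dup_idx), 5L), "reading_index",
              "duplicate reading index within a session")
  }
  res <- bp_sessions(raw, config = config)
  if (nrow(attr(res, "quarantined"))) {
    warning(sprintf("%s: quarantined %d malformed session(s) (%d raw rows)",
                    basename(path),
                    length(unique(attr(res, "quarantined")$session_id)),
                    nrow(attr(res, "quarantined"))), call. = FALSE)
  }
  res
}

#' Read a trial roster
#'
#' @param path Path to `roster.csv` (`patient_id,arm,age_years`).
#' @return A tibble: `patient_id`, `arm` (factor), `age_years` (numeric).
#' @export
read_roster <- function(path) {
  df <- read_study_csv(path, c("patient_id", "arm", "age_years"))
  if (!nrow(df)) {
    return(tibble::tibble(patient_id = character(),
                          arm = factor(character(), ARM_LEVELS),
                          age_years = numeric()))
  }
  arm_raw <- toupper(trimws(df$arm))
  bad <- which(!arm_raw %in% ARM_LEVELS)
  if (length(bad)) row_error(path, head(bad, 5L), "arm", "unknown arm label")
  age <- parse_column(df, path, "age_years",
                      function(x) suppressWarnings(as.numeric(x)),
                      "unparseable age")
  dplyr::arrange(
    tibble::tibble(patient_id = df$patient_id,
                   arm = factor(arm_raw, ARM_LEVELS), age_years = age),
    .data$patient_id)
}

#' Read a long-format trial outcome table
#'
#' @param path Path to `trial.csv` with columns `patient_id,arm,timepoint,
#'   adherence,sbp,dbp,age_years` (outcomes may be blank for missing).
#' @return A tibble suitable for [rm_anova()]: `timepoint` is a factor with
#'   levels `BASELINE, M1, M2, M3`.
#' @export
read_trial_table <- function(path) {
  df <- read_study_csv(path, c("patient_id", "arm", "timepoint"))
  num <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(ifelse(df[[col]] == "", NA, df[[col]])))
  }
  arm_raw <- toupper(trimws(df$arm))
  bad <- which(!arm_raw %in% ARM_LEVELS)
  if (length(bad)) row_error(path, head(bad, 5L), "arm", "unknown arm label")
  tp <- toupper(trimws(df$timepoint))
  bad <- which(!tp %in% TIMEPOINT_LEVELS)
  if (length(bad)) row_error(path, head(bad, 5L), "timepoint",
                             "timepoint must be one of BASELINE, M1, M2, M3")
  out <- tibble::tibble(
    patient_id = df$patient_id,
    arm = factor(arm_raw, ARM_LEVELS),
    timepoint = factor(tp, TIMEPOINT_LEVELS),
    adherence = num("adherence"), sbp = num("sbp"), dbp = num("dbp"),
    age_years = num("age_years")
  )
  if (anyDuplicated(out[c("patient_id", "timepoint")])) {
    stop(sprintf("%s: more than one row per (patient, timepoint)", basename(path)),
         call. = FALSE)
  }
  dplyr::arrange(out, .data$patient_id, .data$timepoint)
}

# ---- writers ----------------------------------------------------------

#' Write study logs
#'
#' Inverse of the readers: writing then reading any valid log reproduces
#' the same records at minute / mmHg resolution.
#'
#' @param x A tibble in the corresponding reader's layout. For
#'   `write_bp_log()`, raw readings (as produced by the simulator) with
#'   columns `patient_id,session_id,timestamp,reading_index,sbp,dbp,source`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(x, path) {
  df <- data.frame(patient_id = x$patient_id,
                   timestamp = format_timestamp(x$timestamp),
                   compartment = x$compartment)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_regimen <- function(x, path) {
  df <- data.frame(patient_id = x$patient_id, arm = as.character(x$arm),
                   dose_label = x$dose_label,
                   time_of_day = format_time_of_day(x$time_of_day),
                   start_date = format(x$start_date),
                   end_date = format(x$end_date))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_bp_log <- function(x, path) {
  df <- data.frame(patient_id = x$patient_id, session_id = x$session_id,
                   timestamp = format_timestamp(x$timestamp),
                   reading_index = x$reading_index,
                   sbp = x$sbp, dbp = x$dbp, source = as.character(x$source))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_roster <- function(x, path) {
  df <- data.frame(patient_id = x$patient_id, arm = as.character(x$arm),
                   age_years = x$age_years)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_log
#' @export
write_trial_table <- function(x, path) {
  df <- data.frame(patient_id = x$patient_id, arm = as.character(x$arm),
                   timepoint = as.character(x$timepoint),
                   adherence = x$adherence, sbp = x$sbp, dbp = x$dbp,
                   age_years = x$age_years)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' Write a simulated study to a directory
#'
#' Writes `events.csv`, `regimen.csv`, `bp.csv`, `roster.csv` and
#' `trial.csv` for a [simulate_trial()] result.
#'
#' @param sim A list as returned by [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_event_log(sim$events, file.path(dir, "events.csv"))
  write_regimen(sim$regimen, file.path(dir, "regimen.csv"))
  write_bp_log(sim$bp, file.path(dir, "bp.csv"))
  write_roster(sim$roster, file.path(dir, "roster.csv"))
  write_trial_table(sim$trial, file.path(dir, "trial.csv"))
  invisible(dir)
}

# ---- validation -------------------------------------------------------

#' Validate a study directory
#'
#' Reads every log in `dir`, cross-checks them (openings outside a
#' patient's regimen active range are flagged, not dropped; arm labels must
#' agree between regimen and roster) and summarises quarantines.
#'
#' @param dir Directory containing `events.csv`, `regimen.csv`, `bp.csv`
#'   and `roster.csv`.
#' @param config A [study_config()].
#' @return A list of class `"study_validation"`: the parsed tibbles plus
#'   `n_events`, `n_out_of_range` (flagged openings), `n_quarantined_rows`,
#'   `n_quarantined_sessions`, and `ok` (`TRUE` when nothing was flagged or
#'   quarantined).
#' @export
validate_study <- function(dir, config = study_config()) {
  config <- as_study_config(config)
  events <- read_event_log(file.path(dir, "events.csv"))
  regimen <- read_regimen(file.path(dir, "regimen.csv"))
  bp <- withCallingHandlers(
    read_bp_log(file.path(dir, "bp.csv"), config = config),
    warning = function(w) invokeRestart("muffleWarning"))
  roster <- read_roster(file.path(dir, "roster.csv"))

  rng <- dplyr::summarise(dplyr::group_by(regimen, .data$patient_id),
                          start = min(.data$start_date),
                          end = max(.data$end_date), .groups = "drop")
  ev <- dplyr::left_join(events, rng, by = "patient_id")
  out_of_range <- !is.na(ev$start) &
    (as.Date(ev$timestamp, tz = "UTC") < ev$start |
       as.Date(ev$timestamp, tz = "UTC") > ev$end)
  events$out_of_range <- out_of_range

  arms <- dplyr::distinct(regimen, .data$patient_id, .data$arm)
  joined <- dplyr::inner_join(arms, roster, by = "patient_id",
                              suffix = c("_regimen", "_roster"))
  arm_mismatch <- sum(as.character(joined$arm_regimen) !=
                        as.character(joined$arm_roster))

  quarantined <- attr(bp, "quarantined")
  structure(
    list(events = events, regimen = regimen, bp = bp, roster = roster,
         n_events = nrow(events),
         n_out_of_range = sum(out_of_range),
         n_quarantined_rows = nrow(quarantined),
         n_quarantined_sessions = length(unique(quarantined$session_id)),
         n_arm_mismatch = arm_mismatch,
         ok = sum(out_of_range) == 0 && nrow(quarantined) == 0 &&
           arm_mismatch == 0),
    class = "study_validation")
}

#' @export
print.study_validation <- function(x, ...) {
  cat("<study_validation>\n")
  cat(sprintf("  %d patients, %d tray openings, %d BP sessions\n",
              length(unique(x$roster$patient_id)), x$n_events, nrow(x$bp)))
  cat(sprintf("  flagged out-of-range openings : %d\n", x$n_out_of_range))
  cat(sprintf("  quarantined BP sessions       : %d (%d raw rows)\n",
              x$n_quarantined_sessions, x$n_quarantined_rows))
  cat(sprintf("  arm mismatches regimen/roster : %d\n", x$n_arm_mismatch))
  cat(if (x$ok) "  OK\n" else "  PROBLEMS FOUND\n")
  invisible(x)
}
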