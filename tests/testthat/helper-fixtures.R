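# Fixture builders: every fixture is constructed in code at test time.

`%||%` <- function(x, y) if (is.null(x)) y else x

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

write_tmp_csv <- function(lines, name = "fixture.csv") {
  dir <- tempfile("fixture")
  dir.create(dir)
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

events_csv <- function(rows) {
  write_tmp_csv(c("patient_id,timestamp,compartment", rows), "events.csv")
}

regimen_csv <- function(rows) {
  write_tmp_csv(c("patient_id,arm,dose_label,time_of_day,start_date,end_date",
                  rows), "regimen.csv")
}

bp_csv <- function(rows) {
  write_tmp_csv(c("patient_id,session_id,timestamp,reading_index,sbp,dbp,source",
                  rows), "bp.csv")
}

# A protocol session's three raw rows as CSV lines.
protocol_rows <- function(pid, sid, date, sbp, dbp) {
  sprintf("%s,%s,%sT08:%02d,%d,%d,%d,PROTOCOL", pid, sid, date,
          c(0, 7, 9), 0:2, sbp, dbp)
}

# Raw BP reading tibble for one protocol session.
protocol_tibble <- function(pid = "P1", sid = "S1", sbp, dbp,
                            at = ts_utc("2013-02-01 08:00")) {
  tibble::tibble(patient_id = pid, session_id = sid,
                 timestamp = at + c(0, 420, 540),
                 reading_index = 0:2, sbp = sbp, dbp = dbp,
                 source = "PROTOCOL")
}

# Long trial table from per-arm outcome matrices (patients x timepoints).
trial_table <- function(a, b, timepoints = NULL) {
  t_lv <- ncol(a)
  timepoints <- timepoints %||% c("BASELINE", "M1", "M2", "M3")[seq_len(t_lv)]
  mk <- function(m, arm, off) {
    tibble::tibble(
      patient_id = rep(sprintf("%s%02d", arm, seq_len(nrow(m)) + off), each = t_lv),
      arm = factor(arm, c("MHEALTH", "SC")),
      timepoint = factor(rep(timepoints, nrow(m)), timepoints),
      adherence = as.vector(t(m)), sbp = as.vector(t(m)),
      dbp = as.vector(t(m)), age_years = 50)
  }
  dplyr::bind_rows(mk(a, "MHEALTH", 0), mk(b, "SC", 0))
}

# Session-value tibble with given pressures, 3 days apart.
session_values <- function(sbp, dbp = rep(70, length(sbp)), pid = "P1") {
  tibble::tibble(patient_id = pid,
                 session_id = sprintf("S%02d", seq_along(sbp)),
                 at = ts_utc("2013-02-01 08:00") + (seq_along(sbp) - 1) * 86400,
                 sbp = sbp, dbp = dbp)
}
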