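test_that("event logs parse, sort deterministically, and collapse duplicate minutes", {
  path <- events_csv(c("P2,2013-02-01T21:05,B",
                       "P1,2013-02-01T09:10,A",
                       "P1,2013-02-01T08:55,A"))
  ev <- read_event_log(path)
  expect_equal(ev$patient_id, c("P1", "P1", "P2"))
  expect_equal(ev$timestamp,
               ts_utc(c("2013-02-01 08:55", "2013-02-01 09:10",
                        "2013-02-01 21:05")))

  # same rows, shuffled -> identical output
  path2 <- events_csv(c("P1,2013-02-01T08:55,A",
                        "P2,2013-02-01T21:05,B",
                        "P1,2013-02-01T09:10,A"))
  expect_identical(read_event_log(path2), ev)

  dup <- events_csv(c("P1,2013-02-01T09:10,A", "P1,2013-02-01T09:10,A"))
  expect_warning(evd <- read_event_log(dup), "duplicate")
  expect_equal(nrow(evd), 1)

  empty <- events_csv(character())
  expect_equal(nrow(read_event_log(empty)), 0)
})

test_that("malformed event rows raise errors naming file, row and column", {
  bad <- events_csv(c("P1,2013-13-01T09:00,A"))
  expect_error(read_event_log(bad), "events\\.csv.*row 2.*timestamp")
  nocol <- write_tmp_csv(c("patient_id,when", "P1,2013-02-01T09:00"))
  expect_error(read_event_log(nocol), "missing column")
})

test_that("regimens group doses per patient and enforce tray constraints", {
  path <- regimen_csv(c(
    "P1,mHealth,PM,21:00,2013-02-01,2013-03-02",
    "P1,mHealth,AM,09:00,2013-02-01,2013-03-02",
    "P2,sc,AM,08:00,2013-02-01,2013-03-02"))
  reg <- read_regimen(path)
  expect_equal(reg$time_of_day[reg$patient_id == "P1"], c(540L, 1260L))
  # arm parsed case-insensitively
  expect_equal(as.character(reg$arm), c("MHEALTH", "MHEALTH", "SC"))

  five <- regimen_csv(sprintf("P1,SC,D%d,%02d:00,2013-02-01,2013-03-02",
                              1:5, c(6, 10, 14, 18, 22)))
  expect_error(read_regimen(five), "4 doses per day")

  badarm <- regimen_csv("P1,placebo,AM,09:00,2013-02-01,2013-03-02")
  expect_error(read_regimen(badarm), "arm")

  duptime <- regimen_csv(c("P1,SC,A,09:00,2013-02-01,2013-03-02",
                           "P1,SC,B,09:00,2013-02-01,2013-03-02"))
  expect_error(read_regimen(duptime), "strictly increasing")
})

test_that("BP logs assemble protocol and nurse sessions, quarantining the rest", {
  path <- bp_csv(c(
    protocol_rows("P1", "S1", "2013-02-01", c(140, 130, 126), c(92, 84, 80)),
    "P1,S2,2013-02-04T08:00,0,138,86,NURSE",
    protocol_rows("P1", "S3", "2013-02-07", c(150, 140, 138), c(95, 88, 86))[1:2]))
  expect_warning(sess <- read_bp_log(path), "quarantined 1")
  expect_equal(nrow(sess), 2)
  expect_equal(sess$sbp[sess$session_id == "S1"], 128)
  expect_equal(sess$dbp[sess$session_id == "S1"], 82)
  expect_true(sess$substituted[sess$session_id == "S2"])
  q <- attr(sess, "quarantined")
  expect_equal(unique(q$session_id), "S3")
  expect_match(q$reason[1], "incomplete protocol")

  inverted <- bp_csv("P1,S1,2013-02-01T08:00,0,80,120,PROTOCOL")
  expect_error(read_bp_log(inverted), "row 2.*dbp < sbp")
})

test_that("writing then reading reproduces records field-wise", {
  withr::with_seed(11, {
    sim <- simulate_trial(n_per_arm = 2, seed = 5)
  })
  dir <- withr::local_tempdir()
  write_study(sim, dir)
  ev <- read_event_log(file.path(dir, "events.csv"))
  expect_equal(ev$timestamp, sim$events$timestamp)
  expect_equal(ev$patient_id, sim$events$patient_id)
  reg <- read_regimen(file.path(dir, "regimen.csv"))
  expect_equal(reg$time_of_day, sim$regimen$time_of_day)
  expect_equal(reg$start_date, sim$regimen$start_date)
  ros <- read_roster(file.path(dir, "roster.csv"))
  expect_equal(ros$age_years, sim$roster$age_years)
  tri <- read_trial_table(file.path(dir, "trial.csv"))
  expect_equal(tri$adherence, sim$trial$adherence, tolerance = 1e-12)
  bp <- read_bp_log(file.path(dir, "bp.csv"))
  expect_equal(nrow(attr(bp, "quarantined")), 0)
  expect_equal(sort(bp$session_id), sort(unique(sim$bp$session_id)))
})

test_that("validate_study flags out-of-range openings without dropping them", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,timestamp,compartment",
               "P1,2013-01-15T09:00,A",     # before active range
               "P1,2013-02-02T09:05,A"),
             file.path(dir, "events.csv"))
  writeLines(c("patient_id,arm,dose_label,time_of_day,start_date,end_date",
               "P1,MHEALTH,AM,09:00,2013-02-01,2013-03-02"),
             file.path(dir, "regimen.csv"))
  writeLines(c("patient_id,session_id,timestamp,reading_index,sbp,dbp,source",
               protocol_rows("P1", "S1", "2013-02-03",
                             c(130, 126, 124), c(84, 80, 78))),
             file.path(dir, "bp.csv"))
  writeLines(c("patient_id,arm,age_years", "P1,MHEALTH,45"),
             file.path(dir, "roster.csv"))
  v <- validate_study(dir)
  expect_equal(v$n_events, 2)              # flagged, not dropped
  expect_equal(v$n_out_of_range, 1)
  expect_equal(v$n_quarantined_sessions, 0)
  expect_false(v$ok)
})
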