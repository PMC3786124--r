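test_that("score_dose applies the windowed credit with inclusive boundaries", {
  expect_equal(score_dose(45), 1.0)     # in the 3-hour window
  expect_equal(score_dose(150), 0.5)    # outside 3h, inside 6h
  expect_equal(score_dose(NA), 0.0)     # missed dose
  expect_equal(score_dose(c(90, -90)), c(1, 1))   # boundary toward full
  expect_equal(score_dose(c(180, -180)), c(0.5, 0.5))
  expect_equal(score_dose(c(91, 181)), c(0.5, 0))
  # non-increasing step function of |delay|
  d <- seq(0, 400, by = 1)
  s <- score_dose(d)
  expect_true(all(diff(s) <= 0))
  expect_equal(s, score_dose(-d))
  # windows read from config
  cfg <- study_config(full_window_min = 30, half_window_min = 60)
  expect_equal(score_dose(45, cfg), 0.5)
})

test_that("greedy matching follows the first-come, earliest-dose contract", {
  day <- function(x) ts_utc(paste("2013-02-01", x))
  # one in-window candidate: 09:00 matched at +40, 21:00 missed
  de <- match_openings(day(c("09:00", "21:00")), day("09:40"))
  expect_equal(de$delay_min, c(40, NA))
  expect_length(attr(de, "surplus"), 0)

  # first-come rule: second opening of a served compartment is surplus
  de <- match_openings(day("09:00"), day(c("09:10", "09:20")))
  expect_equal(de$delay_min, 10)
  expect_equal(attr(de, "surplus"), day("09:20"))

  # 15:00 is 360 and -360 minutes from the two doses: no admissible
  # match (exhaustive search over all assignments agrees)
  de <- match_openings(day(c("09:00", "21:00")), day("15:00"))
  expect_equal(de$delay_min, c(NA_real_, NA_real_))
  expect_equal(attr(de, "surplus"), day("15:00"))
  expect_equal(oracle_optimal_total(c(540, 1260), 900), 0)

  # order of supplied openings is irrelevant after sorting
  de1 <- match_openings(day(c("09:00", "21:00")),
                        day(c("21:10", "08:30")))
  de2 <- match_openings(day(c("21:00", "09:00")),
                        day(c("08:30", "21:10")))
  expect_identical(de1, de2)
})

test_that("daily and period scores average with equal day weighting", {
  day1 <- tibble::tibble(
    scheduled = ts_utc(c("2013-02-01 09:00", "2013-02-01 21:00")),
    opened = ts_utc(c("2013-02-01 09:30", "2013-02-01 23:30")),
    delay_min = c(30, 150))
  expect_equal(daily_score(day1), 0.75)
  expect_equal(daily_score(day1[0, ]), NA_real_)  # no-score signal

  # three days at 1.0, 0.5, 0.0 -> period mean 0.5
  mk_day <- function(date, delays) tibble::tibble(
    scheduled = ts_utc(paste(date, c("09:00", "21:00"))),
    opened = ts_utc(paste(date, c("09:00", "21:00"))) + delays * 60,
    delay_min = delays)
  events <- dplyr::bind_rows(mk_day("2013-02-01", c(0, 0)),
                             mk_day("2013-02-02", c(120, 120)),
                             mk_day("2013-02-03", c(500, 500)))
  series <- adherence_series(events)
  expect_equal(series$score, c(1, 0.5, 0))
  expect_equal(period_score(series), 0.5)
  expect_equal(period_score(series, c("2013-02-01", "2013-02-02")), 0.75)
  expect_equal(period_score(series, c("2013-03-01", "2013-03-31")), NA_real_)

  # concatenation: day-count-weighted mean of window scores
  w1 <- period_score(series, c("2013-02-01", "2013-02-01"))
  w2 <- period_score(series, c("2013-02-02", "2013-02-03"))
  expect_equal(period_score(series), (1 * w1 + 2 * w2) / 3)
})

test_that("eligibility uses the strict 0.85 cutoff", {
  expect_equal(as.character(classify_eligibility(0.57)),
               "NON_ADHERENT_ELIGIBLE")
  expect_equal(as.character(classify_eligibility(0.90)),
               "ADHERENT_INELIGIBLE")
  # exactly at the cutoff counts as adherent ("<0.85" is strict)
  expect_equal(as.character(classify_eligibility(0.85)),
               "ADHERENT_INELIGIBLE")
  cfg <- study_config(eligibility_cutoff = 0.9)
  expect_equal(as.character(classify_eligibility(0.85, cfg)),
               "NON_ADHERENT_ELIGIBLE")
})

test_that("simulated mixture behaviour recovers the closed-form period score", {
  # E[credit] = p_full + 0.5 p_half = 0.7; per-dose variance
  # E[X^2] - E[X]^2 = (0.6 + 0.2/4) - 0.49 = 0.16 over 300 dose slots
  reg <- tibble::tibble(patient_id = "P1", arm = factor("MHEALTH"),
                        dose_label = c("AM", "PM"),
                        time_of_day = c(540L, 1260L),
                        start_date = as.Date("2013-02-01"),
                        end_date = as.Date("2013-02-01") + 149)
  ev <- simulate_patient_events(reg, behavior_params(0.6, 0.2, 0.2),
                                n_days = 150, seed = 303)
  de <- match_openings(
    ts_utc("2013-02-01 00:00") + rep(0:149, each = 2) * 86400 +
      rep(c(540, 1260), 150) * 60,
    ev$timestamp)
  got <- mean(score_dose(de$delay_min))
  expect_lt(abs(got - 0.7), 3 * sqrt(0.16 / 300))
})

test_that("score_patients scores a multi-patient log end to end", {
  reg <- regimen_csv(c("P1,MHEALTH,AM,09:00,2013-02-01,2013-03-02",
                       "P1,MHEALTH,PM,21:00,2013-02-01,2013-03-02",
                       "P2,SC,AM,09:00,2013-02-01,2013-03-02"))
  # P1 takes every dose on time for 30 days; P2 takes nothing
  rows <- sprintf("P1,2013-%02d-%02dT%s,A",
                  rep(c(2, 3), c(56, 4)),
                  rep(c(1:28, 1:2), each = 2),
                  rep(c("09:05", "21:10"), 30))
  ev <- read_event_log(events_csv(rows))
  out <- score_patients(ev, read_regimen(reg), "2013-02-01", 30)
  expect_equal(out$patient_id, c("P1", "P2"))
  expect_equal(out$n_days, c(30L, 30L))
  expect_equal(out$period_score, c(1, 0))
  expect_equal(as.character(out$eligibility),
               c("ADHERENT_INELIGIBLE", "NON_ADHERENT_ELIGIBLE"))
})
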