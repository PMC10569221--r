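test_that("wear-time day validity is boundary-inclusive at 16 h", {
  expect_true(valid_day(16.0))
  expect_false(valid_day(15.99))
  expect_true(valid_day(24))
  expect_equal(valid_day(c(15, 16, 17, NA)), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(valid_day(25), "\\[0, 24\\]")
})

test_that("participant inclusion requires 4 valid days including a weekend day", {
  mk <- function(types, wear) data.frame(day_type = types, wear_hours = wear)
  # exactly at the criterion: 3 weekdays + 1 weekend
  expect_true(include_participant(mk(c("weekday", "weekday", "weekday", "weekend"),
                                     rep(17, 4))))
  # 5 valid weekdays but no weekend day
  expect_false(include_participant(mk(rep("weekday", 5), rep(20, 5))))
  # weekend day present but only 3 valid days in total
  expect_false(include_participant(mk(c("weekday", "weekday", "weekend"), rep(18, 3))))
  # low-wear days do not count
  expect_false(include_participant(mk(c("weekday", "weekday", "weekday", "weekend"),
                                      c(17, 17, 17, 15))))
  expect_warning(res <- include_participant(mk(character(0), numeric(0))), "no measurement")
  expect_false(res)
  # order of days is irrelevant
  d <- mk(c("weekend", "weekday", "weekday", "weekday", "weekday"),
          c(16, 15, 17, 18, 19))
  for (s in 1:5) {
    expect_true(include_participant(d[sample(nrow(d)), ]))
  }
})

test_that("weekly average weights weekdays 5/7 and weekends 2/7, then closes", {
  mk <- function(type, sleep, sb, lpa, mvpa)
    data.frame(day_type = type, sleep_h = sleep, sb_h = sb, lpa_h = lpa, mvpa_h = mvpa)
  # identical weekday and weekend profile passes through unchanged
  d <- rbind(mk("weekday", 8, 11, 4, 1), mk("weekend", 8, 11, 4, 1))
  expect_equal(unname(weekly_average(d)), c(8, 11, 4, 1), tolerance = 1e-12)
  # forced arithmetic: weekday sleep 10, weekend sleep 3 -> (5*10 + 2*3)/7 = 8
  d <- rbind(mk("weekday", 10, 9, 4, 1), mk("weekend", 3, 16, 4, 1))
  expect_equal(unname(weekly_average(d)), c(8, 11, 4, 1), tolerance = 1e-12)
  # closure applied after weighting: day totals != 24 still close to 24
  d <- rbind(mk("weekday", 9, 10, 3, 1), mk("weekend", 7, 12, 3, 0.5))
  expect_equal(sum(weekly_average(d)), 24, tolerance = 1e-9)
  # missing day type is an aggregation error
  expect_error(weekly_average(mk("weekday", 8, 11, 4, 1)), "weekend")
})

test_that("FMI is fat mass over height squared", {
  expect_equal(derive_fmi(18, 1.5), 8.0)
  expect_equal(derive_fmi(0, 1.6), 0.0)
  expect_equal(derive_fmi(c(12, 16), c(1.42, 1.74)), c(12 / 1.42^2, 16 / 1.74^2))
  expect_error(derive_fmi(10, 0), "height")
  expect_error(derive_fmi(-1, 1.5), "fat_mass")
})

test_that("snacking is high iff any snack is consumed at least daily", {
  expect_equal(classify_snacking(c("2-4 times a week", "once a day (everyday)", "never")),
               "high")
  expect_equal(classify_snacking(c("never", "never", "never")), "low")
  expect_equal(classify_snacking(rep("5-6 times a week", 3)), "low")
  expect_equal(classify_snacking(c("never", "more than once every day", "never")), "high")
  # en-dash and case variants normalize
  expect_equal(classify_snacking(c("2–4 times a week", "Never", "ONCE A WEEK")), "low")
  # a daily answer dominates an NA; otherwise NA propagates
  expect_equal(classify_snacking(c(NA, "once a day (everyday)", "never")), "high")
  expect_true(is.na(classify_snacking(c(NA, "never", "never"))))
  expect_error(classify_snacking(c("sometimes", "never", "never")), "unknown snacking")
  # matrix input classifies per row
  m <- rbind(c("never", "never", "never"),
             c("once a day (everyday)", "never", "never"))
  expect_equal(classify_snacking(m), c("low", "high"))
})

test_that("age groups split at 13/14 completed years and reject out-of-range ages", {
  expect_equal(as.character(age_group(c(8, 13, 13.9, 14, 18))),
               c("children", "children", "children", "adolescents", "adolescents"))
  expect_error(age_group(7), "range")
  expect_error(age_group(19), "range")
})

test_that("read_cohort ingests the fixture, derives analysis fields, and logs filters", {
  fx <- write_mini_cohort()
  cohort <- read_cohort(fx$days, fx$participants)
  p <- cohort$participants
  expect_s3_class(cohort, "cohort")
  expect_equal(nrow(p), 2L)
  expect_equal(as.character(p$age_group), c("children", "adolescents"))
  # constant day profiles: weekly average equals the daily profile
  expect_equal(unname(unlist(p[1, behavior_parts()])), c(9, 10, 4, 1),
               tolerance = 1e-9)
  expect_equal(p$fmi, c(12 / 1.42^2, 16 / 1.74^2), tolerance = 1e-12)
  expect_equal(p$snacking, c("low", "high"))
  expect_match(cohort$filter_log[1], "2 of 2 retained")
})

test_that("read_cohort schema and uniqueness violations are informative errors", {
  fx <- write_mini_cohort()
  # drop a behaviour column
  days <- fx$day_table
  days$lpa_h <- NULL
  bad <- file.path(fx$dir, "days_bad.csv")
  write.csv(days, bad, row.names = FALSE)
  expect_error(read_cohort(bad, fx$participants), "lpa_h")
  # duplicate participant id
  ppl <- rbind(fx$participant_table, fx$participant_table[1, ])
  badp <- file.path(fx$dir, "ppl_bad.csv")
  write.csv(ppl, badp, row.names = FALSE)
  expect_error(read_cohort(fx$days, badp), "duplicate participant_id")
  # non-numeric wear time names the row
  days2 <- fx$day_table
  days2$wear_hours <- as.character(days2$wear_hours)
  days2$wear_hours[3] <- "lots"
  bad2 <- file.path(fx$dir, "days_bad2.csv")
  write.csv(days2, bad2, row.names = FALSE)
  expect_error(read_cohort(bad2, fx$participants), "row 3")
  expect_error(read_cohort(file.path(fx$dir, "nope.csv"), fx$participants),
               "not found")
})

test_that("minutes flag converts day-level durations at ingest", {
  fx <- write_mini_cohort()
  days_min <- fx$day_table
  for (cc in c("wear_hours", "sleep_h", "sb_h", "lpa_h", "mvpa_h"))
    days_min[[cc]] <- days_min[[cc]] * 60
  fmin <- file.path(fx$dir, "days_min.csv")
  write.csv(days_min, fmin, row.names = FALSE)
  a <- read_cohort(fx$days, fx$participants)
  b <- read_cohort(fmin, fx$participants, minutes = TRUE)
  expect_equal(b$participants[, behavior_parts()], a$participants[, behavior_parts()],
               tolerance = 1e-12)
})

test_that("synthetic cohort tables survive a write/read round trip", {
  cfg <- generator_config(n = c(children = 25, adolescents = 25), seed = 11)
  sim <- gen_cohort(cfg, days = TRUE, mcar = FALSE)
  dir <- tempfile("roundtrip_")
  write_cohort_tables(sim$cohort$participants, sim$days, dir)
  back <- read_cohort(file.path(dir, "days.csv"), file.path(dir, "participants.csv"))
  p0 <- sim$cohort$participants
  p1 <- back$participants
  expect_setequal(p1$participant_id, p0$participant_id)
  # participant-level fields are preserved bit-for-bit at CSV precision
  for (cc in c("bmi_z", "fm_pct", "vat_cm2", "maternal_bmi", "fmi")) {
    expect_equal(p1[[cc]], p0[[cc]][match(p1$participant_id, p0$participant_id)],
                 tolerance = 1e-12)
  }
  # compositions re-derived from the jittered day tables sit near the
  # generating weekly profile
  delta <- abs(as.matrix(p1[, behavior_parts()]) -
               as.matrix(p0[match(p1$participant_id, p0$participant_id),
                            behavior_parts()]))
  expect_lt(mean(delta), 0.3)
  expect_lt(max(delta), 2.5)
})

test_that("complete-case restriction drops exactly the records with missing covariates", {
  fx <- write_mini_cohort()
  cohort <- read_cohort(fx$days, fx$participants)
  # no missing values: identity
  same <- complete_case(cohort, c("maternal_bmi", "maternal_edu"))
  expect_equal(nrow(same$participants), 2L)
  # inject a missing maternal BMI
  cohort$participants$maternal_bmi[1] <- NA
  cut <- complete_case(cohort, c("maternal_bmi", "maternal_edu"))
  expect_equal(cut$participants$participant_id, "B2")
  expect_match(tail(cut$filter_log, 1), "1 of 2 retained")
  # all missing: empty cohort with warning
  cohort$participants$maternal_bmi <- NA
  expect_warning(none <- complete_case(cohort, "maternal_bmi"), "every participant")
  expect_equal(nrow(none$participants), 0L)
  expect_error(complete_case(cohort, "not_a_column"), "unknown covariate")
})
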