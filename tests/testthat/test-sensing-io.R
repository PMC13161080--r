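test_that("streams round-trip through CSV, sorted, with validation", {
  dir <- withr::local_tempdir()
  accel <- data.frame(timestamp = DAY0 + c(30, 10, 20),
                      state = c("Walking", "Stationary", "Walking"))
  st <- sensing_streams("s1", accel = accel,
                        wifi = data.frame(timestamp = DAY0 + 1:3,
                                          location_id = c("A", "A", "B")),
                        pam = data.frame(timestamp = DAY0 + 5,
                                         pam_score = 7L))
  # time-shuffled input comes back sorted
  expect_equal(st$accel$timestamp, DAY0 + c(10, 20, 30))
  expect_equal(st$accel$state, c("Stationary", "Walking", "Walking"))
  paths <- write_streams(st, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_streams(paths, student_id = "s1")
  expect_equal(rt$accel, st$accel)
  expect_equal(rt$wifi, st$wifi)
  expect_equal(rt$pam, st$pam)
})

test_that("out-of-vocabulary and malformed records are rejected by row", {
  expect_error(
    sensing_streams("s1", accel = data.frame(timestamp = 1,
                                             state = "Jogging")),
    "Jogging")
  expect_error(
    sensing_streams("s1", sessions = data.frame(login = 10, logout = 5,
                                                traffic_mb = 1)),
    "row 1")
  expect_error(
    sensing_streams("s1", pam = data.frame(timestamp = 1, pam_score = 17)),
    "16-point")
  expect_error(
    sensing_streams("s1", wifi = data.frame(timestamp = 1,
                                            location_id = "")),
    "location_id")
  expect_error(read_streams(list(accel = "/nonexistent/file.csv")),
               "accel")
})

test_that("day segmentation partitions records exhaustively and disjointly", {
  # records at 23:59 and 00:01 straddle the boundary
  st <- sensing_streams("s1", accel = data.frame(
    timestamp = DAY0 + c(hms(23, 59), 86400 + hms(0, 1)),
    state = c("Walking", "Walking")))
  days <- segment_days(st)
  expect_length(days, 2)
  expect_equal(vapply(days, function(d) nrow(d$accel), 0L), c(1L, 1L))

  # a record exactly at the boundary instant belongs to the later day
  st2 <- sensing_streams("s1", accel = data.frame(
    timestamp = DAY0 + c(0, 86400), state = c("Walking", "Walking")))
  days2 <- segment_days(st2)
  expect_length(days2, 2)
  expect_equal(days2[[2]]$accel$timestamp, DAY0 + 86400)

  # 7 days of records give 7 entries; empty streams give none
  st7 <- sensing_streams("s1", accel = data.frame(
    timestamp = DAY0 + (0:6) * 86400 + hms(12), state = rep("Walking", 7)))
  expect_length(segment_days(st7), 7)
  expect_length(segment_days(sensing_streams("s1")), 0)

  # count conservation across a busy multi-stream student
  co <- small_cohort(n_students = 2, n_days = 4)
  st3 <- co$streams[[1]]
  days3 <- segment_days(st3)
  for (s in c("accel", "mic", "wifi", "pam")) {
    expect_equal(sum(vapply(days3, function(d) nrow(d[[s]]), 0L)),
                 nrow(st3[[s]]))
  }
})

test_that("coverage filter measures span unions and is monotone", {
  # continuous accel 08:00-20:00 at 5-min cadence: 12 h, valid
  d1 <- make_day(accel_t = DAY0 + seq(hms(8), hms(20), by = 300),
                 accel_s = "Stationary")
  f1 <- apply_coverage_filter(list(d1))[[1]]
  expect_equal(f1$coverage_hours, 12)
  expect_true(f1$valid)

  # records only 08:00-10:00: 2 h < 6 h, invalid
  d2 <- make_day(accel_t = DAY0 + seq(hms(8), hms(10), by = 300),
                 accel_s = "Stationary")
  f2 <- apply_coverage_filter(list(d2))[[1]]
  expect_equal(f2$coverage_hours, 2)
  expect_false(f2$valid)

  # min_hours = 0: every day valid
  f0 <- apply_coverage_filter(list(d1, d2), min_hours = 0)
  expect_true(all(vapply(f0, `[[`, TRUE, "valid")))

  # a gap beyond the stale threshold breaks the span
  d3 <- make_day(accel_t = DAY0 + c(seq(hms(8), hms(9), 300),
                                    seq(hms(12), hms(13), 300)),
                 accel_s = "Stationary")
  f3 <- apply_coverage_filter(list(d3))[[1]]
  expect_equal(f3$coverage_hours, 2)

  # idempotence and monotonicity in min_hours
  co <- small_cohort(n_students = 3, n_days = 5)
  days <- segment_days(co$streams[[1]])
  once <- apply_coverage_filter(days)
  twice <- apply_coverage_filter(once)
  expect_identical(vapply(once, `[[`, TRUE, "valid"),
                   vapply(twice, `[[`, TRUE, "valid"))
  for (thr in c(0, 2, 6, 10, 20)) {
    lo <- sum(vapply(apply_coverage_filter(days, thr), `[[`, TRUE, "valid"))
    hi <- sum(vapply(apply_coverage_filter(days, thr + 2), `[[`, TRUE,
                     "valid"))
    expect_gte(lo, hi)
  }
})

test_that("imputation median-fills continuous and forward-fills categorical", {
  df <- data.frame(day = 1:3, valid = c(TRUE, FALSE, TRUE),
                   metric = c(5, NA, 9),
                   state = c("A", NA, NA))
  out <- impute_missing(df, continuous = "metric", categorical = "state")
  expect_equal(out$metric, c(5, 7, 9))
  expect_equal(out$state, c("A", "A", "A"))

  # observed values never change; no missing continuous values remain
  expect_equal(out$metric[c(1, 3)], df$metric[c(1, 3)])
  expect_false(anyNA(out$metric))

  # leading categorical gap back-fills from the first observation
  df2 <- data.frame(valid = c(TRUE, TRUE), metric = c(1, 2),
                    state = c(NA, "B"))
  expect_equal(impute_missing(df2, "metric", "state")$state, c("B", "B"))

  # zero valid days: student dropped with a warning
  df3 <- data.frame(valid = c(FALSE, FALSE), metric = c(NA_real_, NA))
  expect_warning(res <- impute_missing(df3, "metric"), "zero valid")
  expect_null(res)
})

test_that("PAM levels map surjectively onto the four quadrants", {
  levels <- pam_to_level(1:16)
  expect_setequal(unique(levels), 1:4)
  expect_true(all(tabulate(levels, 4) >= 1))
  expect_error(pam_to_level(0), "1, 16")
  expect_error(pam_to_level(17), "1, 16")
  # the shipped default keeps quadrant blocks of four scores
  expect_equal(pam_to_level(9:12), rep(1L, 4))
})

test_that("daily label is the last response of the logical day", {
  lk <- pam_level_lookup()
  s9 <- which(lk == 3)[1]; s1 <- which(lk == 1)[1]; s4 <- which(lk == 4)[1]
  pam <- data.frame(timestamp = DAY0 + c(hms(9), hms(20)),
                    pam_score = c(s9, s1))
  expect_equal(daily_label(pam, 19010L), 1L)
  expect_true(is.na(daily_label(pam, 19011L)))
  pam2 <- data.frame(timestamp = DAY0 + hms(12), pam_score = s4)
  expect_equal(daily_label(pam2, 19010L), 4L)
})
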