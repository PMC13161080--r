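test_that("activity events are counted into the right bins", {
  sch <- binning_scheme()  # 06:00-22:00, 30 min, 32 bins
  expect_equal(sch$n_bins, 32)
  expect_equal(binning_scheme(0, 24, 30)$n_bins, 48)

  d <- make_day(accel_t = DAY0 + c(hms(8, 5), hms(8, 10), hms(9, 5),
                                   hms(21, 0)),
                accel_s = rep("Walking", 4))
  counts <- bin_events(d, sch)
  expect_equal(sum(counts), 4)
  expect_equal(counts[5], 2)   # 08:00-08:30
  expect_equal(counts[7], 1)   # 09:00-09:30
  expect_equal(counts[31], 1)  # 21:00-21:30

  # Wi-Fi trace A,A,B,B has exactly one transition
  d2 <- make_day(wifi_t = DAY0 + hms(10) + (0:3) * 60,
                 wifi_l = c("A", "A", "B", "B"))
  expect_equal(sum(bin_events(d2, sch)), 1)

  # all stationary, single location: zero vector
  d3 <- make_day(accel_t = DAY0 + hms(10) + (0:5) * 60,
                 accel_s = "Stationary",
                 wifi_t = DAY0 + hms(11), wifi_l = "A")
  expect_equal(bin_events(d3, sch), rep(0L, 32))

  # events outside the window are discarded
  d4 <- make_day(accel_t = DAY0 + c(hms(5, 59), hms(22, 0)),
                 accel_s = rep("Running", 2))
  expect_equal(sum(bin_events(d4, sch)), 0)
})

test_that("regularity entropy matches closed forms and scales with sparsity", {
  sch <- binning_scheme(6, 8, 30)  # 4 bins
  one_bin_day <- function() {
    make_day(accel_t = DAY0 + hms(6, 10) + (0:9) * 30,
             accel_s = "Walking")
  }
  # fully concentrated distribution: r_f = 0
  r <- regularity_entropy(list(one_bin_day(), one_bin_day()), sch,
                          t_span = 2)
  expect_equal(r$r_f, 0)
  expect_equal(r$entropy_raw, 0)

  # uniform over 4 bins with D = t_span: r_f = ln 4
  unif_day <- make_day(accel_t = DAY0 + hms(6) + c(0, 30, 60, 90) * 60 + 10,
                       accel_s = "Walking")
  ru <- regularity_entropy(list(unif_day), sch, t_span = 1)
  expect_equal(ru$entropy_raw, log(4), tolerance = 1e-12)
  expect_equal(ru$r_f, log(4), tolerance = 1e-12)

  # same distribution but half the days valid: the score doubles
  rs <- regularity_entropy(list(unif_day), sch, t_span = 2)
  expect_equal(rs$r_f, 2 * log(4), tolerance = 1e-12)

  # degenerate: no events at all
  empty <- make_day(accel_t = DAY0 + hms(7), accel_s = "Stationary")
  expect_warning(r0 <- regularity_entropy(list(empty), sch, t_span = 1),
                 "no activity")
  expect_equal(r0$r_f, 0)
})

test_that("entropy bounds, permutation invariance and bin-merge property", {
  set.seed(21)
  ent <- tsnaffect:::entropy_nats
  for (i in 1:50) {
    n <- sample(3:12, 1)
    p <- stats::runif(n); p <- p / sum(p)
    h <- ent(p)
    expect_gte(h, 0)
    expect_lte(h, log(n) + 1e-12)
    expect_equal(ent(sample(p)), h, tolerance = 1e-12)
    # merging two bins never increases entropy
    q <- c(p[1] + p[2], p[-(1:2)])
    expect_lte(ent(q), h + 1e-12)
  }
})

test_that("morning onset is the earliest sustained-activity or departure", {
  # walking run 07:30-07:40 and Wi-Fi departure 08:15: onset 07:30
  d <- make_day(
    accel_t = DAY0 + seq(hms(7, 30), hms(7, 40), by = 30),
    accel_s = "Walking",
    wifi_t = DAY0 + c(hms(2), hms(3), hms(8, 15)),
    wifi_l = c("home", "home", "lab"))
  expect_equal(morning_onset(d, night_cluster = "home"), hms(7, 30))

  # only the Wi-Fi criterion fires
  d2 <- make_day(wifi_t = DAY0 + c(hms(2), hms(9)),
                 wifi_l = c("home", "lib"))
  expect_equal(morning_onset(d2, night_cluster = "home"), hms(9))

  # a 3-minute run does not satisfy the 5-minute sustain rule
  d3 <- make_day(accel_t = DAY0 + seq(hms(7), hms(7, 3), by = 30),
                 accel_s = "Walking")
  expect_true(is.na(morning_onset(d3)))

  # an interruption longer than the gap limit restarts the run
  d4 <- make_day(accel_t = DAY0 + c(seq(hms(7), hms(7, 4), 30),
                                    seq(hms(7, 10), hms(7, 16), 30)),
                 accel_s = "Walking")
  expect_equal(morning_onset(d4), hms(7, 10))
})

test_that("mean onset averages valid days only", {
  r <- mean_onset(c(25200, 28800))
  expect_equal(r$r_wh, 27000)
  expect_equal(r$t_days, 2)
  expect_equal(mean_onset(c(NA, 30000, NA))$r_wh, 30000)
  expect_true(is.na(mean_onset(c(NA_real_, NA))$r_wh))
})

test_that("night cluster is the modal nighttime location", {
  w <- data.frame(timestamp = DAY0 + c(rep(hms(2), 10), rep(hms(3), 2)),
                  location_id = c(rep("A", 10), rep("B", 2)))
  expect_equal(infer_night_cluster(w), "A")
  # tie broken lexicographically
  w2 <- data.frame(timestamp = DAY0 + hms(1) + 1:10,
                   location_id = rep(c("B", "A"), 5))
  expect_equal(infer_night_cluster(w2), "A")
  w3 <- data.frame(timestamp = DAY0 + hms(12), location_id = "A")
  expect_message(res <- infer_night_cluster(w3), "undefined")
  expect_true(is.na(res))
})

test_that("logical day shift maps 01:00 to 25:00 and is idempotent", {
  expect_equal(shift_logical_day(DAY0 + hms(1)), hms(25))
  expect_equal(shift_logical_day(DAY0 + hms(1)), 90000)
  expect_equal(shift_logical_day(DAY0 + hms(23, 30)), hms(23, 30))
  expect_equal(shift_logical_day(DAY0 + hms(5)), hms(5))  # boundary: unshifted
  # order preservation within one logical day (20:00 ... 04:59)
  ts <- DAY0 + c(hms(20), hms(23, 59), 86400 + hms(0, 1), 86400 + hms(4, 59))
  expect_false(is.unsorted(shift_logical_day(ts)))
})

test_that("usage duration divides by observed days, split by day type", {
  # day 19002 is a Monday
  mon <- 19002L
  s <- data.frame(login = mon * 86400 + c(hms(10), hms(14)),
                  logout = mon * 86400 + c(hms(10, 30), hms(15)),
                  traffic_mb = c(1, 2))
  expect_equal(usage_duration(s, mon, "weekday"), 5400)  # 90 min over 1 day
  expect_equal(usage_duration(s, mon + 0:4, "weekday"), 5400 / 5)
  expect_true(is.na(usage_duration(s, mon, "weekend")))
  # weekend split excludes weekday sessions
  expect_equal(usage_duration(s, mon + 5L, "weekend"), 0)
  none <- s[0, ]
  expect_equal(usage_duration(none, mon + 0:4, "all"), 0)
  # numerator additivity under disjoint day unions
  s2 <- data.frame(login = (mon + 1) * 86400 + hms(9),
                   logout = (mon + 1) * 86400 + hms(10), traffic_mb = 0)
  lhs <- usage_duration(rbind(s, s2), mon + 0:1, "all") * 2
  rhs <- usage_duration(s, mon, "all") + usage_duration(s2, mon + 1L, "all")
  expect_equal(lhs, rhs)
})

test_that("late-night metric averages shifted final logouts per day", {
  d1 <- 19010 * 86400; d2 <- 19011 * 86400
  s <- data.frame(login = c(d1 + hms(21), d2 + hms(22)),
                  logout = c(d1 + hms(23), d2 + 86400 + hms(1)),
                  traffic_mb = 0)
  # logouts 23:00 and 25:00 on two logical days: mean 24:00
  expect_equal(late_night(s), 86400)
  s2 <- data.frame(login = d1 + hms(20), logout = d1 + hms(22),
                   traffic_mb = 0)
  expect_equal(late_night(s2), hms(22))
  # a 04:59 logout counts toward the previous day
  s3 <- data.frame(login = d1 + hms(23), logout = d2 + hms(4, 59),
                   traffic_mb = 0)
  expect_equal(late_night(s3), hms(4, 59) + 86400)
})

test_that("data intensity is daily mean traffic", {
  s <- data.frame(login = DAY0 + c(1, 2), logout = DAY0 + c(10, 20),
                  traffic_mb = c(100, 300))
  expect_equal(data_intensity(s, 2), 200)
  expect_equal(data_intensity(s[0, ], 5), 0)
  one <- data.frame(login = DAY0, logout = DAY0 + 60, traffic_mb = 50)
  expect_equal(data_intensity(one, 5), 10)
  expect_true(is.na(data_intensity(s, 0)))
  # invariant to session ordering
  expect_equal(data_intensity(s[2:1, ], 2), 200)
})
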