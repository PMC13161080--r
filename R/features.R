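#' Temporal binning scheme for activity events
#'
#' The daily timeline is discretized into fixed-width bins within a
#' wall-clock window. The default follows the 06:00--22:00 window with
#' 30-minute bins, giving 32 bins; `binning_scheme(0, 24, 30)` gives the
#' 48-bin full-day variant.
#'
#' @param window_start,window_end window in hours of local time,
#'   half-open `[window_start, window_end)`.
#' @param bin_minutes bin width in minutes.
#' @return An object of class `"binning_scheme"` with derived `n_bins`.
#' @export
binning_scheme <- function(window_start = 6, window_end = 22,
                           bin_minutes = 30) {
  stopifnot(window_end > window_start, bin_minutes > 0)
  n_bins <- ceiling((window_end - window_start) * 60 / bin_minutes)
  if (n_bins < 2) stop("binning scheme must have at least 2 bins")
  structure(list(window_start = window_start, window_end = window_end,
                 bin_minutes = bin_minutes, n_bins = n_bins),
            class = "binning_scheme")
}

# Map local seconds-of-day to a bin index (1-based), NA outside the window.
bin_of <- function(sod, scheme) {
  m <- sod / 60 - scheme$window_start * 60
  b <- floor(m / scheme$bin_minutes) + 1L
  b[m < 0 | sod >= scheme$window_end * 3600] <- NA_integer_
  b
}

# Activity-event times of one day: one event per non-stationary
# accelerometer record (Walking/Running) and one per Wi-Fi location
# transition (consecutive records with differing location_id; the event is
# stamped at the later record). With debounce = TRUE a run of consecutive
# non-stationary records collapses into one event at the run start.
event_times <- function(day, debounce = FALSE) {
  acc <- day$accel
  ns <- acc$state %in% c("Walking", "Running")
  if (debounce && any(ns)) {
    r <- rle(ns)
    starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    t_acc <- acc$timestamp[starts[r$values]]
  } else {
    t_acc <- acc$timestamp[ns]
  }
  w <- day$wifi
  t_wifi <- numeric(0)
  if (nrow(w) >= 2) {
    tr <- w$location_id[-1] != w$location_id[-nrow(w)]
    t_wifi <- w$timestamp[-1][tr]
  }
  c(t_acc, t_wifi)
}

#' Count activity events per time bin for one day
#'
#' Events are non-stationary accelerometer states (walking/running) plus
#' Wi-Fi location transitions; events outside the scheme's window are
#' discarded.
#'
#' @param day a `"student_day"` object from [segment_days()].
#' @param scheme a [binning_scheme()].
#' @param debounce collapse runs of consecutive non-stationary records into
#'   a single event (off by default).
#' @return Integer vector of length `scheme$n_bins`.
#' @export
bin_events <- function(day, scheme = binning_scheme(), debounce = FALSE) {
  ts <- event_times(day, debounce)
  b <- bin_of(seconds_of_day(ts, day$tz_offset), scheme)
  tabulate(b[!is.na(b)], nbins = scheme$n_bins)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Routine-regularity score from sensor-state entropy
#'
#' Pools activity-event counts over a student's valid days into a single
#' within-day temporal distribution `p` over the bins, and computes
#' `r_f = (t_span / D) * (-sum p_i log p_i)` in nats, where `D` is the
#' number of valid sensing days and `t_span` the total observation span in
#' days. Concentrated routines give low entropy; the span/valid-days factor
#' inflates the score for students with sparse participation.
#'
#' @param days list of `"student_day"` objects; only days with `valid =
#'   TRUE` contribute (pass a pre-filtered list to override).
#' @param scheme a [binning_scheme()].
#' @param t_span total observation span in days; defaults to the number of
#'   days supplied (valid or not).
#' @param debounce see [bin_events()].
#' @return An object of class `"regularity_result"`: `r_f`, `entropy_raw`
#'   (nats), `d_valid`, `t_span`, and the bin probability vector `p`.
#' @export
regularity_entropy <- function(days, scheme = binning_scheme(),
                               t_span = length(days), debounce = FALSE) {
  valid <- vapply(days, function(d) isTRUE(d$valid) || is.na(d$valid), TRUE)
  vdays <- days[valid]
  d_valid <- length(vdays)
  if (d_valid == 0) stop("no valid days")
  counts <- Reduce(`+`, lapply(vdays, bin_events, scheme = scheme,
                               debounce = debounce))
  tot <- sum(counts)
  if (tot == 0) {
    warning("no activity events; regularity score degenerate at 0")
    p <- rep(0, scheme$n_bins)
    h <- 0
  } else {
    p <- counts / tot
    h <- entropy_nats(p)
  }
  structure(list(r_f = (t_span / d_valid) * h, entropy_raw = h,
                 d_valid = d_valid, t_span = t_span, p = p),
            class = "regularity_result")
}

#' @export
print.regularity_result <- function(x, ...) {
  cat(sprintf("r_f = %.4f nats (entropy %.4f, D = %d valid days, span %d)\n",
              x$r_f, x$entropy_raw, x$d_valid, x$t_span))
  invisible(x)
}

#' Morning activity onset of one day
#'
#' The onset is the earliest of (i) the start of the first maximal run of
#' non-stationary accelerometer activity sustained for at least
#' `min_sustained` minutes (interruptions no longer than `max_gap` seconds
#' do not break the run), and (ii) the first Wi-Fi record away from the
#' student's nighttime residence cluster after at least one record at the
#' cluster. Missing if neither criterion fires.
#'
#' @param day a `"student_day"` object.
#' @param min_sustained minimum sustained activity in minutes (default 5).
#' @param max_gap maximum interruption between non-stationary records, in
#'   seconds (default 60).
#' @param night_cluster residence-cluster location id from
#'   [infer_night_cluster()]; `NA` disables criterion (ii).
#' @return Onset as local seconds-of-day, or `NA`.
#' @export
morning_onset <- function(day, min_sustained = 5, max_gap = 60,
                          night_cluster = NA) {
  cand <- numeric(0)
  acc <- day$accel
  ns_t <- acc$timestamp[acc$state %in% c("Walking", "Running")]
  if (length(ns_t)) {
    run_start <- ns_t[1]
    last <- ns_t[1]
    found <- NA_real_
    for (t in ns_t) {
      if (t - last > max_gap) {
        run_start <- t
      }
      last <- t
      if (last - run_start >= min_sustained * 60) {
        found <- run_start
        break
      }
    }
    if (!is.na(found)) cand <- c(cand, found)
  }
  w <- day$wifi
  if (!is.na(night_cluster) && nrow(w) >= 2) {
    at_home <- w$location_id == night_cluster
    first_home <- match(TRUE, at_home)
    if (!is.na(first_home)) {
      away <- which(!at_home & seq_len(nrow(w)) > first_home)
      if (length(away)) cand <- c(cand, w$timestamp[away[1]])
    }
  }
  if (!length(cand)) return(NA_real_)
  seconds_of_day(min(cand), day$tz_offset)
}

#' Average morning onset across days
#'
#' `r_wh = (1/T) * sum(t_j)` over the `T` days with a valid onset; a lower
#' value means an earlier habitual start of the day.
#'
#' @param onsets numeric vector of per-day onsets (seconds-of-day), `NA`
#'   for days without valid morning records.
#' @return An object of class `"onset_result"`: `r_wh`, `t_days`, `onsets`.
#'   `r_wh` is `NA` when no day has a valid onset.
#' @export
mean_onset <- function(onsets) {
  ok <- !is.na(onsets)
  structure(list(r_wh = if (any(ok)) mean(onsets[ok]) else NA_real_,
                 t_days = sum(ok), onsets = onsets),
            class = "onset_result")
}

#' Infer a student's nighttime residence cluster
#'
#' The modal Wi-Fi location over records falling in the nighttime window
#' (00:00--05:00 local, configurable); ties break lexicographically.
#'
#' @param wifi data frame with `timestamp`, `location_id`.
#' @param tz_offset local-time offset in seconds.
#' @param night_window two hours-of-day delimiting the window.
#' @return Location id, or `NA` (with a message) if the student has no
#'   nighttime records; criterion (ii) of [morning_onset()] is then
#'   disabled.
#' @export
infer_night_cluster <- function(wifi, tz_offset = 0, night_window = c(0, 5)) {
  sod <- seconds_of_day(wifi$timestamp, tz_offset)
  sel <- sod >= night_window[1] * 3600 & sod < night_window[2] * 3600
  if (!any(sel)) {
    message("no nighttime Wi-Fi records; residence cluster undefined")
    return(NA_character_)
  }
  tab <- table(wifi$location_id[sel])
  names(tab)[order(-tab, names(tab))][1]
}

#' Shift post-midnight times onto the previous logical day
#'
#' Late-night activity between 00:00 and 05:00 is treated as an extension of
#' the previous day, so 01:00 becomes 25:00 (90000 s). Times at or after
#' 05:00 are returned unshifted (half-open boundary). Idempotent on already
#' shifted values.
#'
#' @param ts epoch seconds (vectorized).
#' @param tz_offset local-time offset in seconds.
#' @return Adjusted seconds-of-day (may exceed 86400).
#' @export
shift_logical_day <- function(ts, tz_offset = 0) {
  sod <- seconds_of_day(ts, tz_offset)
  ifelse(sod < 5 * 3600, sod + 86400, sod)
}

# Logical day index owning a timestamp under the 05:00 shift convention.
shifted_day_index <- function(ts, tz_offset = 0) {
  d <- day_index(ts, tz_offset)
  ifelse(seconds_of_day(ts, tz_offset) < 5 * 3600, d - 1, d)
}

#' Mean daily online time
#'
#' `r_dt = (1/T_d) * sum(duration_i)` where the sum runs over internet
#' sessions on days of the requested type and `T_d` is the number of
#' observed days of that type -- the denominator is days, not sessions, so
#' the metric is mean daily online seconds. Weekdays (academic focus) and
#' weekends (leisure) are computed separately.
#'
#' @param sessions data frame with `login`, `logout`, `traffic_mb`.
#' @param observed_days integer vector of observed day indices (the
#'   student's observation span).
#' @param day_type `"all"`, `"weekday"` or `"weekend"`.
#' @param tz_offset local-time offset in seconds.
#' @return Mean daily online time in seconds, `NA` if no observed day of
#'   the type.
#' @export
usage_duration <- function(sessions, observed_days,
                           day_type = c("all", "weekday", "weekend"),
                           tz_offset = 0) {
  day_type <- match.arg(day_type)
  keep_day <- switch(day_type,
    all = rep(TRUE, length(observed_days)),
    weekday = !is_weekend_day(observed_days),
    weekend = is_weekend_day(observed_days))
  t_d <- sum(keep_day)
  if (t_d == 0) return(NA_real_)
  if (nrow(sessions) == 0) return(0)
  sday <- shifted_day_index(sessions$login, tz_offset)
  keep_s <- switch(day_type,
    all = rep(TRUE, nrow(sessions)),
    weekday = !is_weekend_day(sday),
    weekend = is_weekend_day(sday))
  sum(sessions$logout[keep_s] - sessions$login[keep_s]) / t_d
}

#' Mean adjusted last-logout time (late-night activity)
#'
#' For each active day, the final logout's shifted seconds-of-day (see
#' [shift_logical_day()]); `r_nt` is the mean over the `M` active days. A
#' logout at 01:00 counts as 25:00 on the previous day, so habitual night
#' owls score above 86400.
#'
#' @inheritParams usage_duration
#' @return Mean adjusted logout in seconds-of-day, `NA` with no sessions.
#' @export
late_night <- function(sessions, tz_offset = 0) {
  if (nrow(sessions) == 0) return(NA_real_)
  d <- shifted_day_index(sessions$logout, tz_offset)
  adj <- shift_logical_day(sessions$logout, tz_offset)
  last <- tapply(adj, d, max)
  mean(last)
}

#' Mean daily data traffic
#'
#' `r_fr = (1/d) * sum(F_k)` over all sessions, in MB per day.
#'
#' @inheritParams usage_duration
#' @param d_days number of days in the observation span.
#' @return MB per day; `NA` if `d_days` is 0.
#' @export
data_intensity <- function(sessions, d_days) {
  if (d_days < 1) return(NA_real_)
  sum(sessions$traffic_mb) / d_days
}
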