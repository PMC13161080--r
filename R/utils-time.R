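#' @keywords internal
"_PACKAGE"

# All timestamps are integer epoch seconds (UTC). Wall-clock logic uses a
# single fixed offset (seconds east of UTC); no tz database is consulted.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Local seconds-of-day for an epoch timestamp
#' @param ts numeric vector of epoch seconds.
#' @param tz_offset fixed local-time offset in seconds east of UTC.
#' @return numeric vector in [0, 86400).
#' @keywords internal
seconds_of_day <- function(ts, tz_offset = 0) {
  (ts + tz_offset) %% 86400
}

# Integer day index (days since epoch of the local day containing ts).
day_index <- function(ts, tz_offset = 0, day_start_hour = 0) {
  floor((ts + tz_offset - day_start_hour * 3600) / 86400)
}

# Day-of-week for a day index; 1970-01-01 (index 0) was a Thursday.
# Returns 0 = Sunday .. 6 = Saturday.
day_of_week <- function(day) (day + 4L) %% 7L

is_weekend_day <- function(day) day_of_week(day) %in% c(0L, 6L)

# Union length (hours) of spans between consecutive timestamps closer than
# `stale_sec`, pooled over several streams, capped at 24 h.
union_coverage_hours <- function(ts_list, stale_sec = 600) {
  iv <- matrix(numeric(0), ncol = 2)
  for (ts in ts_list) {
    ts <- sort(unique(as.numeric(ts)))
    if (length(ts) >= 2) {
      d <- diff(ts)
      keep <- d <= stale_sec
      if (any(keep)) {
        iv <- rbind(iv, cbind(ts[-length(ts)][keep], ts[-1][keep]))
      }
    }
  }
  if (nrow(iv) == 0) return(0)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0
  cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= cur_e) {
        cur_e <- max(cur_e, iv[i, 2])
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- iv[i, 1]; cur_e <- iv[i, 2]
      }
    }
  }
  total <- total + (cur_e - cur_s)
  min(total / 3600, 24)
}
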