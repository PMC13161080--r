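#' Closed state vocabularies for the activity and acoustic classifiers
#'
#' Accelerometer records carry one of four inferred activity states and
#' microphone records one of four inferred acoustic states. Any other value
#' in an input file is rejected at read time.
#' @format Character vectors.
#' @name state-vocabularies
NULL

#' @rdname state-vocabularies
#' @export
ACCEL_STATES <- c("Stationary", "Walking", "Running", "Unknown")

#' @rdname state-vocabularies
#' @export
MIC_STATES <- c("Quiet", "Speaking", "Noisy", "Unknown")

stream_names <- c("accel", "mic", "wifi", "sessions", "pam")

empty_stream <- function(stream) {
  switch(stream,
    accel = data.frame(timestamp = numeric(0), state = character(0),
                       stringsAsFactors = FALSE),
    mic = data.frame(timestamp = numeric(0), state = character(0),
                     stringsAsFactors = FALSE),
    wifi = data.frame(timestamp = numeric(0), location_id = character(0),
                      stringsAsFactors = FALSE),
    sessions = data.frame(login = numeric(0), logout = numeric(0),
                          traffic_mb = numeric(0), stringsAsFactors = FALSE),
    pam = data.frame(timestamp = numeric(0), pam_score = integer(0),
                     stringsAsFactors = FALSE))
}

validate_stream <- function(df, stream, where = stream) {
  bad_row <- function(i, msg) {
    stop(sprintf("%s: row %d: %s", where, i, msg), call. = FALSE)
  }
  check_num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    i <- which(!is.finite(x))
    if (length(i)) bad_row(i[1], sprintf("non-numeric %s '%s'", col, df[[col]][i[1]]))
    x
  }
  if (stream %in% c("accel", "mic")) {
    vocab <- if (stream == "accel") ACCEL_STATES else MIC_STATES
    df$timestamp <- check_num("timestamp")
    df$state <- as.character(df$state)
    i <- which(!df$state %in% vocab)
    if (length(i)) {
      bad_row(i[1], sprintf("state '%s' not in {%s}", df$state[i[1]],
                            paste(vocab, collapse = ", ")))
    }
    df <- df[order(df$timestamp), c("timestamp", "state"), drop = FALSE]
  } else if (stream == "wifi") {
    df$timestamp <- check_num("timestamp")
    df$location_id <- as.character(df$location_id)
    i <- which(is.na(df$location_id) | df$location_id == "")
    if (length(i)) bad_row(i[1], "empty location_id")
    df <- df[order(df$timestamp), c("timestamp", "location_id"), drop = FALSE]
  } else if (stream == "sessions") {
    df$login <- check_num("login")
    df$logout <- check_num("logout")
    df$traffic_mb <- check_num("traffic_mb")
    i <- which(df$logout <= df$login)
    if (length(i)) bad_row(i[1], "logout not after login")
    i <- which(df$traffic_mb < 0)
    if (length(i)) bad_row(i[1], "negative traffic_mb")
    df <- df[order(df$login), c("login", "logout", "traffic_mb"), drop = FALSE]
  } else if (stream == "pam") {
    df$timestamp <- check_num("timestamp")
    df$pam_score <- check_num("pam_score")
    i <- which(df$pam_score != round(df$pam_score) |
                 df$pam_score < 1 | df$pam_score > 16)
    if (length(i)) bad_row(i[1], sprintf("pam_score %s outside the 16-point scale",
                                         df$pam_score[i[1]]))
    df$pam_score <- as.integer(df$pam_score)
    df <- df[order(df$timestamp), c("timestamp", "pam_score"), drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Bundle one student's raw sensing streams
#'
#' Constructs the canonical per-student container holding the five raw
#' streams: accelerometer activity states, microphone acoustic states, Wi-Fi
#' location scans, internet sessions and PAM self-reports. Streams are
#' validated (closed vocabularies, `logout > login`, PAM scores on the
#' 16-point scale) and sorted by time.
#'
#' @param student_id character scalar.
#' @param accel data frame with columns `timestamp`, `state`
#'   (one of `ACCEL_STATES`).
#' @param mic data frame with columns `timestamp`, `state`
#'   (one of `MIC_STATES`).
#' @param wifi data frame with columns `timestamp`, `location_id`.
#' @param sessions data frame with columns `login`, `logout`, `traffic_mb`.
#' @param pam data frame with columns `timestamp`, `pam_score` (1--16).
#' @return An object of class `"sensing_streams"`.
#' @export
sensing_streams <- function(student_id,
                            accel = NULL, mic = NULL, wifi = NULL,
                            sessions = NULL, pam = NULL) {
  stopifnot(is.character(student_id), length(student_id) == 1)
  out <- list(student_id = student_id)
  raw <- list(accel = accel, mic = mic, wifi = wifi,
              sessions = sessions, pam = pam)
  for (s in stream_names) {
    df <- raw[[s]] %||% empty_stream(s)
    out[[s]] <- validate_stream(as.data.frame(df), s,
                                where = paste0(student_id, "/", s))
  }
  structure(out, class = "sensing_streams")
}

#' @export
print.sensing_streams <- function(x, ...) {
  cat("<sensing_streams> student", x$student_id, "\n")
  for (s in stream_names) cat(sprintf("  %-8s %6d records\n", s, nrow(x[[s]])))
  invisible(x)
}

#' Read one student's sensing streams from delimited text files
#'
#' Each stream is a CSV (UTF-8, header row). Column names default to the
#' canonical ones but can be remapped per stream via `columns`. Records are
#' returned sorted by timestamp; out-of-vocabulary activity/acoustic states,
#' malformed numeric fields, non-positive session durations and PAM scores
#' outside 1--16 raise errors naming the stream and row.
#'
#' @param paths named list or character vector with elements `accel`, `mic`,
#'   `wifi`, `sessions`, `pam` giving file locations; a missing or `NA`
#'   element yields an empty stream.
#' @param student_id student identifier for the returned container.
#' @param columns optional named list; `columns$wifi`, say, is a character
#'   vector mapping canonical names to file column names, e.g.
#'   `c(timestamp = "time", location_id = "bssid")`.
#' @param sep field separator, default comma.
#' @return A [sensing_streams()] object.
#' @export
read_streams <- function(paths, student_id = "student", columns = list(),
                         sep = ",") {
  paths <- as.list(paths)
  streams <- list()
  for (s in stream_names) {
    p <- paths[[s]]
    if (is.null(p) || is.na(p)) {
      streams[[s]] <- empty_stream(s)
      next
    }
    if (!file.exists(p)) {
      stop(sprintf("stream '%s': file not found: %s", s, p), call. = FALSE)
    }
    df <- utils::read.csv(p, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character")
    map <- columns[[s]]
    if (!is.null(map)) {
      for (canon in names(map)) {
        if (!map[[canon]] %in% names(df)) {
          stop(sprintf("stream '%s': column '%s' not found in %s",
                       s, map[[canon]], p), call. = FALSE)
        }
        names(df)[names(df) == map[[canon]]] <- canon
      }
    }
    need <- names(empty_stream(s))
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(sprintf("stream '%s': missing column(s) %s in %s",
                   s, paste(miss, collapse = ", "), p), call. = FALSE)
    }
    streams[[s]] <- df[, need, drop = FALSE]
  }
  sensing_streams(student_id,
                  accel = streams$accel, mic = streams$mic,
                  wifi = streams$wifi, sessions = streams$sessions,
                  pam = streams$pam)
}

#' Write one student's streams as CSV files
#'
#' Emits the exact layout [read_streams()] accepts (round-trip property):
#' `<student>_<stream>.csv` for the five streams.
#'
#' @param streams a [sensing_streams()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_streams <- function(streams, dir) {
  stopifnot(inherits(streams, "sensing_streams"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in stream_names) {
    p <- file.path(dir, paste0(streams$student_id, "_", s, ".csv"))
    utils::write.csv(streams[[s]], p, row.names = FALSE, quote = FALSE)
    paths[s] <- p
  }
  invisible(paths)
}

#' Partition a student's streams into logical days
#'
#' Every record is assigned to exactly one logical day (half-open convention:
#' a record at the boundary instant belongs to the later day). Sessions are
#' assigned by login time. The returned sequence covers every day from the
#' first to the last observed day, including days with no records, so that
#' the observation span is explicit.
#'
#' @param streams a [sensing_streams()] object.
#' @param day_start_hour hour of day at which a logical day begins (default 0).
#' @param tz_offset fixed local-time offset in seconds east of UTC.
#' @return A list of `"student_day"` objects, each holding `student_id`,
#'   `day` (integer day index), per-stream slices, and placeholder
#'   `valid`/`coverage_hours` fields set by [apply_coverage_filter()].
#'   Empty streams give an empty list.
#' @export
segment_days <- function(streams, day_start_hour = 0, tz_offset = 0) {
  stopifnot(inherits(streams, "sensing_streams"))
  all_ts <- c(streams$accel$timestamp, streams$mic$timestamp,
              streams$wifi$timestamp, streams$sessions$login,
              streams$pam$timestamp)
  if (length(all_ts) == 0) return(list())
  di <- function(ts) day_index(ts, tz_offset, day_start_hour)
  days <- seq(di(min(all_ts)), di(max(all_ts)))
  slice <- function(df, ts) df[di(ts) == d, , drop = FALSE]
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    out[[i]] <- structure(list(
      student_id = streams$student_id,
      day = d,
      day_start_hour = day_start_hour,
      tz_offset = tz_offset,
      accel = slice(streams$accel, streams$accel$timestamp),
      mic = slice(streams$mic, streams$mic$timestamp),
      wifi = slice(streams$wifi, streams$wifi$timestamp),
      sessions = slice(streams$sessions, streams$sessions$login),
      pam = slice(streams$pam, streams$pam$timestamp),
      valid = NA,
      coverage_hours = NA_real_
    ), class = "student_day")
  }
  out
}

#' Flag days with insufficient sensing coverage
#'
#' Coverage for a day is the union length of time spanned by its
#' accelerometer and Wi-Fi records, where a gap longer than `stale_minutes`
#' between consecutive same-stream records breaks the span (capped at 24 h).
#' Days below `min_hours` are flagged invalid; they are excluded from
#' feature aggregation downstream but retained here as imputation context.
#'
#' @param days list of `"student_day"` objects from [segment_days()].
#' @param min_hours minimum combined coverage in hours (default 6).
#' @param stale_minutes staleness threshold breaking a coverage span
#'   (default 10).
#' @return The same list with `valid` and `coverage_hours` filled in.
#' @export
apply_coverage_filter <- function(days, min_hours = 6, stale_minutes = 10) {
  stale_sec <- stale_minutes * 60
  for (i in seq_along(days)) {
    cov <- union_coverage_hours(
      list(days[[i]]$accel$timestamp, days[[i]]$wifi$timestamp), stale_sec)
    days[[i]]$coverage_hours <- cov
    days[[i]]$valid <- cov >= min_hours
  }
  days
}

#' Impute missing per-day metrics within one student's daily table
#'
#' Continuous metrics take the per-student median over valid days
#' (median-fill); categorical columns carry the last observed value forward,
#' with leading gaps back-filled from the first observation. Observed values
#' are never changed. A student with zero valid days cannot be imputed and
#' yields `NULL` with a warning (the caller drops the student).
#'
#' @param daily data frame for one student with a logical `valid` column,
#'   ordered by day.
#' @param continuous character vector of continuous metric columns.
#' @param categorical character vector of categorical columns.
#' @return The imputed data frame, or `NULL` if the student has no valid day.
#' @export
impute_missing <- function(daily, continuous = character(0),
                           categorical = character(0)) {
  stopifnot(is.data.frame(daily), "valid" %in% names(daily))
  if (!any(daily$valid, na.rm = TRUE)) {
    warning("student has zero valid days; excluded from the cohort")
    return(NULL)
  }
  for (col in continuous) {
    x <- daily[[col]]
    med <- stats::median(x[daily$valid & !is.na(x)])
    if (is.na(med)) med <- stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- med
    daily[[col]] <- x
  }
  for (col in categorical) {
    x <- daily[[col]]
    obs <- which(!is.na(x))
    if (length(obs)) {
      # forward fill, then back-fill the leading run
      idx <- cummax(ifelse(!is.na(x), seq_along(x), 0L))
      x <- ifelse(idx > 0L, x[pmax(idx, 1L)], x[obs[1]])
      daily[[col]] <- x
    }
  }
  daily
}

#' Default lookup from PAM score to affect level
#'
#' The Photographic Affect Meter maps momentary mood to a 16-point scale on
#' the valence-arousal circumplex, discretized into four levels:
#' 1 = Negative/High-Arousal ("High Stress"), 2 = Negative/Low-Arousal
#' ("Depressive Mood"), 3 = Positive/Low-Arousal ("Calmness"),
#' 4 = Positive/High-Arousal ("High Energy"). The PAM protocol's exact
#' score-to-quadrant table is an instrument detail, so the package ships an
#' explicit, overridable lookup (`inst/extdata/pam_levels.csv`) rather than
#' hard-coding one: scores 1--4 map to level 2, 5--8 to level 3, 9--12 to
#' level 1, and 13--16 to level 4 by default.
#'
#' @param path optional CSV with columns `pam_score`, `level` overriding the
#'   shipped default.
#' @return Integer vector of length 16; entry `s` is the level of score `s`.
#' @export
pam_level_lookup <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pam_levels.csv", package = "tsnaffect")
  }
  df <- utils::read.csv(path)
  stopifnot(all(c("pam_score", "level") %in% names(df)))
  lk <- integer(16)
  lk[df$pam_score] <- as.integer(df$level)
  if (any(lk < 1 | lk > 4) || !setequal(unique(lk), 1:4)) {
    stop("PAM lookup must map the 16 scores onto all four levels")
  }
  lk
}

#' Map a PAM score to one of the four affect levels
#'
#' @param pam_score integer vector of scores in 1--16.
#' @param lookup level lookup from [pam_level_lookup()].
#' @return Integer vector of levels in 1--4.
#' @export
pam_to_level <- function(pam_score, lookup = pam_level_lookup()) {
  if (any(is.na(pam_score)) || any(pam_score != round(pam_score)) ||
      any(pam_score < 1) || any(pam_score > 16)) {
    stop("pam_score must be an integer in [1, 16]")
  }
  lookup[as.integer(pam_score)]
}

#' Ground-truth affect level of one logical day
#'
#' The label of a day is the level of the last PAM response on that day
#' (self-reports are noisy; the last response summarizes the day's terminal
#' state). Days with no response have a missing label and are excluded from
#' supervised training.
#'
#' @param pam data frame with columns `timestamp`, `pam_score`.
#' @param day integer day index.
#' @param day_start_hour,tz_offset day-boundary convention, as in
#'   [segment_days()].
#' @param lookup level lookup from [pam_level_lookup()].
#' @return Integer level in 1--4, or `NA` if no response that day.
#' @export
daily_label <- function(pam, day, day_start_hour = 0, tz_offset = 0,
                        lookup = pam_level_lookup()) {
  if (nrow(pam) == 0) return(NA_integer_)
  sel <- day_index(pam$timestamp, tz_offset, day_start_hour) == day
  if (!any(sel)) return(NA_integer_)
  last <- which(sel)[which.max(pam$timestamp[sel])]
  pam_to_level(pam$pam_score[last], lookup)
}
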