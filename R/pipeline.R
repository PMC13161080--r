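#' Extract per-day and per-student behavioral features for a cohort
#'
#' Runs the full feature pipeline: day segmentation, the 6-hour coverage
#' filter, per-day activity-event entropy, morning onset, cohort-wide
#' co-location social episodes, internet-usage metrics, and the daily
#' affect label. Aggregates the per-student features (regularity `r_f`,
#' mean onset `r_wh`, episode count `social`, mean daily online time
#' `r_dt` split weekday/weekend, adjusted last logout `r_nt`, daily
#' traffic `r_fr`) used for association mining.
#'
#' @param cohort named list of [sensing_streams()] objects.
#' @param scheme a [binning_scheme()].
#' @param tz_offset fixed local-time offset in seconds east of UTC.
#' @param min_hours,stale_minutes coverage rule, see
#'   [apply_coverage_filter()].
#' @param lookup PAM level lookup, see [pam_level_lookup()].
#' @param ... further arguments passed to [social_interactions()].
#' @return List with elements
#'   \describe{
#'     \item{daily}{data frame `student_id`, `day`, `entropy`, `onset`,
#'       `social`, `session_min`, `last_logout`, `traffic`,
#'       `coverage_hours`, `valid`, `label` (unimputed).}
#'     \item{students}{data frame `student_id`, `r_f`, `r_wh`, `social`,
#'       `r_dt_weekday`, `r_dt_weekend`, `r_nt`, `r_fr`, `level` (modal
#'       daily level), `d_valid`, `t_span`.}
#'     \item{episodes}{the [social_interactions()] episode table.}
#'   }
#' @export
extract_features <- function(cohort, scheme = binning_scheme(),
                             tz_offset = 0, min_hours = 6,
                             stale_minutes = 10,
                             lookup = pam_level_lookup(), ...) {
  ids <- names(cohort) %||% vapply(cohort, `[[`, "", "student_id")
  names(cohort) <- ids
  day_rows <- list()
  per_student_days <- list()
  for (sid in ids) {
    st <- cohort[[sid]]
    days <- apply_coverage_filter(segment_days(st, tz_offset = tz_offset),
                                  min_hours, stale_minutes)
    per_student_days[[sid]] <- days
    if (!length(days)) next
    night <- suppressMessages(infer_night_cluster(st$wifi, tz_offset))
    # per-day usage aggregates from the session stream
    sess <- st$sessions
    sday <- shifted_day_index(sess$login, tz_offset)
    lday <- shifted_day_index(sess$logout, tz_offset)
    for (d in days) {
      bc <- bin_events(d, scheme)
      ent <- if (sum(bc) > 0) entropy_nats(bc / sum(bc)) else 0
      on_day <- sday == d$day
      smin <- if (any(on_day)) {
        sum(sess$logout[on_day] - sess$login[on_day]) / 60
      } else 0
      out_day <- lday == d$day
      llog <- if (any(out_day)) {
        max(shift_logical_day(sess$logout[out_day], tz_offset))
      } else NA_real_
      traf <- if (any(on_day)) sum(sess$traffic_mb[on_day]) else 0
      day_rows[[length(day_rows) + 1]] <- data.frame(
        student_id = sid, day = d$day,
        entropy = ent,
        onset = morning_onset(d, night_cluster = night),
        social = 0L,
        session_min = smin,
        last_logout = llog,
        traffic = traf,
        coverage_hours = d$coverage_hours,
        valid = d$valid,
        label = daily_label(st$pam, d$day, tz_offset = tz_offset,
                            lookup = lookup),
        stringsAsFactors = FALSE)
    }
  }
  daily <- do.call(rbind, day_rows)
  validity <- daily[, c("student_id", "day", "valid")]
  soc <- social_interactions(cohort, day_validity = validity,
                             stale_minutes = stale_minutes,
                             tz_offset = tz_offset, ...)
  if (nrow(soc$episodes)) {
    ep_day <- day_index(soc$episodes$overlap_start, tz_offset)
    ep <- data.frame(student_id = c(soc$episodes$student_a,
                                    soc$episodes$student_b),
                     day = rep(ep_day, 2))
    tab <- table(paste(ep$student_id, ep$day))
    key <- paste(daily$student_id, daily$day)
    hit <- match(key, names(tab))
    daily$social <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }

  # per-student aggregates over valid days
  stu_rows <- lapply(ids, function(sid) {
    days <- per_student_days[[sid]]
    if (!length(days)) return(NULL)
    sub <- daily[daily$student_id == sid, , drop = FALSE]
    t_span <- nrow(sub)
    vdays <- days[vapply(days, function(d) isTRUE(d$valid), TRUE)]
    reg <- if (length(vdays)) {
      suppressWarnings(regularity_entropy(vdays, scheme, t_span = t_span))
    } else NULL
    onset_valid <- sub$onset[sub$valid]
    om <- mean_onset(onset_valid)
    observed <- sub$day
    st <- cohort[[sid]]
    data.frame(
      student_id = sid,
      r_f = if (is.null(reg)) NA_real_ else reg$r_f,
      r_wh = om$r_wh,
      social = sum(sub$social[sub$valid]),
      r_dt_weekday = usage_duration(st$sessions, observed, "weekday",
                                    tz_offset),
      r_dt_weekend = usage_duration(st$sessions, observed, "weekend",
                                    tz_offset),
      r_nt = late_night(st$sessions, tz_offset),
      r_fr = data_intensity(st$sessions, t_span),
      level = modal_level(sub$label),
      d_valid = length(vdays),
      t_span = t_span,
      stringsAsFactors = FALSE)
  })
  students <- do.call(rbind, stu_rows)
  rownames(daily) <- rownames(students) <- NULL
  list(daily = daily, students = students, episodes = soc$episodes)
}

# Modal daily level; ties break toward the lower (more severe) level.
modal_level <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_integer_)
  tab <- tabulate(labels, N_LEVELS)
  which.max(tab)
}

#' Assemble imputed, model-ready daily feature vectors
#'
#' Applies per-student median-fill imputation (over valid days) to the
#' per-day metrics of [extract_features()] and returns the fixed-order
#' feature table feeding [build_samples()]. Standardization happens inside
#' [tsn()] using training-split statistics only, so no leakage occurs
#' here. Students with zero valid days are dropped with a warning.
#'
#' @param daily the `daily` table from [extract_features()].
#' @return The imputed table; feature order is given by attribute
#'   `"feature_cols"`: entropy, onset, social, session_min, last_logout,
#'   traffic.
#' @export
build_daily_vectors <- function(daily) {
  cols <- c("entropy", "onset", "social", "session_min", "last_logout",
            "traffic")
  parts <- lapply(split(daily, daily$student_id), impute_missing,
                  continuous = cols)
  out <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  out <- out[order(out$student_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_cols") <- cols
  out
}

#' Mine association rules between discretized behavior and affect levels
#'
#' Convenience wrapper for the first analysis phase: fits Jenks breaks to
#' each per-student feature, discretizes the cohort into transactions
#' (one per student, label = modal daily level), and runs Apriori plus
#' rule generation at the given thresholds.
#'
#' @param students the `students` table from [extract_features()].
#' @param features feature columns to mine (default the six aggregates).
#' @param k Jenks class count per feature (default 3).
#' @param min_support,min_confidence mining thresholds (default 0.5 each).
#' @return List with `models` (per-feature [jenks_breaks()]), `frequent`
#'   (itemsets), `rules`, and `shortlist` (see [select_features()]).
#' @export
mine_rules <- function(students,
                       features = c("r_f", "r_wh", "social",
                                    "r_dt_weekday", "r_nt", "r_fr"),
                       k = 3, min_support = 0.5, min_confidence = 0.5) {
  tab <- students[!is.na(students$level), , drop = FALSE]
  models <- lapply(features, function(f) {
    jenks_breaks(tab[[f]], k = k, feature_name = f)
  })
  names(models) <- features
  tx <- discretize(tab, models)
  freq <- apriori(tx, min_support = min_support)
  rules <- generate_rules(freq, min_confidence = min_confidence)
  shortlist <- select_features(rules, features)
  list(models = models, frequent = freq, rules = rules,
       shortlist = shortlist)
}
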