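# Seeded generator of sensing cohorts with controllable behavioral
# archetypes and planted behavior-affect rules, so every pipeline stage is
# testable without external data.

#' Behavioral archetype specification
#'
#' An archetype fixes the distributional parameters of one behavioral
#' phenotype: how temporally concentrated daily activity is, when the day
#' starts, how socially active the student is, and the internet-usage
#' profile, together with the affect level the archetype is planted to
#' produce.
#'
#' `activity_concentration` is the symmetric Dirichlet parameter of the
#' student's bin-probability vector: values near 0 put almost all activity
#' in a few bins (low entropy); large values spread it uniformly (high
#' entropy).
#'
#' @param name archetype label.
#' @param activity_concentration symmetric Dirichlet parameter (> 0).
#' @param events_per_day mean activity events per day.
#' @param onset_mean,onset_sd morning onset, seconds-of-day.
#' @param social_rate mean co-location episodes per day.
#' @param session_rate mean internet sessions per day.
#' @param session_minutes_mean mean session duration, minutes.
#' @param logout_mean,logout_sd final-logout time in shifted hours (25.5 =
#'   01:30 next morning) and its sd in hours.
#' @param traffic_mean mean daily traffic, MB.
#' @param level the affect level (1--4) this archetype is planted to
#'   produce.
#' @return A list of class `"archetype_spec"`.
#' @export
archetype_spec <- function(name, activity_concentration, events_per_day,
                           onset_mean, onset_sd, social_rate, session_rate,
                           session_minutes_mean, logout_mean, logout_sd,
                           traffic_mean, level) {
  stopifnot(activity_concentration > 0, events_per_day >= 0,
            social_rate >= 0, session_rate >= 0, level %in% 1:4)
  level <- as.integer(level)
  structure(as.list(environment()), class = "archetype_spec")
}

#' Default archetype set
#'
#' Four archetypes populate the four affect levels (all levels must appear
#' for stratified cross-validation). Two mirror the planted association
#' rules: an anxious-irregular phenotype (dispersed activity, late logout,
#' level 1 "High Stress") and a withdrawn phenotype (low social contact,
#' late onset, level 2 "Depressive Mood"); a healthy-regular phenotype
#' (concentrated routine, early onset, sociable, level 3 "Calmness") and a
#' high-energy phenotype (very active and sociable, level 4) complete the
#' set.
#'
#' @return Named list of [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    anxious_irregular = archetype_spec(
      "anxious_irregular", activity_concentration = 20,
      events_per_day = 40, onset_mean = 9 * 3600, onset_sd = 3600,
      social_rate = 1.5, session_rate = 4, session_minutes_mean = 45,
      logout_mean = 25.5, logout_sd = 0.5, traffic_mean = 600, level = 1),
    withdrawn = archetype_spec(
      "withdrawn", activity_concentration = 2,
      events_per_day = 25, onset_mean = 10.5 * 3600, onset_sd = 3600,
      social_rate = 0.3, session_rate = 3, session_minutes_mean = 50,
      logout_mean = 23.5, logout_sd = 0.5, traffic_mean = 300, level = 2),
    healthy_regular = archetype_spec(
      "healthy_regular", activity_concentration = 0.15,
      events_per_day = 35, onset_mean = 7.5 * 3600, onset_sd = 1800,
      social_rate = 3, session_rate = 3, session_minutes_mean = 35,
      logout_mean = 22.8, logout_sd = 0.4, traffic_mean = 350, level = 3),
    high_energy = archetype_spec(
      "high_energy", activity_concentration = 1,
      events_per_day = 50, onset_mean = 8 * 3600, onset_sd = 2700,
      social_rate = 4, session_rate = 4, session_minutes_mean = 40,
      logout_mean = 23.2, logout_sd = 0.5, traffic_mean = 500, level = 4)
  )
}

#' Cohort specification for the synthetic generator
#'
#' @param n_students number of students (>= 2).
#' @param n_days observation span in days.
#' @param archetype_mix proportions over `archetypes`, summing to 1.
#' @param rule_strength probability that a student conforms to their
#'   archetype's planted affect level (the confidence at which the planted
#'   rules hold).
#' @param noise daily label-flip probability.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @param archetypes list from [default_archetypes()] or custom.
#' @param start_day first day index (days since epoch); the default lands
#'   on a Monday so weekday/weekend structure is present.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_students = 200, n_days = 60,
                        archetype_mix = NULL, rule_strength = 0.8,
                        noise = 0.1, seed = 1,
                        archetypes = default_archetypes(),
                        start_day = 19002L) {
  if (is.null(archetype_mix)) {
    archetype_mix <- rep(1 / length(archetypes), length(archetypes))
  }
  stopifnot(n_students >= 2, n_days >= 1,
            length(archetype_mix) == length(archetypes),
            abs(sum(archetype_mix) - 1) < 1e-8,
            rule_strength >= 0, rule_strength <= 1, noise >= 0, noise <= 1)
  structure(list(n_students = n_students, n_days = as.integer(n_days),
                 archetype_mix = archetype_mix,
                 rule_strength = rule_strength, noise = noise,
                 seed = as.integer(seed), archetypes = archetypes,
                 start_day = as.integer(start_day)),
            class = "cohort_spec")
}

# inverse of the default PAM lookup: scores belonging to each level
scores_for_level <- function(lookup) {
  lapply(1:4, function(l) which(lookup == l))
}

#' Generate a synthetic sensing cohort
#'
#' Realizes the cohort specification as raw sensing streams. Per student:
#' a bin-probability vector drawn from the archetype's Dirichlet
#' concentration drives scattered walking events; a sustained morning walk
#' (Gaussian onset) plus a Wi-Fi departure from the home cluster realize
#' the onset signal; co-location episodes appear as synchronized Wi-Fi
#' scans of both participants at a shared location with Speaking
#' microphone records; internet sessions have log-normal durations, a
#' final logout drawn around the archetype's (possibly post-midnight)
#' logout time, and gamma-distributed traffic; one PAM response per day
#' encodes the label.
#'
#' The planted rules are enforced per student: with probability
#' `rule_strength` the student conforms to their archetype's affect level,
#' otherwise a random other level is substituted; each day's label then
#' flips to a random other level with probability `noise`.
#'
#' @param spec a [cohort_spec()].
#' @param lookup PAM level lookup (labels are encoded as scores through
#'   its inverse).
#' @return A list of class `"synthetic_cohort"`: `streams` (named list of
#'   [sensing_streams()]), `labels` (data frame `student_id`, `day`,
#'   `level`), `students` (data frame `student_id`, `archetype`,
#'   `conforming`, `base_level`), and `spec`.
#' @export
generate_cohort <- function(spec, lookup = pam_level_lookup()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_students
  n_days <- spec$n_days
  arch_names <- names(spec$archetypes)
  scheme <- binning_scheme()
  n_bins <- scheme$n_bins
  lvl_scores <- scores_for_level(lookup)

  sid <- sprintf("s%03d", seq_len(n))
  # archetype assignment: exact proportions, shuffled
  cnt <- floor(spec$archetype_mix * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(spec$archetype_mix * n - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  arch <- sample(rep(arch_names, cnt))
  conforming <- stats::runif(n) < spec$rule_strength
  base_level <- integer(n)
  for (i in seq_len(n)) {
    al <- spec$archetypes[[arch[i]]]$level
    base_level[i] <- if (conforming[i]) al else
      sample(setdiff(1:4, al), 1)
  }

  days <- spec$start_day + seq_len(n_days) - 1L
  day0 <- as.numeric(days) * 86400

  # ---- plan social episodes cohort-wide, then realize per student ----
  # each pair occupies a half-hour slot (16 from 12:00) so one student's
  # episodes never overlap in time and their Wi-Fi segments stay clean
  rates <- vapply(arch, function(a) spec$archetypes[[a]]$social_rate, 0)
  slot_len <- 1800
  ep_rows <- list()
  for (d in seq_len(n_days)) {
    slots_used <- integer(n)
    n_slots <- stats::rpois(n, rates)
    pool <- sample(rep(seq_len(n), n_slots))
    e <- 0L
    while (length(pool) >= 2) {
      i <- pool[1]; j <- pool[2]; pool <- pool[-(1:2)]
      if (i == j) next
      slot <- max(slots_used[i], slots_used[j])
      if (slot >= 16L) next
      slots_used[i] <- slots_used[j] <- slot + 1L
      e <- e + 1L
      st <- day0[d] + 12 * 3600 + slot * slot_len +
        stats::runif(1, 0, slot_len - 1260)
      ep_rows[[length(ep_rows) + 1]] <- data.frame(
        day = d, i = i, j = j, start = st, end = st + 1200,
        loc = sprintf("meet_%d_%d", d, e), stringsAsFactors = FALSE)
    }
  }
  episodes <- if (length(ep_rows)) do.call(rbind, ep_rows) else
    data.frame(day = integer(0), i = integer(0), j = integer(0),
               start = numeric(0), end = numeric(0), loc = character(0))
  # windows seen from one participant's side; the first participant
  # carries the conversational (Speaking) evidence
  part <- rbind(
    data.frame(day = episodes$day, who = episodes$i, start = episodes$start,
               end = episodes$end, loc = episodes$loc,
               speaks = rep(TRUE, nrow(episodes)), stringsAsFactors = FALSE),
    data.frame(day = episodes$day, who = episodes$j, start = episodes$start,
               end = episodes$end, loc = episodes$loc,
               speaks = rep(FALSE, nrow(episodes)), stringsAsFactors = FALSE))

  part_by_who <- split(part, part$who)
  streams <- vector("list", n)
  label_rows <- vector("list", n)
  for (i in seq_len(n)) {
    my_part <- part_by_who[[as.character(i)]]
    a <- spec$archetypes[[arch[i]]]
    home <- paste0("home_", sid[i])
    camp <- paste0("camp_", sid[i])
    q <- stats::rgamma(n_bins, shape = a$activity_concentration, rate = 1)
    if (sum(q) == 0) q[sample.int(n_bins, 1)] <- 1
    q <- q / sum(q)
    acc_t <- list(); acc_s <- list()
    mic_t <- list(); mic_s <- list()
    wifi_t <- list(); wifi_l <- list()
    se_login <- list(); se_logout <- list(); se_mb <- list()
    pam_t <- numeric(n_days); pam_sc <- integer(n_days)
    lab <- integer(n_days)
    for (d in seq_len(n_days)) {
      t0 <- day0[d]
      onset <- min(max(stats::rnorm(1, a$onset_mean, a$onset_sd),
                       5.75 * 3600), 12 * 3600)
      # background stationary records give the day its coverage
      bg <- seq(6 * 3600, 22 * 3600, by = 480)
      # sustained morning walk realizes the onset
      walk <- seq(onset, onset + 360, by = 30)
      # scattered activity events per the bin distribution
      n_ev <- stats::rpois(1, a$events_per_day)
      ev_bin <- sample.int(n_bins, n_ev, replace = TRUE, prob = q)
      ev <- 6 * 3600 + (ev_bin - 1) * scheme$bin_minutes * 60 +
        stats::runif(n_ev, 0, scheme$bin_minutes * 60)
      acc_t[[d]] <- t0 + c(bg, walk, ev)
      acc_s[[d]] <- c(rep("Stationary", length(bg)),
                      rep("Walking", length(walk) + n_ev))
      # microphone: quiet background
      mt <- t0 + seq(9 * 3600, 21 * 3600, by = 600)
      ms <- rep("Quiet", length(mt))
      # wifi: night at home, day at a personal campus location
      night <- t0 + seq(1800, 4.5 * 3600, by = 3600)
      campus <- t0 + seq(onset + 600, 21 * 3600, by = 1800)
      wt <- c(night, campus)
      wl <- c(rep(home, length(night)), rep(camp, length(campus)))
      # co-location episodes: synchronized scans + conversation evidence
      wins <- if (is.null(my_part)) NULL else
        my_part[my_part$day == d, , drop = FALSE]
      if (!is.null(wins) && nrow(wins)) {
        for (w in seq_len(nrow(wins))) {
          ws <- wins$start[w]; we <- wins$end[w]
          # suppress campus scans colliding with the episode
          drop <- wt >= ws - 60 & wt <= we + 60
          wt <- wt[!drop]; wl <- wl[!drop]
          scan <- seq(ws, we, by = 180)
          wt <- c(wt, scan); wl <- c(wl, rep(wins$loc[w], length(scan)))
          if (wins$speaks[w]) {
            sp <- ws + c(120, 480, 900)
            mt <- c(mt, sp); ms <- c(ms, rep("Speaking", 3))
          }
        }
      }
      wifi_t[[d]] <- wt; wifi_l[[d]] <- wl
      mic_t[[d]] <- mt; mic_s[[d]] <- ms
      # internet sessions; the last one ends at the archetype's logout time
      n_s <- max(1L, stats::rpois(1, a$session_rate))
      dur <- pmin(stats::rlnorm(n_s, log(a$session_minutes_mean * 60) - 0.28,
                                0.75), 4 * 3600)
      login <- t0 + stats::runif(n_s - 1, 9 * 3600, 20 * 3600)
      last_out <- t0 + max(stats::rnorm(1, a$logout_mean, a$logout_sd),
                           21) * 3600
      login <- c(login, last_out - dur[n_s])
      logout <- pmin(login + dur, last_out - 1)
      logout[n_s] <- last_out
      mb <- stats::rgamma(n_s, shape = 2,
                          rate = 2 * a$session_rate / a$traffic_mean)
      se_login[[d]] <- login; se_logout[[d]] <- logout; se_mb[[d]] <- mb
      # daily label and PAM encoding
      l <- base_level[i]
      if (stats::runif(1) < spec$noise) l <- sample(setdiff(1:4, l), 1)
      lab[d] <- l
      pam_t[d] <- t0 + 21.5 * 3600
      pam_sc[d] <- lvl_scores[[l]][sample.int(4, 1)]
    }
    streams[[i]] <- sensing_streams(
      sid[i],
      accel = data.frame(timestamp = unlist(acc_t), state = unlist(acc_s)),
      mic = data.frame(timestamp = unlist(mic_t), state = unlist(mic_s)),
      wifi = data.frame(timestamp = unlist(wifi_t),
                        location_id = unlist(wifi_l)),
      sessions = data.frame(login = unlist(se_login),
                            logout = unlist(se_logout),
                            traffic_mb = unlist(se_mb)),
      pam = data.frame(timestamp = pam_t, pam_score = pam_sc))
    label_rows[[i]] <- data.frame(student_id = sid[i], day = days,
                                  level = lab, stringsAsFactors = FALSE)
  }
  names(streams) <- sid
  structure(list(
    streams = streams,
    labels = do.call(rbind, label_rows),
    students = data.frame(student_id = sid, archetype = arch,
                          conforming = conforming,
                          base_level = base_level,
                          stringsAsFactors = FALSE),
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d students x %d days (seed %d)\n",
              x$spec$n_students, x$spec$n_days, x$spec$seed))
  print(table(x$students$archetype))
  invisible(x)
}

#' Write a synthetic cohort as delimited-text files
#'
#' Emits exactly the layout [read_streams()] accepts (five CSVs per
#' student), plus `labels.csv`, `students.csv` and a `manifest.json`
#' recording the generating specification and seed for provenance.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (st in cohort$streams) write_streams(st, dir)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$students, file.path(dir, "students.csv"),
                   row.names = FALSE, quote = FALSE)
  spec <- cohort$spec
  manifest <- list(
    n_students = spec$n_students, n_days = spec$n_days,
    archetype_mix = spec$archetype_mix, rule_strength = spec$rule_strength,
    noise = spec$noise, seed = spec$seed, start_day = spec$start_day,
    archetypes = names(spec$archetypes),
    students = unname(vapply(cohort$streams, `[[`, "", "student_id")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return A list with `streams` (named list of [sensing_streams()]) and
#'   `labels` (data frame, `NULL` if absent).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    ids <- jsonlite::read_json(mf, simplifyVector = TRUE)$students
  } else {
    ids <- unique(sub("_(accel|mic|wifi|sessions|pam)\\.csv$", "",
                      list.files(dir, pattern = "_accel\\.csv$")))
    ids <- sub("_accel$", "", ids)
  }
  streams <- lapply(ids, function(s) {
    paths <- stats::setNames(
      file.path(dir, paste0(s, "_", stream_names, ".csv")), stream_names)
    read_streams(paths, student_id = s)
  })
  names(streams) <- ids
  lf <- file.path(dir, "labels.csv")
  labels <- if (file.exists(lf)) utils::read.csv(lf) else NULL
  list(streams = streams, labels = labels)
}
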