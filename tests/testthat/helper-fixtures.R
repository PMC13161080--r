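# Shared fixtures and independent brute-force oracles.

DAY0 <- 19010 * 86400  # an arbitrary reference midnight (UTC)

hms <- function(h, m = 0, s = 0) h * 3600 + m * 60 + s

# Build a "student_day" object directly from record vectors.
make_day <- function(accel_t = numeric(0), accel_s = character(0),
                     wifi_t = numeric(0), wifi_l = character(0),
                     day = 19010L, tz_offset = 0) {
  structure(list(
    student_id = "sx", day = day, day_start_hour = 0, tz_offset = tz_offset,
    accel = data.frame(timestamp = accel_t, state = accel_s,
                       stringsAsFactors = FALSE),
    mic = data.frame(timestamp = numeric(0), state = character(0)),
    wifi = data.frame(timestamp = wifi_t, location_id = wifi_l,
                      stringsAsFactors = FALSE),
    sessions = data.frame(login = numeric(0), logout = numeric(0),
                          traffic_mb = numeric(0)),
    pam = data.frame(timestamp = numeric(0), pam_score = integer(0)),
    valid = TRUE, coverage_hours = NA_real_
  ), class = "student_day")
}

# --- Jenks oracle: exhaustive enumeration of contiguous partitions -------

bf_sse <- function(x) sum((x - mean(x))^2)

bf_jenks_sdcm <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    sdcm <- sum(vapply(seq_len(k), function(c)
      bf_sse(x[(b[c] + 1):b[c + 1]]), 0))
    best <- min(best, sdcm)
  }
  best
}

# --- Apriori oracle: power-set enumeration -------------------------------

key_of <- function(items) paste(sort(items), collapse = "\r")

bf_frequent <- function(transactions, min_support) {
  n <- length(transactions)
  items <- sort(unique(unlist(transactions)))
  out <- list()
  for (sz in seq_along(items)) {
    sets <- utils::combn(items, sz, simplify = FALSE)
    for (s in sets) {
      sup <- mean(vapply(transactions, function(t) all(s %in% t), TRUE))
      if (sup >= min_support) out[[paste(s, collapse = "\r")]] <- sup
    }
  }
  out
}

bf_rules <- function(freq, min_confidence, label_prefix = "level=") {
  out <- list()
  for (key in names(freq)) {
    s <- strsplit(key, "\r", fixed = TRUE)[[1]]
    lab <- startsWith(s, label_prefix)
    if (sum(lab) != 1 || length(s) < 2) next
    a_key <- paste(s[!lab], collapse = "\r")
    conf <- freq[[key]] / freq[[a_key]]
    if (conf >= min_confidence) {
      out[[paste(paste(s[!lab], collapse = " & "), "->", s[lab])]] <- conf
    }
  }
  out
}

# --- Social-interaction oracle: naive all-pairs overlap scan -------------

bf_social <- function(cohort, min_overlap_minutes = 5, min_scans = 3,
                      unknown_frac_max = 0.5, stale_minutes = 10) {
  ids <- names(cohort)
  counts <- stats::setNames(integer(length(ids)), ids)
  n_ep <- 0L
  segs <- lapply(cohort, function(x) wifi_segments(x$wifi, stale_minutes))
  in_win <- function(ts, s, e) ts >= s - 1e-9 & ts <= e + 1e-9
  for (ui in seq_along(ids)) for (vi in seq_along(ids)) {
    if (vi <= ui) next
    u <- ids[ui]; v <- ids[vi]
    su <- segs[[u]]; sv <- segs[[v]]
    for (i in seq_len(nrow(su))) for (j in seq_len(nrow(sv))) {
      if (su$location_id[i] != sv$location_id[j]) next
      s <- max(su$start[i], sv$start[j])
      e <- min(su$end[i], sv$end[j])
      if (e - s < min_overlap_minutes * 60) next
      ok <- TRUE
      for (w in c(u, v)) {
        wf <- cohort[[w]]$wifi
        n_sc <- sum(in_win(wf$timestamp, s, e) &
                      wf$location_id == su$location_id[i])
        if (n_sc < min_scans) ok <- FALSE
      }
      if (!ok) next
      conv <- FALSE
      for (w in c(u, v)) {
        mc <- cohort[[w]]$mic
        sel <- in_win(mc$timestamp, s, e)
        if (any(sel)) {
          if (mean(mc$state[sel] == "Unknown") > unknown_frac_max) {
            ok <- FALSE
          }
          if (any(mc$state[sel] %in% c("Speaking", "Noisy"))) conv <- TRUE
        }
      }
      if (!ok || !conv) next
      n_ep <- n_ep + 1L
      counts[u] <- counts[u] + 1L
      counts[v] <- counts[v] + 1L
    }
  }
  list(n_episodes = n_ep, counts = counts)
}

# Random small cohort of raw streams for fuzzing the co-location scan.
rand_streams <- function(n_students, seed) {
  set.seed(seed)
  locs <- c("L1", "L2", "L3")
  mic_states <- c("Quiet", "Speaking", "Noisy", "Unknown")
  cohort <- list()
  for (i in seq_len(n_students)) {
    n_w <- sample(3:25, 1)
    wifi <- data.frame(
      timestamp = sort(DAY0 + sample(0:7200, n_w)) ,
      location_id = sample(locs, n_w, replace = TRUE))
    n_m <- sample(0:15, 1)
    mic <- if (n_m > 0) data.frame(
      timestamp = sort(DAY0 + sample(0:7200, n_m)),
      state = sample(mic_states, n_m, replace = TRUE)) else NULL
    cohort[[paste0("u", i)]] <- sensing_streams(
      paste0("u", i), wifi = wifi, mic = mic)
  }
  cohort
}

# Hand-built separable classification set: level = argmax of 4 coordinate
# blocks of the short-term vector, history uninformative noise.
separable_samples <- function(n = 160, t_window = 3, seed = 42) {
  set.seed(seed)
  p <- 4
  y <- rep(1:4, length.out = n)
  Xs <- matrix(rnorm(n * p, 0, 0.1), n, p)
  Xs[cbind(seq_len(n), y)] <- Xs[cbind(seq_len(n), y)] + 3
  XH <- matrix(rnorm(n * t_window * p, 0, 0.1), n * t_window, p)
  structure(list(XH = XH, Xs = Xs, y = y,
                 student = paste0("g", seq_len(n)), day = seq_len(n),
                 t_window = t_window,
                 feature_cols = paste0("f", 1:p)),
            class = "tsn_samples")
}

small_cohort <- function(n_students = 10, n_days = 8, seed = 11, ...) {
  generate_cohort(cohort_spec(n_students = n_students, n_days = n_days,
                              seed = seed, ...))
}
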