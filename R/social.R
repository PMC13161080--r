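#' Merge a Wi-Fi scan stream into location segments
#'
#' Maximal runs of identical consecutive location ids become segments; a
#' location change or a gap longer than `stale_minutes` closes a segment.
#' Each segment is extended past its last scan by half the student's median
#' scan interval (the closure rule), so a single scan yields a short
#' non-degenerate segment.
#'
#' @param wifi data frame with `timestamp`, `location_id`, time-ordered.
#' @param stale_minutes gap that closes a segment (default 10).
#' @param default_closure closure extension in seconds when the stream has
#'   fewer than two scans (default 30).
#' @return Data frame with columns `location_id`, `start`, `end`,
#'   `n_scans`.
#' @export
wifi_segments <- function(wifi, stale_minutes = 10, default_closure = 30) {
  if (nrow(wifi) == 0) {
    return(data.frame(location_id = character(0), start = numeric(0),
                      end = numeric(0), n_scans = integer(0)))
  }
  ts <- wifi$timestamp
  loc <- wifi$location_id
  closure <- if (length(ts) >= 2) stats::median(diff(ts)) / 2 else default_closure
  closure <- min(closure, stale_minutes * 60 / 2)
  brk <- c(TRUE, loc[-1] != loc[-length(loc)] |
                 diff(ts) > stale_minutes * 60)
  starts_at <- which(brk)
  ends_at <- c(starts_at[-1] - 1L, length(ts))
  data.frame(location_id = loc[starts_at],
             start = ts[starts_at],
             end = ts[ends_at] + closure,
             n_scans = ends_at - starts_at + 1L,
             stringsAsFactors = FALSE)
}

# Count mic records of given states within [s, e] using a pre-sorted
# timestamp vector and matching state vector.
count_in_window <- function(ts, sel, s, e) {
  if (length(ts) == 0) return(0L)
  lo <- findInterval(s - 1e-9, ts) + 1L
  hi <- findInterval(e + 1e-9, ts)
  if (hi < lo) return(0L)
  sum(sel[lo:hi])
}

#' Co-location social-interaction episodes across a cohort
#'
#' Infers social episodes from multimodal co-evidence: interpersonal
#' proximity from overlapping Wi-Fi location segments, and conversational
#' context from microphone states. Candidate segment pairs are found
#' through a (location id, time bucket) hash index, so the search is
#' near-linear in the total number of segments rather than quadratic in
#' students. A temporal intersection of two students' segments at the same
#' location becomes an episode iff
#' \itemize{
#'   \item its duration is at least `min_overlap_minutes`;
#'   \item each participant has at least `min_scans` Wi-Fi scans at that
#'     location within the overlap;
#'   \item the fraction of `Unknown` microphone labels within the overlap
#'     is at most `unknown_frac_max` for each participant with mic data
#'     there (low-fidelity windows are excluded);
#'   \item at least one participant has a `Speaking` or `Noisy` mic record
#'     within the overlap (conversational evidence).
#' }
#' Episodes whose start falls on a student-day failing the coverage rule
#' (for either participant) are discarded when `day_validity` is given.
#'
#' @param cohort named list of [sensing_streams()] objects.
#' @param min_overlap_minutes minimum episode duration (default 5).
#' @param min_scans minimum Wi-Fi scans per participant in the overlap
#'   (default 3).
#' @param unknown_frac_max maximum tolerated fraction of Unknown mic labels
#'   (default 0.5).
#' @param bucket_minutes time-bucket width of the spatiotemporal index
#'   (default 15).
#' @param stale_minutes passed to [wifi_segments()].
#' @param day_validity optional data frame `student_id`, `day`, `valid`
#'   from the coverage filter.
#' @param tz_offset local-time offset in seconds.
#' @return List with `episodes` (data frame: `student_a`, `student_b`,
#'   `location_id`, `overlap_start`, `overlap_end`) and `counts` (named
#'   integer vector, episodes per student -- each episode increments both
#'   participants).
#' @export
social_interactions <- function(cohort, min_overlap_minutes = 5,
                                min_scans = 3, unknown_frac_max = 0.5,
                                bucket_minutes = 15, stale_minutes = 10,
                                day_validity = NULL, tz_offset = 0) {
  ids <- names(cohort) %||% vapply(cohort, `[[`, "", "student_id")
  names(cohort) <- ids
  segs <- do.call(rbind, lapply(ids, function(sid) {
    s <- wifi_segments(cohort[[sid]]$wifi, stale_minutes)
    if (nrow(s)) s$student_id <- sid
    s
  }))
  empty <- data.frame(student_a = character(0), student_b = character(0),
                      location_id = character(0), overlap_start = numeric(0),
                      overlap_end = numeric(0))
  counts0 <- stats::setNames(integer(length(ids)), ids)
  if (is.null(segs) || nrow(segs) == 0) {
    return(list(episodes = empty, counts = counts0))
  }
  bsec <- bucket_minutes * 60
  # spatiotemporal index: each segment registers under every
  # (location, bucket) key it spans
  nb <- floor(segs$end / bsec) - floor(segs$start / bsec) + 1
  seg_id <- rep(seq_len(nrow(segs)), nb)
  bucket <- floor(segs$start / bsec)[seg_id] +
    (sequence(nb) - 1)
  key <- paste(segs$location_id[seg_id], bucket)
  busy <- key %in% unique(key[duplicated(key)])
  plist <- lapply(split(seg_id[busy], key[busy]), function(grp) {
    g <- sort(unique(grp))
    if (length(g) >= 2) utils::combn(g, 2) else NULL
  })
  plist <- plist[!vapply(plist, is.null, TRUE)]
  if (!length(plist)) return(list(episodes = empty, counts = counts0))
  pairs <- unique(t(do.call(cbind, plist)))
  a <- pairs[, 1]; b <- pairs[, 2]
  keep <- segs$student_id[a] != segs$student_id[b] &
    segs$location_id[a] == segs$location_id[b]
  a <- a[keep]; b <- b[keep]
  ov_s <- pmax(segs$start[a], segs$start[b])
  ov_e <- pmin(segs$end[a], segs$end[b])
  keep <- ov_e - ov_s >= min_overlap_minutes * 60
  a <- a[keep]; b <- b[keep]; ov_s <- ov_s[keep]; ov_e <- ov_e[keep]
  # per-student sorted evidence vectors
  wifi_ts <- lapply(cohort, function(x) x$wifi$timestamp)
  wifi_loc <- lapply(cohort, function(x) x$wifi$location_id)
  mic_ts <- lapply(cohort, function(x) x$mic$timestamp)
  mic_state <- lapply(cohort, function(x) x$mic$state)
  episode_ok <- function(i) {
    sa <- segs$student_id[a[i]]; sb <- segs$student_id[b[i]]
    loc <- segs$location_id[a[i]]
    s <- ov_s[i]; e <- ov_e[i]
    for (sid in c(sa, sb)) {
      n_sc <- count_in_window(wifi_ts[[sid]], wifi_loc[[sid]] == loc, s, e)
      if (n_sc < min_scans) return(FALSE)
    }
    conv <- FALSE
    for (sid in c(sa, sb)) {
      n_all <- count_in_window(mic_ts[[sid]],
                               rep(TRUE, length(mic_ts[[sid]])), s, e)
      if (n_all > 0) {
        n_unk <- count_in_window(mic_ts[[sid]], mic_state[[sid]] == "Unknown",
                                 s, e)
        if (n_unk / n_all > unknown_frac_max) return(FALSE)
        n_conv <- count_in_window(mic_ts[[sid]],
                                  mic_state[[sid]] %in% c("Speaking", "Noisy"),
                                  s, e)
        if (n_conv > 0) conv <- TRUE
      }
    }
    conv
  }
  ok <- vapply(seq_along(a), episode_ok, TRUE)
  a <- a[ok]; b <- b[ok]; ov_s <- ov_s[ok]; ov_e <- ov_e[ok]
  ep <- data.frame(student_a = segs$student_id[a],
                   student_b = segs$student_id[b],
                   location_id = segs$location_id[a],
                   overlap_start = ov_s, overlap_end = ov_e,
                   stringsAsFactors = FALSE)
  if (!is.null(day_validity) && nrow(ep)) {
    vd <- paste(day_validity$student_id,
                day_validity$day)[day_validity$valid]
    d <- day_index(ep$overlap_start, tz_offset)
    keep <- paste(ep$student_a, d) %in% vd & paste(ep$student_b, d) %in% vd
    ep <- ep[keep, , drop = FALSE]
  }
  counts <- counts0
  if (nrow(ep)) {
    tab <- table(c(ep$student_a, ep$student_b))
    counts[names(tab)] <- as.integer(tab)
  }
  list(episodes = ep, counts = counts)
}
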