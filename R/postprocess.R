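# Post-session analyses: trial segmentation, reward-aligned velocity
# profiles, lost-tracking exclusion, and the session performance
# criterion rule.

#' Segment a session into trials
#'
#' Splits an event log from a trial-structured session (e.g. the spatial
#' reorientation task) into trials: each trial runs from an entry into the
#' start-of-trial marker to the next entry into the end-of-track zone,
#' with the reward timestamp attached when one occurred in between.
#' Unpaired markers are dropped and reported as warnings.
#'
#' For the reorientation task the trial start is the `next_cue` press that
#' arms the rewarded zone (the physical start zone is unreachable), so
#' `start_kind = "next_cue"` is the default; a reachable start zone can be
#' used instead with `start_kind = "zone_entry"` and `start_zone`.
#'
#' @param events Event log data frame.
#' @param samples Sample log data frame (`t,x,y,angle,valid`).
#' @param end_zone Zone id whose entry closes a trial.
#' @param start_kind `"next_cue"` or `"zone_entry"`.
#' @param start_zone Zone id opening a trial when
#'   `start_kind = "zone_entry"`.
#' @param reward_center Optional `(x, y)`; when given, each trial records
#'   `start_offset`, the distance from the trial's first valid sample to
#'   the reward-zone center.
#' @return List with `trials` (list of trial objects: `start_t`, `end_t`,
#'   `reward_t` or NA, `samples`, `start_offset`) and `warnings`
#'   (character vector describing orphan events).
#' @export
segment_trials <- function(events, samples, end_zone,
                           start_kind = c("next_cue", "zone_entry"),
                           start_zone = NULL, reward_center = NULL) {
  start_kind <- match.arg(start_kind)
  if (start_kind == "next_cue") {
    starts <- events$t[events$kind == "next_cue"]
  } else {
    if (is.null(start_zone)) stop("start_zone required", call. = FALSE)
    starts <- events$t[events$kind == "zone_entry" &
                         !is.na(events$zone_id) & events$zone_id == start_zone]
  }
  ends <- events$t[events$kind == "zone_entry" &
                     !is.na(events$zone_id) & events$zone_id == end_zone]
  rewards <- events$t[events$kind == "reward"]
  trials <- list()
  warnings <- character(0)
  used_end <- rep(FALSE, length(ends))
  for (i in seq_along(starts)) {
    s <- starts[i]
    # trial must close before the next trial opens
    s_next <- if (i < length(starts)) starts[i + 1L] else Inf
    cand <- which(!used_end & ends > s & ends <= s_next)
    if (length(cand) == 0L) {
      warnings <- c(warnings,
                    sprintf("trial starting at %.3f s has no end-zone entry; dropped", s))
      next
    }
    e <- ends[cand[1L]]
    used_end[cand[1L]] <- TRUE
    rw <- rewards[rewards >= s & rewards <= e]
    sam <- samples[samples$t >= s & samples$t <= e, , drop = FALSE]
    start_offset <- NA_real_
    if (!is.null(reward_center) && any(sam$valid)) {
      p0 <- sam[sam$valid, ][1L, ]
      start_offset <- sqrt((p0$x - reward_center[1])^2 +
                             (p0$y - reward_center[2])^2)
    }
    trials[[length(trials) + 1L]] <-
      list(start_t = s, end_t = e,
           reward_t = if (length(rw) > 0L) rw[1L] else NA_real_,
           samples = sam, start_offset = start_offset)
  }
  if (any(!used_end))
    warnings <- c(warnings,
                  sprintf("%d end-zone entries were not matched to a trial start",
                          sum(!used_end)))
  list(trials = trials, warnings = warnings)
}

#' Reward-aligned velocity profile of one trial
#'
#' Computes the running speed (central finite difference over the valid
#' samples, optionally smoothed with a moving average) and bins it by the
#' signed along-track distance to the reward-zone center: positions are
#' projected onto the track axis (the outbound start-to-end direction), so
#' negative distances lie before the reward zone on the outbound run and
#' positive distances beyond it.
#'
#' @param trial One trial from [segment_trials()] (needs `samples`).
#' @param reward_center `(x, y)` of the reward zone, pixels.
#' @param bin_width Bin width in px (default 5).
#' @param smooth_window Moving-average window in samples (default 5;
#'   1 disables smoothing).
#' @param track_axis Unit-ish vector giving the outbound direction
#'   (default `(1, 0)`, a horizontal track).
#' @return A `velocity_profile`: data frame with `bin_center` (px,
#'   signed distance), `mean_speed` (px/s) and `n`; attribute `excluded`
#'   (logical) with `reason`. Trials with fewer than two valid samples are
#'   returned empty and excluded.
#' @export
velocity_profile <- function(trial, reward_center, bin_width = 5,
                             smooth_window = 5, track_axis = c(1, 0)) {
  s <- trial$samples[trial$samples$valid, , drop = FALSE]
  empty <- data.frame(bin_center = numeric(0), mean_speed = numeric(0),
                      n = integer(0))
  if (nrow(s) < 2L) {
    return(structure(empty, class = c("velocity_profile", "data.frame"),
                     excluded = TRUE, reason = "fewer than 2 valid samples"))
  }
  n <- nrow(s)
  # central difference speed (one-sided at the ends)
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  speed <- sqrt((s$x[ip] - s$x[im])^2 + (s$y[ip] - s$y[im])^2) /
    (s$t[ip] - s$t[im])
  if (smooth_window > 1L) {
    k <- rep(1 / smooth_window, smooth_window)
    speed <- stats::filter(speed, k, sides = 2)
    pad <- is.na(speed)
    speed[pad] <- NA
  }
  ax <- track_axis / sqrt(sum(track_axis^2))
  dist <- (s$x - reward_center[1]) * ax[1] + (s$y - reward_center[2]) * ax[2]
  keep <- !is.na(speed)
  if (!any(keep)) {
    return(structure(empty, class = c("velocity_profile", "data.frame"),
                     excluded = TRUE, reason = "no smoothed speed samples"))
  }
  bins <- floor(dist[keep] / bin_width)
  agg <- tapply(as.numeric(speed)[keep], bins, mean)
  prof <- data.frame(bin_center = (as.numeric(names(agg)) + 0.5) * bin_width,
                     mean_speed = as.numeric(agg),
                     n = as.integer(table(bins)))
  prof <- prof[order(prof$bin_center), ]
  rownames(prof) <- NULL
  structure(prof, class = c("velocity_profile", "data.frame"),
            excluded = FALSE, reason = NA_character_)
}

#' @export
print.velocity_profile <- function(x, ...) {
  if (isTRUE(attr(x, "excluded"))) {
    cat(sprintf("<velocity profile> excluded: %s\n", attr(x, "reason")))
  } else {
    cat(sprintf("<velocity profile> %d bins, span %.0f..%.0f px, mean speed %.1f px/s\n",
                nrow(x), min(x$bin_center), max(x$bin_center),
                mean(x$mean_speed)))
  }
  invisible(x)
}

#' Flag trials with extensive lost tracking
#'
#' A trial is excluded when any contiguous run of invalid samples spans
#' more than `max_gap` seconds; shorter gaps are filled by linear
#' interpolation of the surrounding valid positions.
#'
#' @param trial One trial (needs `samples`).
#' @param max_gap Longest tolerable lost-tracking gap, seconds.
#' @return List with `excluded` (logical), `reason` (text or NA) and
#'   `trial` (gaps interpolated and samples revalidated when kept).
#' @export
exclude_lost_tracking <- function(trial, max_gap = 0.5) {
  s <- trial$samples
  if (nrow(s) == 0L || all(s$valid)) {
    return(list(excluded = FALSE, reason = NA_character_, trial = trial))
  }
  r <- rle(!s$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    # gap duration spans from the last valid fix to the next one
    t0 <- if (i0 > 1L) s$t[i0 - 1L] else s$t[i0]
    t1 <- if (i1 < nrow(s)) s$t[i1 + 1L] else s$t[i1]
    if (t1 - t0 > max_gap) {
      return(list(excluded = TRUE,
                  reason = sprintf("lost tracking for %.3f s (%.3f..%.3f s) exceeds max gap %.3f s",
                                   t1 - t0, t0, t1, max_gap),
                  trial = trial))
    }
  }
  # interpolate the short gaps
  ok <- s$valid
  if (sum(ok) >= 2L) {
    s$x[!ok] <- stats::approx(s$t[ok], s$x[ok], xout = s$t[!ok], rule = 2)$y
    s$y[!ok] <- stats::approx(s$t[ok], s$y[ok], xout = s$t[!ok], rule = 2)$y
    s$valid <- TRUE
  }
  trial$samples <- s
  list(excluded = FALSE, reason = NA_character_, trial = trial)
}

#' Session performance criterion
#'
#' Tests the training criterion used before advancing a task phase:
#' strictly more than `threshold` percent correct in at least `k` of the
#' last `n` sessions (defaults 80%, 3 of 4 — "over 80%" is strict, so a
#' session at exactly the threshold does not count).
#'
#' @param session_pct_correct Ordered numeric vector of per-session
#'   percent-correct values (oldest first).
#' @param threshold Percent threshold (default 80).
#' @param k_of_n Integer `(k, n)` (default `c(3, 4)`).
#' @param window `"recent"` tests only the most recent `n` sessions;
#'   `"any"` tests every window of `n` consecutive sessions.
#' @return Logical.
#' @export
criterion_met <- function(session_pct_correct, threshold = 80,
                          k_of_n = c(3L, 4L),
                          window = c("recent", "any")) {
  window <- match.arg(window)
  k <- k_of_n[1]; n <- k_of_n[2]
  m <- length(session_pct_correct)
  if (m < n)
    stop(sprintf("insufficient data: %d sessions, criterion window is %d",
                 m, n), call. = FALSE)
  hit <- session_pct_correct > threshold
  if (window == "recent") {
    return(sum(hit[(m - n + 1L):m]) >= k)
  }
  for (i in seq_len(m - n + 1L))
    if (sum(hit[i:(i + n - 1L)]) >= k) return(TRUE)
  FALSE
}
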