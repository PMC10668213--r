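# Session state machine: zone entry/exit detection over a sample stream,
# one-armed-rewarded-zone sequencing, dwell-delay gating, reward dispatch.

# Run fun() under a stored RNG state, returning value + advanced state,
# without disturbing the caller's RNG.
with_rng_state <- function(rng, fun) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  assign(".Random.seed", rng, envir = genv)
  value <- fun()
  list(value = value, rng = get(".Random.seed", envir = genv))
}

rng_state_from_seed <- function(seed) {
  with_rng_state_seed <- function() NULL
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  get(".Random.seed", envir = genv)
}

#' Initialize the task-engine state for a session
#'
#' Sets all zone occupancy flags to "outside", zeroes the counters, seeds
#' the session RNG and arms the first rewarded zone (or a random draw when
#' `randomize_rewards` is set).
#'
#' @param config A [session_config()].
#' @return An `engine_state` object; feed it to [engine_step()].
#' @export
engine_init <- function(config) {
  stopifnot(inherits(config, "session_config"))
  ids <- config$active_zone_ids
  inside <- stats::setNames(rep(FALSE, length(ids)), as.character(ids))
  entries <- stats::setNames(integer(length(ids)), as.character(ids))
  state <- structure(list(
    config = config,
    inside = inside,
    armed_pos = NA_integer_,
    armed_id = NA_integer_,
    dwell_entry_t = NA_real_,
    counters = list(rewards = 0L, stim_manual = 0L, stim_animal = 0L,
                    invalid_samples = 0L, entries = entries),
    last_t = -Inf,
    rng = rng_state_from_seed(config$rng_seed)
  ), class = "engine_state")
  if (length(config$rewarded_zone_ids) > 0L) {
    if (config$randomize_rewards) {
      drawn <- draw_next_reward(state)
      state <- drawn$state
      state$armed_id <- drawn$zone_id
    } else {
      state$armed_pos <- 1L
      state$armed_id <- config$rewarded_zone_ids[1L]
    }
  }
  state
}

#' @export
print.engine_state <- function(x, ...) {
  cat(sprintf("<engine state> t=%.3f, armed zone %s, rewards %d, entries %d\n",
              x$last_t,
              if (is.na(x$armed_id)) "none" else x$armed_id,
              x$counters$rewards, sum(x$counters$entries)))
  invisible(x)
}

# Advance the armed rewarded zone (list order or seeded random draw);
# emits LED cue events when the armed zone's cue light moves.
advance_armed <- function(state, t) {
  cfg <- state$config
  events <- empty_events()
  if (length(cfg$rewarded_zone_ids) == 0L)
    return(list(state = state, events = events))
  old_id <- state$armed_id
  if (cfg$randomize_rewards) {
    drawn <- draw_next_reward(state)
    state <- drawn$state
    state$armed_id <- drawn$zone_id
  } else {
    state$armed_pos <- (state$armed_pos %% length(cfg$rewarded_zone_ids)) + 1L
    state$armed_id <- cfg$rewarded_zone_ids[state$armed_pos]
  }
  state$dwell_entry_t <- NA_real_
  old_led <- if (!is.na(old_id)) cfg$zones[[as.character(old_id)]]$led_index else NULL
  new_led <- if (!is.na(state$armed_id)) cfg$zones[[as.character(state$armed_id)]]$led_index else NULL
  if (!is.null(old_led) && !identical(old_led, new_led))
    events <- bind_events(events, maze_event(t, "led_off", old_id,
                                             detail = sprintf("cue LED %d", old_led)))
  if (!is.null(new_led) && !identical(old_led, new_led))
    events <- bind_events(events, maze_event(t, "led_on", state$armed_id,
                                             detail = sprintf("cue LED %d", new_led)))
  list(state = state, events = events)
}

# The armed zone was triggered (entry, dwell satisfied). A reward is
# dispensed only when the zone's role is "rewarded" and the session
# delivers a reward type; rewarded lists may mix in tracked zones that
# merely advance the sequence (e.g. an end-of-track zone).
deliver_reward <- function(state, t) {
  cfg <- state$config
  zid <- state$armed_id
  zone <- cfg$zones[[as.character(zid)]]
  events <- empty_events()
  if (zone$role == "rewarded" && cfg$reward_type != "none") {
    state$counters$rewards <- state$counters$rewards + 1L
    events <- maze_event(t, "reward", zid, detail = cfg$reward_type)
    if (cfg$reward_type == "stimulation") {
      state$counters$stim_animal <- state$counters$stim_animal + 1L
      events <- bind_events(events, maze_event(t, "stim_animal", zid,
                                               detail = sprintf("%g Hz x %g s",
                                                                cfg$stim$frequency,
                                                                cfg$stim$duration)))
    }
  }
  state$dwell_entry_t <- NA_real_
  adv <- advance_armed(state, t)
  list(state = adv$state, events = bind_events(events, adv$events))
}

#' Advance the engine by one tracking sample
#'
#' Emits `zone_entry` / `zone_exit` events (with their binary TTL words)
#' for every active zone whose occupancy flag flipped, applying entry
#' hysteresis; delivers the reward when the armed rewarded zone has been
#' occupied continuously for the configured dwell delay; arms the next
#' rewarded zone after each reward. Invalid samples (lost tracking) freeze
#' all occupancy state: they are counted but never fabricate zone exits.
#'
#' @param state An `engine_state` from [engine_init()] or a previous step.
#' @param sample One tracking sample: list or one-row data frame with
#'   `t` (seconds, strictly greater than the last processed time),
#'   `x`, `y` (pixels) and `valid` (logical).
#' @return List with the updated `state` and `events` (data frame, possibly
#'   empty).
#' @export
engine_step <- function(state, sample) {
  stopifnot(inherits(state, "engine_state"))
  t <- as.numeric(sample$t)
  if (!is.finite(t) || t <= state$last_t)
    stop(structure(class = c("mazesim_rejected_sample", "error", "condition"),
                   list(message = sprintf(
                     "sample timestamp %.6f not after last processed time %.6f",
                     t, state$last_t), call = NULL)))
  state$last_t <- t
  if (!isTRUE(as.logical(sample$valid))) {
    state$counters$invalid_samples <- state$counters$invalid_samples + 1L
    return(list(state = state, events = empty_events()))
  }
  p <- c(as.numeric(sample$x), as.numeric(sample$y))
  cfg <- state$config
  events <- empty_events()
  for (zid in cfg$active_zone_ids) {
    key <- as.character(zid)
    zone <- cfg$zones[[key]]
    was <- state$inside[[key]]
    now <- occupancy_test(zone, p, currently_inside = was)
    if (now == was) {
      # continuous occupancy of the armed zone: check the dwell clock
      if (now && !is.na(state$armed_id) && zid == state$armed_id &&
          !is.na(state$dwell_entry_t) &&
          (t - state$dwell_entry_t) >= cfg$dwell_delay) {
        res <- deliver_reward(state, t)
        state <- res$state
        events <- bind_events(events, res$events)
      }
      next
    }
    state$inside[[key]] <- now
    if (now) {
      state$counters$entries[[key]] <- state$counters$entries[[key]] + 1L
      events <- bind_events(events,
        maze_event(t, "zone_entry", zid, encode_zone_event(zid, "entry")))
      if (!is.na(state$armed_id) && zid == state$armed_id) {
        if (cfg$dwell_delay <= 0) {
          res <- deliver_reward(state, t)
          state <- res$state
          events <- bind_events(events, res$events)
        } else {
          state$dwell_entry_t <- t
        }
      }
    } else {
      events <- bind_events(events,
        maze_event(t, "zone_exit", zid, encode_zone_event(zid, "exit")))
      if (!is.na(state$armed_id) && zid == state$armed_id) {
        # left the armed zone before the dwell elapsed
        state$dwell_entry_t <- NA_real_
        if (cfg$advance_on_passthrough) {
          adv <- advance_armed(state, t)
          state <- adv$state
          events <- bind_events(events, adv$events)
        }
      }
    }
  }
  list(state = state, events = events)
}

#' Manually advance the armed rewarded zone ("Next Cue")
#'
#' Advances the arming to the next id in the rewarded list (wrapping at
#' the end; a random draw when `randomize_rewards` is set) without
#' delivering a reward, and emits a `next_cue` event. With no rewarded
#' zones configured this is a no-op that logs a warning note.
#'
#' @param state An `engine_state`.
#' @param t Event time in seconds.
#' @return List with updated `state` and `events`.
#' @export
next_cue <- function(state, t = state$last_t) {
  stopifnot(inherits(state, "engine_state"))
  if (length(state$config$rewarded_zone_ids) == 0L) {
    return(list(state = state,
                events = maze_event(t, "session_note",
                                    detail = "next_cue ignored: no rewarded zones configured")))
  }
  adv <- advance_armed(state, t)
  state <- adv$state
  ev <- maze_event(t, "next_cue", state$armed_id,
                   detail = sprintf("armed zone -> %d", state$armed_id))
  list(state = state, events = bind_events(ev, adv$events))
}

#' Draw the next rewarded zone at random
#'
#' Uniform draw with replacement from the session's rewarded-zone list,
#' using the session RNG, so the draw sequence is reproducible from
#' `rng_seed`.
#'
#' @param state An `engine_state` whose config has a non-empty rewarded list.
#' @return List with updated `state` (advanced RNG) and the drawn `zone_id`.
#' @export
draw_next_reward <- function(state) {
  stopifnot(inherits(state, "engine_state"))
  ids <- state$config$rewarded_zone_ids
  if (length(ids) == 0L)
    stop("no rewarded zones configured", call. = FALSE)
  res <- with_rng_state(state$rng, function() ids[sample.int(length(ids), 1L)])
  state$rng <- res$rng
  list(state = state, zone_id = res$value)
}

#' Generate a random-lights zone sequence
#'
#' Draws an ordered sequence of rewarded zone ids independently and
#' uniformly with replacement, as used by the random-lights task (the
#' published sessions drew sequences of up to 900 elements from the 32
#' light/reward zones).
#'
#' @param zone_ids Candidate zone ids (non-empty).
#' @param length Number of elements to draw, >= 1.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return Integer vector of `length` zone ids.
#' @export
generate_random_lights_sequence <- function(zone_ids, length, seed) {
  zone_ids <- as.integer(zone_ids)
  if (base::length(zone_ids) == 0L)
    stop("zone_ids must be non-empty", call. = FALSE)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1", call. = FALSE)
  res <- with_rng_state(rng_state_from_seed(seed), function()
    zone_ids[sample.int(base::length(zone_ids), length, replace = TRUE)])
  res$value
}

#' Session counters
#'
#' The running tallies the control GUI displays: rewards delivered, manual
#' and animal-triggered stimulations, invalid (lost-tracking) samples, and
#' per-zone entry counts.
#'
#' @param state An `engine_state`.
#' @return A list with `rewards`, `stim_manual`, `stim_animal`,
#'   `invalid_samples` and the named integer vector `entries`.
#' @export
session_counters <- function(state) {
  stopifnot(inherits(state, "engine_state"))
  state$counters
}

#' Run the engine over a whole sample stream
#'
#' Convenience wrapper: initializes the engine and steps it through every
#' row of a sample data frame, collecting all events.
#'
#' @param config A [session_config()].
#' @param samples Data frame with columns `t,x,y,valid` (and optionally
#'   `angle`), `t` strictly increasing.
#' @return List with the final `state` and the full `events` log.
#' @export
run_engine <- function(config, samples) {
  state <- engine_init(config)
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    res <- engine_step(state, samples[i, ])
    state <- res$state
    out[[i]] <- res$events
  }
  events <- do.call(bind_events, out)
  list(state = state, events = events)
}
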