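# Ready-made session configurations for the published task protocols,
# each paired with a scripted compliant agent. The platform geometry is a
# 480 x 480 px camera frame, ring of 32 wall LEDs at radius 200 px around
# (240, 240), circular zones of radius 20 px with hysteresis 1.5.

preset_names <- function() {
  c("spatial_reorientation", "sequence_task", "random_lights", "oppa",
    "mat_allocentric", "mat_transformation", "mat_egocentric")
}

platform_layout <- function() {
  perimeter_layout(32, center = c(240, 240), ring_radius = 200,
                   start_angle = 0)
}

zone_at <- function(id, center, role = "tracked", led_index = NULL,
                    radius = 20) {
  zone_spec(id, center, radius = radius, hysteresis = 1.5,
            led_index = led_index, role = role)
}

#' Load a task preset
#'
#' Returns a complete, runnable configuration for one of the platform's
#' published task protocols, together with a scripted compliant agent that
#' performs the task:
#'
#' * `spatial_reorientation` — linear track with three tracked zones
#'   (an unreachable start zone advanced manually at trial start, a
#'   rewarded zone with a dwell delay, an end-of-track zone); start
#'   positions vary across trials from a seeded list; passing through the
#'   rewarded zone advances the sequence.
#' * `sequence_task` — the complex spatial sequence: five zones among the
#'   32 perimeter positions, rewarded in the repeating eight-item order
#'   1-2-3-4-1-2-3-5 starting from zone 5, no dwell delay, reward on
#'   entry.
#' * `random_lights` — all 32 perimeter zones; the rewarded order is a
#'   seeded uniform draw with replacement (`sequence_length` elements,
#'   default 900).
#' * `oppa` — object-place paired-associate maze: seven zones (two choice
#'   platforms, two arms, the central platform, two off-maze zones for
#'   manual-reward timestamps), no automatic reward.
#' * `mat_allocentric`, `mat_transformation` — map-to-action
#'   transformation task: eight arm zones on the ring plus a center zone;
#'   two rewarded zones, one on the rewarded arm and one off the maze so
#'   each reward is delivered once until the experimenter re-arms with
#'   "Next Cue".
#' * `mat_egocentric` — the same arena, but zone entries are only
#'   timestamped; rewards are triggered manually through the stimulation
#'   counter.
#'
#' @param name Preset name (see above).
#' @param seed Integer seed used for the preset's own randomization
#'   (random-lights sequence, reorientation start offsets).
#' @param sequence_length Random-lights sequence length (default 900).
#' @param n_trials Number of scripted trials for trial-structured presets.
#' @return An object of class `task_preset`: list with `name`, `config`
#'   ([session_config()]), `agent` ([agent_model()]), `layout`, `scene`,
#'   and `next_cue_when` (a predicate `(state, sample)` telling
#'   [run_session()] when the scripted experimenter presses "Next Cue",
#'   or NULL).
#' @export
load_preset <- function(name, seed = 1L, sequence_length = 900L,
                        n_trials = 10L) {
  if (!name %in% preset_names())
    stop("unknown preset: ", name, "; known presets: ",
         paste(preset_names(), collapse = ", "), call. = FALSE)
  lay <- platform_layout()
  scene <- sim_scene(lay)
  switch(name,
    spatial_reorientation = {
      reward_c <- c(240, 240)
      end_c <- c(430, 240)
      zones <- list(
        zone_at(1L, c(-100, 240)),                       # unreachable start
        zone_at(2L, reward_c, role = "rewarded"),
        zone_at(3L, end_c))
      cfg <- session_config(zones, rewarded_zone_ids = c(1L, 2L, 3L),
                            reward_type = "stimulation",
                            stim = stim_params(100, 0.5, 50),
                            dwell_delay = 1.5,
                            advance_on_passthrough = TRUE,
                            rng_seed = seed)
      # movable start box: per-trial start x offset from a seeded list
      offs <- with_rng_state(rng_state_from_seed(seed), function()
        stats::runif(n_trials, 30, 110))$value
      wps <- list()
      for (i in seq_len(n_trials)) {
        start <- c(offs[i], 240)
        wps <- c(wps, list(start, reward_c, end_c, start))
      }
      agent <- agent_model(wps, speed = 80, jitter_sd = 1,
                           dwell_at_waypoint = 2, seed = seed)
      # experimenter's clicker: trial starts when the animal is back in
      # the start-box region with the (unreachable) start zone armed
      press <- function(state, sample)
        state$armed_id == 1L && sample$x < 130
      make_preset(name, cfg, agent, lay, scene, press)
    },
    sequence_task = {
      # five task zones on the 32-position ring; LED index = ring position
      ring_pos <- c(5L, 12L, 18L, 25L, 31L)
      zones <- lapply(1:5, function(k)
        zone_at(k, lay$positions[ring_pos[k], ], role = "rewarded",
                led_index = ring_pos[k]))
      order8 <- c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 5L)
      cfg <- session_config(zones, rewarded_zone_ids = order8,
                            reward_type = "liquid", dwell_delay = 0,
                            rng_seed = seed)
      centers <- lapply(zones, `[[`, "center")
      wps <- c(centers[5L], centers[order8])       # start at zone 5
      agent <- agent_model(wps, speed = 120, jitter_sd = 1,
                           dwell_at_waypoint = 0.3, seed = seed)
      make_preset(name, cfg, agent, lay, scene, NULL)
    },
    random_lights = {
      zones <- lapply(1:32, function(k)
        zone_at(k, lay$positions[k, ], role = "rewarded", led_index = k))
      seq_ids <- generate_random_lights_sequence(1:32, sequence_length, seed)
      cfg <- session_config(zones, rewarded_zone_ids = seq_ids,
                            reward_type = "liquid", dwell_delay = 0,
                            rng_seed = seed)
      wps <- list(c(240, 240))
      for (j in seq_along(seq_ids)) {
        # a repeated zone requires an exit and re-entry: bounce via center
        if (j > 1L && seq_ids[j] == seq_ids[j - 1L])
          wps <- c(wps, list(c(240, 240)))
        wps <- c(wps, list(lay$positions[seq_ids[j], ]))
      }
      agent <- agent_model(wps, speed = 150, jitter_sd = 1,
                           dwell_at_waypoint = 0.2, seed = seed)
      make_preset(name, cfg, agent, lay, scene, NULL)
    },
    oppa = {
      zones <- list(
        zone_at(1L, c(60, 240)),    # west choice platform
        zone_at(2L, c(420, 240)),   # east choice platform
        zone_at(3L, c(150, 240)),   # west arm
        zone_at(4L, c(330, 240)),   # east arm
        zone_at(5L, c(240, 240)),   # central platform
        zone_at(6L, c(30, 450)),    # off-maze (manual reward west)
        zone_at(7L, c(450, 450)))   # off-maze (manual reward east)
      cfg <- session_config(zones, reward_type = "none", rng_seed = seed)
      trip <- list(c(240, 240), c(150, 240), c(60, 240), c(150, 240),
                   c(240, 240), c(330, 240), c(420, 240), c(330, 240))
      wps <- c(rep(trip, n_trials), list(c(240, 240)))
      agent <- agent_model(wps, speed = 100, jitter_sd = 1,
                           dwell_at_waypoint = 0.5, seed = seed)
      make_preset(name, cfg, agent, lay, scene, NULL)
    },
    mat_allocentric = ,
    mat_transformation = {
      arm_lay <- perimeter_layout(8, center = c(240, 240), ring_radius = 180,
                                  start_angle = 0)
      zones <- c(
        lapply(1:7, function(k) zone_at(k, arm_lay$positions[k, ])),  # S1-S7
        list(zone_at(8L, arm_lay$positions[8L, ], role = "rewarded"),  # R
             zone_at(9L, c(240, 240)),                                 # center
             zone_at(10L, c(460, 20), role = "rewarded")))             # off-maze
      cfg <- session_config(zones, rewarded_zone_ids = c(8L, 10L),
                            reward_type = "stimulation",
                            stim = stim_params(100, 0.5, 50),
                            dwell_delay = 0, rng_seed = seed)
      starts <- with_rng_state(rng_state_from_seed(seed), function()
        sample.int(7L, n_trials, replace = TRUE))$value
      wps <- list()
      for (s in starts)
        wps <- c(wps, list(arm_lay$positions[s, ], c(240, 240),
                           arm_lay$positions[8L, ], c(240, 240)))
      agent <- agent_model(wps, speed = 100, jitter_sd = 1,
                           dwell_at_waypoint = 0.5, seed = seed)
      # experimenter re-arms the maze reward zone ("Next Cue") once the
      # animal is back at the center after the off-maze zone armed
      press <- function(state, sample)
        state$armed_id == 10L &&
          sqrt((sample$x - 240)^2 + (sample$y - 240)^2) < 60
      make_preset(name, cfg, agent, arm_lay, scene, press)
    },
    mat_egocentric = {
      arm_lay <- perimeter_layout(8, center = c(240, 240), ring_radius = 180,
                                  start_angle = 0)
      zones <- c(
        lapply(1:8, function(k) zone_at(k, arm_lay$positions[k, ])),
        list(zone_at(9L, c(240, 240))))
      cfg <- session_config(zones, reward_type = "none", rng_seed = seed)
      pairs <- with_rng_state(rng_state_from_seed(seed), function()
        sample.int(8L, n_trials, replace = TRUE))$value
      wps <- list()
      for (s in pairs) {
        goal <- ((s + 1L) %% 8L) + 1L   # fixed egocentric offset (e.g. 4 -> 6)
        wps <- c(wps, list(arm_lay$positions[s, ], c(240, 240),
                           arm_lay$positions[goal, ], c(240, 240)))
      }
      agent <- agent_model(wps, speed = 100, jitter_sd = 1,
                           dwell_at_waypoint = 0.5, seed = seed)
      make_preset(name, cfg, agent, arm_lay, scene, NULL)
    })
}

make_preset <- function(name, config, agent, layout, scene,
                        next_cue_when = NULL) {
  structure(list(name = name, config = config, agent = agent,
                 layout = layout, scene = scene,
                 next_cue_when = next_cue_when),
            class = "task_preset")
}

#' @export
print.task_preset <- function(x, ...) {
  cat(sprintf("<task preset '%s'> %d zones, %d rewarded-list entries, reward %s\n",
              x$name, length(x$config$zones),
              length(x$config$rewarded_zone_ids), x$config$reward_type))
  invisible(x)
}

#' Run a simulated session end to end
#'
#' Drives the preset's scripted agent through the task engine: simulates
#' the trajectory, steps the engine over every sample, and plays the
#' experimenter by pressing "Next Cue" whenever the preset's
#' `next_cue_when(state, sample)` predicate fires (the trial-start clicker
#' of the reorientation task, the off-maze re-arm of the MAT task).
#' Deterministic under `seed`.
#'
#' @param preset A [load_preset()] result (or a compatible list with
#'   `config`, `agent`, `next_cue_when`).
#' @param t_max Session duration, seconds.
#' @param seed Integer seed applied to both the agent stream and the
#'   session RNG.
#' @param rate Tracking sample rate, samples/s.
#' @return An object of class `maze_session`: list with `events`,
#'   `samples`, and the final engine `state`.
#' @export
run_session <- function(preset, t_max = 60, seed = 1L, rate = 30) {
  stopifnot(inherits(preset, "task_preset"))
  agent <- preset$agent
  agent$seed <- as.integer(seed)
  config <- preset$config
  config$rng_seed <- as.integer(seed)
  samples <- simulate_trajectory(agent, rate = rate, t_max = t_max)
  state <- engine_init(config)
  logs <- vector("list", nrow(samples) * 2L)
  li <- 0L
  for (i in seq_len(nrow(samples))) {
    if (!is.null(preset$next_cue_when) && !is.na(state$armed_id) &&
        isTRUE(preset$next_cue_when(state, samples[i, ]))) {
      res <- next_cue(state, t = max(0, state$last_t))
      state <- res$state
      li <- li + 1L
      logs[[li]] <- res$events
    }
    res <- engine_step(state, samples[i, ])
    state <- res$state
    li <- li + 1L
    logs[[li]] <- res$events
  }
  events <- do.call(bind_events, logs[seq_len(li)])
  structure(list(events = events, samples = samples, state = state,
                 preset = preset$name),
            class = "maze_session")
}

#' @export
print.maze_session <- function(x, ...) {
  cnt <- session_counters(x$state)
  cat(sprintf("<maze session '%s'> %d samples over %.1f s, %d events\n",
              x$preset, nrow(x$samples), max(x$samples$t), nrow(x$events)))
  cat(sprintf("  rewards %d | animal stim %d | zone entries %d | invalid samples %d\n",
              cnt$rewards, cnt$stim_animal, sum(cnt$entries),
              cnt$invalid_samples))
  invisible(x)
}

#' @export
summary.maze_session <- function(object, ...) {
  cnt <- session_counters(object$state)
  kinds <- table(object$events$kind)
  structure(list(preset = object$preset, counters = cnt,
                 event_kinds = kinds,
                 duration = max(object$samples$t)),
            class = "summary.maze_session")
}

#' @export
print.summary.maze_session <- function(x, ...) {
  cat(sprintf("Session preset: %s (%.1f s)\n", x$preset, x$duration))
  cat("Event counts:\n")
  print(x$event_kinds)
  cat(sprintf("Rewards: %d, entries per zone:\n", x$counters$rewards))
  print(x$counters$entries)
  invisible(x)
}
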