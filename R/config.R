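#' Stimulation parameters
#'
#' Defines the unipolar pulse train used as a brain-stimulation (or
#' optogenetic) reinforcer. The train has `floor(frequency * duration)`
#' cycles of length `1/frequency` seconds; within each cycle the output is
#' high for `duty_cycle` percent, starting at cycle onset. Amplitude and
#' electrode configuration live on the stimulus isolator, not here.
#'
#' @param frequency Pulse rate in Hz, > 0.
#' @param duration Train duration in seconds, > 0. `frequency * duration`
#'   must allow at least one full cycle.
#' @param duty_cycle Percent of each cycle spent high, in (0, 100].
#' @param polarity `"unipolar"` (TTL / laser gate) or `"bipolar"`
#'   (charge-balanced biphasic output, as produced by a stimulus isolator).
#' @param trigger_edge Which edge of an external TTL input triggers an
#'   automatic train: `"rising"` or `"falling"`.
#' @param dwell_delay Seconds the animal must remain in a rewarded zone
#'   before an animal-triggered stimulation is delivered; mirrored here
#'   for standalone use, gating itself is enforced by the task engine.
#' @return An object of class `stim_params`.
#' @examples
#' stim_params(frequency = 100, duration = 0.5, duty_cycle = 50)
#' @export
stim_params <- function(frequency = 100, duration = 0.5, duty_cycle = 50,
                        polarity = c("unipolar", "bipolar"),
                        trigger_edge = c("rising", "falling"),
                        dwell_delay = 0) {
  polarity <- match.arg(polarity)
  trigger_edge <- match.arg(trigger_edge)
  if (!is.numeric(frequency) || frequency <= 0)
    stop("frequency must be > 0 Hz", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0 s", call. = FALSE)
  if (!is.numeric(duty_cycle) || duty_cycle <= 0 || duty_cycle > 100)
    stop("duty_cycle must be in (0, 100]", call. = FALSE)
  if (frequency * duration < 1)
    stop("frequency * duration must allow at least one full cycle",
         call. = FALSE)
  if (!is.numeric(dwell_delay) || dwell_delay < 0)
    stop("dwell_delay must be >= 0 s", call. = FALSE)
  structure(list(frequency = frequency, duration = duration,
                 duty_cycle = duty_cycle, polarity = polarity,
                 trigger_edge = trigger_edge, dwell_delay = dwell_delay),
            class = "stim_params")
}

#' @export
print.stim_params <- function(x, ...) {
  cat(sprintf("<stim params> %g Hz x %g s, duty %g%%, %s, trigger on %s edge, dwell %g s\n",
              x$frequency, x$duration, x$duty_cycle, x$polarity,
              x$trigger_edge, x$dwell_delay))
  invisible(x)
}

#' Session configuration
#'
#' The complete definition of one experimental session: the zones, which
#' of them are active, the ordered rewarded-zone list (repeats allowed),
#' the reward type, stimulation parameters, dwell-delay gating and session
#' metadata. At any given time the engine arms at most one rewarded zone;
#' the list advances when the animal triggers the armed zone or the
#' experimenter advances it manually.
#'
#' @param zones List of [zone_spec()] objects (unique ids).
#' @param active_zone_ids Integer vector: zones tracked this session.
#' @param rewarded_zone_ids Ordered integer vector of zone ids to arm in
#'   sequence; repeats allowed; every id must be active.
#' @param randomize_rewards Logical: draw the next armed zone uniformly
#'   (with replacement) from `rewarded_zone_ids` instead of following the
#'   list order.
#' @param reward_type `"none"`, `"liquid"` or `"stimulation"`.
#' @param stim A [stim_params()] (used when `reward_type = "stimulation"`).
#' @param dwell_delay Seconds of continuous occupancy required in the
#'   armed zone before the reward is delivered; 0 rewards on entry.
#' @param advance_on_passthrough Logical: if TRUE, exiting the armed zone
#'   without earning the reward also advances the arming (used by the
#'   spatial reorientation task, where passing through the reward zone
#'   activates the end zone).
#' @param valve_open Seconds a liquid-reward valve stays open.
#' @param animal_id,comment Session metadata saved with the settings.
#' @param rng_seed Integer seed for the session's random draws.
#' @return An object of class `session_config`.
#' @export
session_config <- function(zones, active_zone_ids = NULL,
                           rewarded_zone_ids = integer(0),
                           randomize_rewards = FALSE,
                           reward_type = c("none", "liquid", "stimulation"),
                           stim = stim_params(), dwell_delay = 0,
                           advance_on_passthrough = FALSE, valve_open = 0.1,
                           animal_id = "", comment = "", rng_seed = 1L) {
  reward_type <- match.arg(reward_type)
  if (!is.list(zones) || !all(vapply(zones, inherits, TRUE, "zone_spec")))
    stop("zones must be a list of zone_spec objects", call. = FALSE)
  ids <- vapply(zones, `[[`, 1L, "id")
  if (anyDuplicated(ids)) stop("zone ids must be unique", call. = FALSE)
  if (is.null(active_zone_ids)) active_zone_ids <- ids
  active_zone_ids <- as.integer(active_zone_ids)
  rewarded_zone_ids <- as.integer(rewarded_zone_ids)
  if (!all(active_zone_ids %in% ids))
    stop("active_zone_ids must reference defined zones", call. = FALSE)
  if (!all(rewarded_zone_ids %in% active_zone_ids))
    stop("every rewarded zone id must be listed in active_zone_ids",
         call. = FALSE)
  if (!is.numeric(dwell_delay) || dwell_delay < 0)
    stop("dwell_delay must be >= 0 s", call. = FALSE)
  stopifnot(inherits(stim, "stim_params"))
  names(zones) <- as.character(ids)
  structure(list(zones = zones, active_zone_ids = active_zone_ids,
                 rewarded_zone_ids = rewarded_zone_ids,
                 randomize_rewards = isTRUE(randomize_rewards),
                 reward_type = reward_type, stim = stim,
                 dwell_delay = dwell_delay,
                 advance_on_passthrough = isTRUE(advance_on_passthrough),
                 valve_open = valve_open, animal_id = animal_id,
                 comment = comment, rng_seed = as.integer(rng_seed)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session config> %d zones (%d active), %d rewarded-list entries%s, reward %s, dwell %g s\n",
              length(x$zones), length(x$active_zone_ids),
              length(x$rewarded_zone_ids),
              if (x$randomize_rewards) " (randomized)" else "",
              x$reward_type, x$dwell_delay))
  if (nzchar(x$animal_id)) cat("  animal:", x$animal_id, "\n")
  invisible(x)
}
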