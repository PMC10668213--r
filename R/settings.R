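# Settings persistence: the canonical session-configuration format is a
# schema-versioned JSON document that round-trips a session_config
# field-for-field.

SETTINGS_SCHEMA_VERSION <- "1.0"

#' Save and load session settings
#'
#' Settings files capture the complete experiment definition — zones,
#' rewarded-zone order, reward and stimulation parameters, animal ID and
#' comments — so that a protocol can be stored once and reloaded
#' identically across days. The on-disk format is canonical JSON with a
#' `schema_version` field; `load_settings()` re-validates every invariant
#' (and names the offending field on failure), so a hand-edited file
#' cannot smuggle in an inconsistent configuration.
#'
#' @param config A [session_config()].
#' @param path File path (`.json`).
#' @return `save_settings` returns `path` invisibly; `load_settings`
#'   returns the validated [session_config()].
#' @examples
#' cfg <- session_config(list(zone_spec(1, c(100, 100), 20)))
#' f <- tempfile(fileext = ".json")
#' save_settings(cfg, f)
#' identical(load_settings(f)$active_zone_ids, cfg$active_zone_ids)
#' @export
save_settings <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  zones <- lapply(config$zones, function(z)
    list(id = z$id, center = z$center, radius = z$radius,
         hysteresis = z$hysteresis,
         led_index = if (is.null(z$led_index)) NULL else z$led_index,
         role = z$role))
  doc <- list(
    schema_version = SETTINGS_SCHEMA_VERSION,
    saved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    config = list(
      zones = unname(zones),
      active_zone_ids = config$active_zone_ids,
      rewarded_zone_ids = config$rewarded_zone_ids,
      randomize_rewards = config$randomize_rewards,
      reward_type = config$reward_type,
      stim = unclass(config$stim),
      dwell_delay = config$dwell_delay,
      advance_on_passthrough = config$advance_on_passthrough,
      valve_open = config$valve_open,
      animal_id = config$animal_id,
      comment = config$comment,
      rng_seed = config$rng_seed))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_settings
#' @export
load_settings <- function(path) {
  if (!file.exists(path)) stop("settings file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, SETTINGS_SCHEMA_VERSION))
    stop(sprintf("unknown settings schema_version '%s' (expected '%s')",
                 as.character(doc$schema_version), SETTINGS_SCHEMA_VERSION),
         call. = FALSE)
  c0 <- doc$config
  zones <- lapply(c0$zones, function(z)
    zone_spec(z$id, unlist(z$center), z$radius, z$hysteresis,
              led_index = z$led_index, role = z$role))
  stim <- do.call(stim_params, c0$stim)
  # session_config() re-checks all invariants and names violations
  session_config(zones,
                 active_zone_ids = unlist(c0$active_zone_ids),
                 rewarded_zone_ids = as.integer(unlist(c0$rewarded_zone_ids)),
                 randomize_rewards = isTRUE(c0$randomize_rewards),
                 reward_type = c0$reward_type,
                 stim = stim,
                 dwell_delay = c0$dwell_delay,
                 advance_on_passthrough = isTRUE(c0$advance_on_passthrough),
                 valve_open = c0$valve_open,
                 animal_id = c0$animal_id %||% "",
                 comment = c0$comment %||% "",
                 rng_seed = c0$rng_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
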