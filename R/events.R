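#' Construct a maze event record
#'
#' Maze events are rows of a plain data frame with a fixed column set,
#' mirroring the session event log the acquisition side sees:
#' `t` (seconds), `kind`, `zone_id` (or NA), `ttl_word` (8-character
#' bit string or NA) and a free-text `detail`.
#'
#' @param t Event time in seconds.
#' @param kind One of `zone_entry`, `zone_exit`, `reward`, `stim_manual`,
#'   `stim_animal`, `next_cue`, `led_on`, `led_off`, `session_note`.
#' @param zone_id Zone number 1..32, or NA.
#' @param ttl_word A `ttl_word` or bit string, or NA.
#' @param detail Free-text annotation.
#' @return One-row data frame.
#' @keywords internal
maze_event <- function(t, kind, zone_id = NA_integer_, ttl_word = NA_character_,
                       detail = "") {
  kinds <- c("zone_entry", "zone_exit", "reward", "stim_manual", "stim_animal",
             "next_cue", "led_on", "led_off", "session_note")
  if (!kind %in% kinds) stop("unknown event kind: ", kind, call. = FALSE)
  if (inherits(ttl_word, "ttl_word")) ttl_word <- format(ttl_word)
  data.frame(t = as.numeric(t), kind = kind,
             zone_id = as.integer(zone_id),
             ttl_word = as.character(ttl_word),
             detail = as.character(detail),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(t = numeric(0), kind = character(0), zone_id = integer(0),
             ttl_word = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

bind_events <- function(...) {
  evs <- list(...)
  evs <- evs[vapply(evs, NROW, 1L) > 0L]
  if (length(evs) == 0L) return(empty_events())
  do.call(rbind, evs)
}

#' Read and write session event logs
#'
#' Event logs are UTF-8 CSV files with a header row and columns
#' `t,kind,zone_id,ttl_word,detail`. Timestamps are written as decimal
#' seconds with 6 digits after the point so logs are byte-stable across
#' platforms.
#'
#' @param events Event data frame (as produced by the task engine).
#' @param path File path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the event data frame.
#' @export
write_event_log <- function(events, path) {
  out <- events
  out$t <- sprintf("%.6f", out$t)
  utils::write.csv(out, path, row.names = FALSE,
                   quote = which(names(out) %in% c("kind", "ttl_word", "detail")),
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(t = "numeric", kind = "character",
                                       zone_id = "integer",
                                       ttl_word = "character",
                                       detail = "character"),
                        na.strings = "")
  ev$detail[is.na(ev$detail)] <- ""
  ev
}

#' Read and write tracking sample logs
#'
#' Sample streams are CSV files `t,x,y,angle,valid` with one row per
#' tracking observation; `valid` is 0/1, `angle` may be empty when no
#' head-direction fix exists.
#'
#' @param samples Sample data frame with columns `t,x,y,angle,valid`.
#' @param path File path.
#' @export
write_sample_log <- function(samples, path) {
  out <- samples[c("t", "x", "y", "angle", "valid")]
  out$t <- sprintf("%.6f", out$t)
  out$x <- sprintf("%.6f", out$x)
  out$y <- sprintf("%.6f", out$y)
  out$angle <- ifelse(is.na(samples$angle), "", sprintf("%.6f", samples$angle))
  out$valid <- as.integer(samples$valid)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sample_log
#' @export
read_sample_log <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  data.frame(t = as.numeric(s$t), x = as.numeric(s$x), y = as.numeric(s$y),
             angle = as.numeric(s$angle), valid = as.integer(s$valid) == 1L)
}

#' Write a TTL change log
#'
#' Timed digital line changes, CSV `t,bank,line,level`.
#'
#' @param changes Data frame `t,bank,line,level`.
#' @param path File path.
#' @export
write_ttl_log <- function(changes, path) {
  out <- changes
  out$t <- sprintf("%.6f", out$t)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
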