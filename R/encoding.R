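#' Binary TTL encoding of maze events
#'
#' Zone entries and exits are announced to the acquisition system as a
#' binary word on a TTL output bank, so that every maze event is
#' timestamped alongside the neural data. The word layout is fixed and
#' bit-exact:
#'
#' * lines 0-5: the zone number (1-32) as a 6-bit big-endian code
#'   (line 0 carries the most significant bit),
#' * line 6: direction flag, 1 = entry, 0 = exit,
#' * line 7: strobe, pulsed high for one engine tick per event.
#'
#' The string form concatenates lines 0..7, e.g. zone 1 entry is
#' `"00000111"`.
#'
#' @param zone_id Integer 1..32.
#' @param direction `"entry"` or `"exit"`.
#' @return A `ttl_word`: integer 0/1 vector of length 8 (lines 0..7).
#' @examples
#' encode_zone_event(5, "entry")
#' decode_zone_event(encode_zone_event(32, "exit"))
#' @export
encode_zone_event <- function(zone_id, direction = c("entry", "exit")) {
  direction <- match.arg(direction)
  zone_id <- as.integer(zone_id)
  if (length(zone_id) != 1L || is.na(zone_id) || zone_id < 1L || zone_id > 32L)
    stop("zone_id must be in 1..32", call. = FALSE)
  data <- as.integer(intToBits(zone_id))[6:1]  # big-endian 6 bits
  word <- c(data, if (direction == "entry") 1L else 0L, 1L)
  structure(word, class = "ttl_word", meaning = "zone_code")
}

#' @rdname encode_zone_event
#' @param word A `ttl_word` (or its 0/1 vector / 8-character string form)
#'   with the zone-code layout.
#' @return For `decode_zone_event`, a list with `zone_id` and `direction`.
#' @export
decode_zone_event <- function(word) {
  if (is.character(word) && length(word) == 1L && nchar(word) == 8L)
    word <- as.integer(strsplit(word, "")[[1]])
  word <- as.integer(word)
  if (length(word) != 8L || anyNA(word) || !all(word %in% 0:1))
    stop("TTL word must be 8 binary lines", call. = FALSE)
  zone_id <- sum(word[1:6] * 2L^(5:0))
  if (zone_id < 1L || zone_id > 32L)
    stop(sprintf("invalid zone code %d in TTL word", zone_id), call. = FALSE)
  list(zone_id = as.integer(zone_id),
       direction = if (word[7] == 1L) "entry" else "exit")
}

#' @export
format.ttl_word <- function(x, ...) paste(unclass(x), collapse = "")

#' @export
print.ttl_word <- function(x, ...) {
  cat(sprintf("<ttl word> %s (lines 0..7)\n", format(x)))
  invisible(x)
}

#' Virtual digital-output banks
#'
#' The platform drives its LEDs, event lines and reward valves through two
#' USB digital I/O modules: a 48-bit LED/event bank and a 16-bit valve
#' bank. `output_bank()` creates an all-low virtual bank whose line state
#' is a pure function of the timed change list applied to it.
#'
#' @param name `"led_event_bank_48"` or `"valve_bank_16"`.
#' @return An `output_bank`: list with `name`, `width`, and `lines`
#'   (integer 0/1 vector, line indices 0..width-1).
#' @export
output_bank <- function(name = c("led_event_bank_48", "valve_bank_16")) {
  name <- match.arg(name)
  width <- if (name == "led_event_bank_48") 48L else 16L
  structure(list(name = name, width = width, lines = integer(width)),
            class = "output_bank")
}

#' @export
print.output_bank <- function(x, ...) {
  cat(sprintf("<output bank %s> %d lines, %d high\n",
              x$name, x$width, sum(x$lines)))
  invisible(x)
}

#' Set a cue LED line, logging only real changes
#'
#' LED status changes are recorded and timestamped; writing the value a
#' line already holds emits no event (the hardware log only records
#' changes).
#'
#' @param bank An `output_bank` of type `led_event_bank_48`.
#' @param led_index LED number 1..32.
#' @param on Logical, desired state.
#' @param t Time in seconds for the emitted event.
#' @return List with the updated `bank` and `events`, a data frame of
#'   zero or one maze events (`t, kind, zone_id, ttl_word, detail`).
#' @export
set_led <- function(bank, led_index, on, t = 0) {
  stopifnot(inherits(bank, "output_bank"))
  led_index <- as.integer(led_index)
  if (is.na(led_index) || led_index < 1L || led_index > min(32L, bank$width))
    stop("led_index out of range for this bank", call. = FALSE)
  on <- as.integer(isTRUE(on))
  line <- led_index - 1L  # LED k drives line k-1
  if (bank$lines[line + 1L] == on) {
    return(list(bank = bank, events = empty_events()))
  }
  bank$lines[line + 1L] <- on
  ev <- maze_event(t = t, kind = if (on == 1L) "led_on" else "led_off",
                   zone_id = led_index,
                   detail = sprintf("line %d -> %d", line, on))
  list(bank = bank, events = ev)
}

#' Pulse a reward valve
#'
#' Opens a solenoid pinch valve for `open_duration` seconds: one rising
#' and one falling change on the valve's line of the 16-bit valve bank.
#'
#' @param bank An `output_bank` of type `valve_bank_16`.
#' @param valve_index Valve number (1..`n_valves`).
#' @param open_duration Seconds the valve stays open, > 0.
#' @param t Pulse start time in seconds.
#' @param n_valves Number of valves wired on the bank (default 8, the
#'   published build).
#' @return Data frame of timed line changes: `t, bank, line, level`.
#' @export
pulse_valve <- function(bank, valve_index, open_duration = 0.1, t = 0,
                        n_valves = 8L) {
  stopifnot(inherits(bank, "output_bank"))
  valve_index <- as.integer(valve_index)
  if (is.na(valve_index) || valve_index < 1L || valve_index > n_valves)
    stop(sprintf("valve_index must be in 1..%d", n_valves), call. = FALSE)
  if (!is.numeric(open_duration) || open_duration <= 0)
    stop("open_duration must be > 0", call. = FALSE)
  line <- valve_index - 1L
  data.frame(t = c(t, t + open_duration), bank = bank$name,
             line = line, level = c(1L, 0L))
}

#' Replay a timed change list onto a bank
#'
#' Bank state is a pure function of the ordered change list; this applies
#' the changes and returns the final line state.
#'
#' @param bank An `output_bank`.
#' @param changes Data frame `t, bank, line, level` (as written by
#'   [pulse_valve()] or the TTL change log).
#' @return The updated bank.
#' @export
apply_changes <- function(bank, changes) {
  stopifnot(inherits(bank, "output_bank"))
  if (nrow(changes) == 0L) return(bank)
  changes <- changes[order(changes$t), , drop = FALSE]
  if (any(changes$line < 0L | changes$line >= bank$width))
    stop("line index outside bank width", call. = FALSE)
  for (i in seq_len(nrow(changes)))
    bank$lines[changes$line[i] + 1L] <- as.integer(changes$level[i])
  bank
}
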