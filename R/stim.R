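# Pulse-train construction and triggering ("Stim Trigger").

#' Build a stimulation pulse train
#'
#' Constructs the unipolar TTL gate train from [stim_params()]: the train
#' has `n = floor(frequency * duration)` cycles of length `1/frequency`
#' seconds (a partial trailing cycle is dropped — the number of stimuli
#' depends on duration and frequency), and each cycle is high for
#' `duty_cycle/100` of its length starting at cycle onset. Adjacent
#' touching high intervals (duty cycle 100%) coalesce into one span.
#'
#' @param p A [stim_params()].
#' @return A `pulse_train`: data frame with columns `t_on`, `t_off`
#'   (seconds), attributes `total_duration` and `params`.
#' @examples
#' build_pulse_train(stim_params(100, 0.5, 50))
#' @export
build_pulse_train <- function(p) {
  stopifnot(inherits(p, "stim_params"))
  n <- floor(p$frequency * p$duration)
  if (n < 1) stop("frequency * duration must be >= 1", call. = FALSE)
  cycle <- 1 / p$frequency
  high <- (p$duty_cycle / 100) * cycle
  t_on <- (seq_len(n) - 1) * cycle
  t_off <- t_on + high
  # coalesce touching intervals (duty 100%: t_off[k] == t_on[k+1])
  keep_on <- c(TRUE, t_on[-1] > t_off[-n] + 1e-12)
  starts <- t_on[keep_on]
  ends <- t_off[c(which(keep_on)[-1] - 1L, n)]
  train <- data.frame(t_on = starts, t_off = ends)
  structure(train, class = c("pulse_train", "data.frame"),
            total_duration = p$duration, n_cycles = n, params = p)
}

#' @export
print.pulse_train <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<pulse train> %d high interval(s), %d cycle(s), %.6f s high total over %g s\n",
              nrow(x), attr(x, "n_cycles"), sum(x$t_off - x$t_on),
              attr(x, "total_duration")))
  if (!is.null(p)) print(p)
  invisible(x)
}

#' Total high time of a pulse train
#'
#' @param train A `pulse_train`.
#' @return Seconds of high output (sum of interval lengths).
#' @export
train_high_time <- function(train) {
  sum(train$t_off - train$t_on)
}

#' Schedule stimulations from a sampled TTL input line
#'
#' Scans a time-ordered 0/1 line history for the configured trigger edge
#' and schedules one pulse train per edge. Edges arriving while a train is
#' still running are ignored (the lockout equals the train duration), so
#' onsets are never closer together than `duration`.
#'
#' @param line_history Data frame with columns `t` (seconds, increasing)
#'   and `level` (0/1): the sampled external TTL input.
#' @param p A [stim_params()]; `trigger_edge` selects rising or falling.
#' @return Numeric vector of stimulation onset times (seconds).
#' @export
on_trigger <- function(line_history, p) {
  stopifnot(inherits(p, "stim_params"))
  lv <- as.integer(line_history$level)
  t <- as.numeric(line_history$t)
  if (length(lv) < 2L) return(numeric(0))
  d <- diff(lv)
  idx <- if (p$trigger_edge == "rising") which(d == 1L) else which(d == -1L)
  edge_times <- t[idx + 1L]
  onsets <- numeric(0)
  lockout_until <- -Inf
  for (et in edge_times) {
    if (et >= lockout_until) {
      onsets <- c(onsets, et)
      lockout_until <- et + p$duration
    }
  }
  onsets
}

#' Stimulation counters
#'
#' Running tallies of manually triggered and animal-triggered
#' stimulations; "Clear Stim" resets both.
#'
#' @param counters A list as returned by `stim_counters()` or
#'   `record_stim()`.
#' @param source `"manual"` or `"animal"`.
#' @return Updated counter list with elements `manual` and `animal`.
#' @export
stim_counters <- function() list(manual = 0L, animal = 0L)

#' @rdname stim_counters
#' @export
record_stim <- function(counters, source = c("manual", "animal")) {
  source <- match.arg(source)
  counters[[source]] <- counters[[source]] + 1L
  counters
}

#' @rdname stim_counters
#' @export
clear_stim <- function(counters) {
  counters$manual <- 0L
  counters$animal <- 0L
  counters
}

#' Convert a unipolar train to a charge-balanced bipolar waveform
#'
#' Models the stimulus isolator's conversion of the TTL gate into a
#' biphasic stimulus: each high interval is split into an initial positive
#' half-phase and an equal negative half-phase, so the signed integral of
#' the waveform is zero (charge balance).
#'
#' @param train A `pulse_train`.
#' @return Data frame `t_start, t_end, sign` (+1 then -1 per pulse).
#' @export
to_bipolar <- function(train) {
  if (nrow(train) == 0L)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      sign = numeric(0)))
  mid <- (train$t_on + train$t_off) / 2
  data.frame(
    t_start = as.vector(rbind(train$t_on, mid)),
    t_end = as.vector(rbind(mid, train$t_off)),
    sign = rep(c(1, -1), times = nrow(train))
  )
}
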