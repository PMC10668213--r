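# Synthetic animal + camera: waypoint-pursuit trajectories, frame
# rendering, tracking dropouts, and presets for the platform's published
# task configurations. The agent dynamics are deliberately simple -- the
# simulator exercises the engine, it does not model rodent behavior.

#' Define a simulated agent
#'
#' The agent pursues a list of waypoints at constant speed along straight
#' segments, pauses `dwell_at_waypoint` seconds at each waypoint, and
#' reports its position with Gaussian jitter. Each sample is independently
#' marked invalid (lost tracking) with probability `dropout_prob`.
#'
#' @param waypoints Numeric matrix (n x 2) or list of `(x, y)` points the
#'   agent visits in order; the first is its start position.
#' @param speed Locomotion speed, px/s, > 0.
#' @param jitter_sd SD of Gaussian positional jitter, px.
#' @param dwell_at_waypoint Pause at each waypoint, seconds.
#' @param dropout_prob Per-sample probability of a lost-tracking sample,
#'   in `[0, 1)`.
#' @param seed Integer RNG seed; the same seed gives an identical stream.
#' @return An object of class `agent_model`.
#' @export
agent_model <- function(waypoints, speed = 80, jitter_sd = 0,
                        dwell_at_waypoint = 0, dropout_prob = 0, seed = 1L) {
  if (is.list(waypoints)) waypoints <- do.call(rbind, waypoints)
  waypoints <- matrix(as.numeric(waypoints), ncol = 2)
  if (nrow(waypoints) < 1L || anyNA(waypoints))
    stop("waypoints must be a non-empty list of (x, y) points", call. = FALSE)
  if (!is.numeric(speed) || speed <= 0) stop("speed must be > 0", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)", call. = FALSE)
  structure(list(waypoints = waypoints, speed = speed, jitter_sd = jitter_sd,
                 dwell_at_waypoint = dwell_at_waypoint,
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "agent_model")
}

#' Simulate a tracking-sample stream
#'
#' Piecewise-linear waypoint pursuit at the agent's speed with dwell
#' pauses, sampled at `rate` samples per second from `1/rate` to `t_max`.
#' Reported positions add the agent's jitter; `valid` is FALSE for
#' dropout samples. The reported heading is the instantaneous direction of
#' motion (degrees, math convention; held through pauses).
#'
#' @param agent An [agent_model()].
#' @param rate Sampling rate, samples/s, > 0.
#' @param t_max Stream duration, seconds.
#' @return Data frame `t, x, y, angle, valid` with strictly increasing `t`.
#' @export
simulate_trajectory <- function(agent, rate = 30, t_max = 10) {
  stopifnot(inherits(agent, "agent_model"))
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  n <- floor(t_max * rate)
  if (n < 1L) stop("t_max too short for the sampling rate", call. = FALSE)
  dt0 <- 1 / rate
  wp <- agent$waypoints
  pos <- wp[1L, ]
  wp_idx <- 2L
  dwell_left <- 0
  heading <- 0
  xs <- ys <- hs <- numeric(n)
  for (i in seq_len(n)) {
    dt <- dt0
    while (dt > 1e-12) {
      if (dwell_left > 1e-12) {
        used <- min(dwell_left, dt)
        dwell_left <- dwell_left - used
        dt <- dt - used
      } else if (wp_idx > nrow(wp)) {
        break  # route finished: rest at the last waypoint
      } else {
        d <- wp[wp_idx, ] - pos
        dist <- sqrt(sum(d^2))
        if (dist < 1e-12) {
          wp_idx <- wp_idx + 1L
          dwell_left <- agent$dwell_at_waypoint
        } else {
          heading <- (atan2(-d[2], d[1]) * 180 / pi) %% 360
          reach <- agent$speed * dt
          if (dist <= reach) {
            pos <- wp[wp_idx, ]
            dt <- dt - dist / agent$speed
            wp_idx <- wp_idx + 1L
            dwell_left <- agent$dwell_at_waypoint
          } else {
            pos <- pos + d / dist * reach
            dt <- 0
          }
        }
      }
    }
    xs[i] <- pos[1]; ys[i] <- pos[2]; hs[i] <- heading
  }
  noise <- with_rng_state(rng_state_from_seed(agent$seed), function() {
    list(jx = stats::rnorm(n, 0, agent$jitter_sd),
         jy = stats::rnorm(n, 0, agent$jitter_sd),
         drop = stats::runif(n) < agent$dropout_prob)
  })$value
  data.frame(t = seq_len(n) * dt0,
             x = xs + noise$jx, y = ys + noise$jy,
             angle = hs, valid = !noise$drop)
}

#' Describe a synthetic camera scene
#'
#' @param layout A [perimeter_layout()] giving the wall-LED positions.
#' @param frame_size `(W, H)` in pixels.
#' @param background,blob_intensity,led_intensity Grayscale levels 0-255
#'   for the dark platform, the animal blob and a lit LED.
#' @param blob_radius,led_radius Disk radii in pixels.
#' @param marker_sep Separation of the two head-direction markers, px.
#' @return A list of class `sim_scene`.
#' @export
sim_scene <- function(layout, frame_size = c(480, 480), background = 20,
                      blob_intensity = 200, led_intensity = 255,
                      blob_radius = 6, led_radius = 2, marker_sep = 14) {
  stopifnot(inherits(layout, "perimeter_layout"))
  structure(list(layout = layout, frame_size = frame_size,
                 background = background, blob_intensity = blob_intensity,
                 led_intensity = led_intensity, blob_radius = blob_radius,
                 led_radius = led_radius, marker_sep = marker_sep),
            class = "sim_scene")
}

# Paint a filled disk onto a matrix (in place value update, returned).
draw_disk <- function(m, cx, cy, r, value) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  if (length(rows) == 0L || length(cols) == 0L) return(m)
  dy2 <- (rows - cy)^2
  dx2 <- (cols - cx)^2
  mask <- outer(dy2, dx2, "+") <= r^2
  sub <- m[rows, cols, drop = FALSE]
  sub[mask] <- value
  m[rows, cols] <- sub
  m
}

#' Render one synthetic camera frame
#'
#' Dark platform background, lit wall LEDs as small bright dots at their
#' perimeter positions, and the animal as a bright disk (single-marker
#' mode) or two colored disks straddling its position along the heading
#' (two-marker mode: front marker in channel 1, rear in channel 3).
#' Invalid samples are rendered without the animal.
#'
#' @param scene A [sim_scene()].
#' @param sample One-row data frame / list `x, y, angle, valid`, or `NULL`
#'   for an empty platform.
#' @param leds_on Integer vector of lit LED indices.
#' @param two_marker Logical: render front/rear head markers in separate
#'   color channels.
#' @return Grayscale matrix, or H x W x 3 array in two-marker mode.
#' @export
render_frame <- function(scene, sample = NULL, leds_on = integer(0),
                         two_marker = FALSE) {
  stopifnot(inherits(scene, "sim_scene"))
  W <- scene$frame_size[1]; H <- scene$frame_size[2]
  base <- matrix(scene$background, nrow = H, ncol = W)
  for (k in leds_on) {
    p <- scene$layout$positions[k, ]
    base <- draw_disk(base, p[1], p[2], scene$led_radius, scene$led_intensity)
  }
  show_animal <- !is.null(sample) && isTRUE(as.logical(sample$valid))
  if (!two_marker) {
    if (show_animal)
      base <- draw_disk(base, sample$x, sample$y, scene$blob_radius,
                        scene$blob_intensity)
    return(base)
  }
  frame <- array(0, dim = c(H, W, 3))
  frame[, , 1] <- base; frame[, , 2] <- base; frame[, , 3] <- base
  if (show_animal) {
    h <- as.numeric(sample$angle) * pi / 180
    off <- scene$marker_sep / 2 * c(cos(h), -sin(h))  # y-down pixels
    fr <- c(sample$x, sample$y) + off
    re <- c(sample$x, sample$y) - off
    frame[, , 1] <- draw_disk(frame[, , 1], fr[1], fr[2], scene$blob_radius,
                              scene$blob_intensity)
    frame[, , 3] <- draw_disk(frame[, , 3], re[1], re[2], scene$blob_radius,
                              scene$blob_intensity)
  }
  frame
}

#' @rdname render_frame
#' @param samples Data frame of tracking samples (`x, y, angle, valid`).
#' @return `render_frames` returns a list of frames, one per sample row.
#' @export
render_frames <- function(samples, scene, leds_on = integer(0),
                          two_marker = FALSE) {
  lapply(seq_len(nrow(samples)),
         function(i) render_frame(scene, samples[i, ], leds_on, two_marker))
}
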