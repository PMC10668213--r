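#' Define a circular maze zone
#'
#' A zone is a closed disk in camera-pixel coordinates (origin top-left,
#' x rightward, y downward). Zones record maze events when the animal
#' crosses them and, optionally, trigger rewards. Entry hysteresis
#' temporarily enlarges the effective radius while the animal is inside,
#' so that small head movements near the boundary are not logged as
#' spurious exits.
#'
#' @param id Integer zone number in 1..32; unique within a session.
#' @param center Numeric length-2, zone center `(x, y)` in pixels.
#' @param radius Zone radius in pixels, > 0.
#' @param hysteresis Dimensionless factor >= 1 by which the radius is
#'   temporarily multiplied while the animal is inside the zone.
#' @param led_index Optional integer 1..32: the perimeter cue LED
#'   associated with this zone.
#' @param role `"tracked"` (timestamp only) or `"rewarded"` (eligible to
#'   deliver a reward when armed).
#' @return An object of class `zone_spec`.
#' @examples
#' z <- zone_spec(1, c(100, 100), radius = 20)
#' occupancy_test(z, c(115, 100), currently_inside = FALSE)
#' @export
zone_spec <- function(id, center, radius, hysteresis = 1.5,
                      led_index = NULL, role = c("tracked", "rewarded")) {
  role <- match.arg(role)
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 32L)
    stop("zone id must be a single integer in 1..32", call. = FALSE)
  if (length(center) != 2L || !is.numeric(center) || anyNA(center))
    stop("center must be numeric (x, y)", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("radius must be a positive number of pixels", call. = FALSE)
  if (!is.numeric(hysteresis) || length(hysteresis) != 1L || hysteresis < 1)
    stop("hysteresis factor must be >= 1", call. = FALSE)
  if (length(led_index) == 0L) led_index <- NULL
  if (!is.null(led_index)) {
    led_index <- as.integer(led_index)
    if (length(led_index) != 1L || is.na(led_index) ||
        led_index < 1L || led_index > 32L)
      stop("led_index must be in 1..32", call. = FALSE)
  }
  structure(list(id = id, center = as.numeric(center), radius = radius,
                 hysteresis = hysteresis, led_index = led_index, role = role),
            class = "zone_spec")
}

#' @export
print.zone_spec <- function(x, ...) {
  cat(sprintf("<zone %d> center (%.1f, %.1f) r=%.1f px, hysteresis %.2f, role %s%s\n",
              x$id, x$center[1], x$center[2], x$radius, x$hysteresis, x$role,
              if (is.null(x$led_index)) "" else sprintf(", LED %d", x$led_index)))
  invisible(x)
}

#' Evenly spaced perimeter layout
#'
#' Places `n` positions on a ring of radius `ring_radius` around `center`,
#' mirroring the platform's ring of evenly spaced wall LEDs. Position `k`
#' sits at angle `start_angle + (k - 1) * 360 / n` degrees. Angles follow
#' the mathematical convention: 0 degrees along +x, increasing
#' counterclockwise in a y-up frame. Because image pixels have y pointing
#' down, a renderer drawing these positions sees the angular order run
#' clockwise on screen; the stored coordinates are
#' `center + r * (cos(theta), sin(theta))` either way.
#'
#' @param n Number of positions (default 32, the platform's complement).
#' @param center Ring center `(x, y)` in pixels.
#' @param ring_radius Ring radius in pixels, > 0.
#' @param start_angle Angle of position 1 in degrees.
#' @return An object of class `perimeter_layout` with a `positions`
#'   matrix (`n` rows, columns `x`, `y`).
#' @examples
#' lay <- perimeter_layout(32, center = c(240, 240), ring_radius = 200)
#' head(lay$positions)
#' @export
perimeter_layout <- function(n = 32, center = c(0, 0), ring_radius = 1,
                             start_angle = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.numeric(ring_radius) || ring_radius <= 0)
    stop("ring_radius must be > 0", call. = FALSE)
  theta <- (start_angle + (seq_len(n) - 1) * 360 / n) * pi / 180
  pos <- cbind(x = center[1] + ring_radius * cos(theta),
               y = center[2] + ring_radius * sin(theta))
  structure(list(n_positions = n, center = as.numeric(center),
                 ring_radius = ring_radius, start_angle = start_angle,
                 positions = pos),
            class = "perimeter_layout")
}

#' @export
print.perimeter_layout <- function(x, ...) {
  cat(sprintf("<perimeter layout> %d positions, center (%.1f, %.1f), ring radius %.1f px\n",
              x$n_positions, x$center[1], x$center[2], x$ring_radius))
  invisible(x)
}

#' Zone occupancy test with entry hysteresis
#'
#' A point is inside a zone when its distance to the center is at most the
#' effective radius; the boundary counts as inside. While the animal is
#' already inside (`currently_inside = TRUE`) the effective radius is
#' `radius * hysteresis`, so an animal must move further out to register
#' an exit than it had to move in to register an entry.
#'
#' @param zone A [zone_spec()].
#' @param p Numeric `(x, y)` position in pixels.
#' @param currently_inside Logical: is the animal currently flagged inside
#'   this zone?
#' @return Logical.
#' @export
occupancy_test <- function(zone, p, currently_inside = FALSE) {
  stopifnot(inherits(zone, "zone_spec"))
  d <- sqrt(sum((as.numeric(p) - zone$center)^2))
  r_eff <- if (isTRUE(currently_inside)) zone$radius * zone$hysteresis else zone$radius
  d <= r_eff
}

#' Map perimeter LEDs to reward spouts
#'
#' The platform places one liquid-reward spout over every `leds_per_spout`-th
#' LED (every fourth on the published build, giving eight spouts for 32
#' LEDs). Spouts sit at LED indices `1, 1 + leds_per_spout, ...`; each LED
#' maps to the spout nearest along the ring, ties resolved toward the
#' lower-indexed spout.
#'
#' @param layout A [perimeter_layout()].
#' @param leds_per_spout Spacing between spouts in LED positions; must
#'   divide the number of positions.
#' @return Named integer vector: for each LED index `1..n`, the spout
#'   number (`1..n/leds_per_spout`) serving it. The LED indices carrying
#'   spouts are in `attr(, "spout_leds")`.
#' @examples
#' led_to_spout_map(perimeter_layout(32, c(0, 0), 100), 4)
#' @export
led_to_spout_map <- function(layout, leds_per_spout) {
  stopifnot(inherits(layout, "perimeter_layout"))
  n <- layout$n_positions
  s <- as.integer(leds_per_spout)
  if (is.na(s) || s < 1L || n %% s != 0L)
    stop("leds_per_spout must divide the number of perimeter positions",
         call. = FALSE)
  spout_leds <- seq(1L, n, by = s)
  # circular index distance from each LED to each spout LED
  map <- vapply(seq_len(n), function(led) {
    d <- abs(led - spout_leds)
    d <- pmin(d, n - d)
    which.min(d)  # ties -> lower spout index
  }, integer(1))
  names(map) <- seq_len(n)
  attr(map, "spout_leds") <- spout_leds
  map
}
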