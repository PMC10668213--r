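# Blob-tracking pipeline: threshold -> connected regions -> largest region
# -> centroid -> normalization; two-marker head direction; sequential-LED
# auto-calibration; streaming position messages.
#
# Frames are numeric matrices (rows = y, columns = x, values 0-255) or
# H x W x 3 arrays for color. A pixel at matrix position [r, c] has
# image coordinates x = c, y = r (1-based pixel centers).

#' Convert a frame to grayscale
#'
#' Color frames (H x W x 3 arrays) are averaged across channels; grayscale
#' matrices pass through.
#'
#' @param f Frame: numeric matrix or H x W x 3 array, intensities 0-255.
#' @return Numeric matrix.
#' @export
to_gray <- function(f) {
  if (is.matrix(f)) return(f)
  if (length(dim(f)) == 3L) return((f[, , 1] + f[, , 2] + f[, , 3]) / 3)
  stop("frame must be a matrix or an H x W x 3 array", call. = FALSE)
}

#' Threshold a frame
#'
#' Pixels with intensity `>= T` become 1, the rest 0. Color input is
#' converted to grayscale first.
#'
#' @param f Frame (matrix or H x W x 3 array), intensities 0-255.
#' @param T Threshold intensity in 0-255.
#' @return Binary (0/1) integer matrix.
#' @export
threshold_frame <- function(f, T) {
  g <- to_gray(f)
  b <- matrix(0L, nrow(g), ncol(g))
  b[g >= T] <- 1L
  b
}

#' Find 8-connected regions in a binary frame
#'
#' Labels every 8-connected component of foreground (1) pixels and returns
#' each component's area and plain (unweighted) binary centroid in image
#' coordinates (x = column, y = row).
#'
#' @param b Binary 0/1 matrix.
#' @return Data frame with columns `area`, `x`, `y`; zero rows for a blank
#'   frame.
#' @export
find_regions <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  fg <- which(b == 1L)
  out <- data.frame(area = integer(0), x = numeric(0), y = numeric(0))
  if (length(fg) == 0L) return(out)
  label <- integer(nr * nc)  # 0 = background / unvisited
  # 8-neighborhood offsets in linear (column-major) indexing
  areas <- integer(0); cxs <- numeric(0); cys <- numeric(0)
  next_label <- 0L
  stack <- integer(length(fg))
  for (seed in fg) {
    if (label[seed] != 0L) next
    next_label <- next_label + 1L
    top <- 1L
    stack[1L] <- seed
    label[seed] <- next_label
    area <- 0L; sx <- 0; sy <- 0
    while (top > 0L) {
      idx <- stack[top]; top <- top - 1L
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      area <- area + 1L; sx <- sx + c; sy <- sy + r
      for (dc in -1:1) {
        cc <- c + dc
        if (cc < 1L || cc > nc) next
        base <- (cc - 1L) * nr
        for (dr in -1:1) {
          rr <- r + dr
          if (rr < 1L || rr > nr) next
          nidx <- base + rr
          if (b[nidx] == 1L && label[nidx] == 0L) {
            label[nidx] <- next_label
            top <- top + 1L
            stack[top] <- nidx
          }
        }
      }
    }
    areas <- c(areas, area); cxs <- c(cxs, sx / area); cys <- c(cys, sy / area)
  }
  data.frame(area = areas, x = cxs, y = cys)
}

#' Select the largest region
#'
#' Picks the region with the greatest area, after discarding regions
#' smaller than `min_area` (a noise floor). Ties are broken
#' deterministically toward the smallest centroid `y`, then smallest `x`.
#'
#' @param regions Data frame from [find_regions()].
#' @param min_area Minimum pixel area for a region to be considered
#'   (default 5, rejecting single-pixel noise).
#' @return One-row data frame (`area, x, y`), or `NULL` when no region
#'   qualifies (the sample should then be flagged invalid).
#' @export
largest_region <- function(regions, min_area = 5) {
  if (is.null(regions) || nrow(regions) == 0L) return(NULL)
  keep <- regions[regions$area >= min_area, , drop = FALSE]
  if (nrow(keep) == 0L) return(NULL)
  ord <- order(-keep$area, keep$y, keep$x)
  keep[ord[1L], , drop = FALSE]
}

#' Normalize a pixel position to the unit square
#'
#' Divides by the frame size so downstream consumers are independent of
#' camera resolution. Out-of-frame points are clamped to `[0, 1]` with a
#' warning.
#'
#' @param p Numeric `(x, y)` in pixels.
#' @param frame_size `(W, H)` in pixels.
#' @return Numeric `(x_norm, y_norm)` in `[0, 1]`.
#' @export
normalize_position <- function(p, frame_size) {
  xy <- as.numeric(p) / as.numeric(frame_size)
  if (any(xy < 0 | xy > 1)) {
    warning("position outside frame; clamped to [0, 1]", call. = FALSE)
    xy <- pmin(pmax(xy, 0), 1)
  }
  xy
}

#' @rdname normalize_position
#' @param pn Normalized `(x_norm, y_norm)`.
#' @export
denormalize_position <- function(pn, frame_size) {
  as.numeric(pn) * as.numeric(frame_size)
}

#' Head direction from two tracking markers
#'
#' Computes the heading of the rear-to-front marker vector in degrees,
#' `[0, 360)`, with 0 along +x and angles increasing counterclockwise in a
#' y-up mathematical frame (image y points down, hence the internal sign
#' flip). With a missing or coincident marker the heading cannot be
#' determined and is reported as 0 degrees with `single_marker = TRUE`,
#' matching the tracker's behavior when two-color tracking is not
#' available.
#'
#' @param front,rear Marker centroids `(x, y)` in pixels; `NULL`/NA marks a
#'   missing marker.
#' @return List with `angle` (degrees) and `single_marker` (logical flag).
#' @export
head_direction <- function(front, rear) {
  bad <- function(p) is.null(p) || anyNA(p) || length(p) != 2L
  if (bad(front) || bad(rear))
    return(list(angle = 0, single_marker = TRUE))
  dx <- front[1] - rear[1]
  dy <- front[2] - rear[2]
  if (dx == 0 && dy == 0)
    return(list(angle = 0, single_marker = TRUE))
  ang <- atan2(-dy, dx) * 180 / pi  # y-down pixels -> y-up math frame
  list(angle = ang %% 360, single_marker = FALSE)
}

#' Track the animal in one frame
#'
#' Runs the full single-marker pipeline: threshold, connected regions,
#' largest region, centroid. Returns an invalid sample when no region
#' clears the noise floor.
#'
#' @param f Frame (matrix or color array).
#' @param T Threshold intensity.
#' @param min_area Noise floor for [largest_region()].
#' @param t Sample timestamp (seconds).
#' @return One-row data frame `t, x, y, angle, valid` (angle is NA here;
#'   see [head_direction()] for two-marker tracking).
#' @export
track_frame <- function(f, T, min_area = 5, t = NA_real_) {
  reg <- largest_region(find_regions(threshold_frame(f, T)), min_area)
  if (is.null(reg))
    return(data.frame(t = t, x = NA_real_, y = NA_real_, angle = NA_real_,
                      valid = FALSE))
  data.frame(t = t, x = reg$x, y = reg$y, angle = NA_real_, valid = TRUE)
}

# Per-pixel median of a list of equally sized grayscale frames.
# Vectorized closed forms for 1-3 frames (the common detection windows);
# larger stacks fall back to a row-sorted matrix.
median_frames <- function(frames) {
  k <- length(frames)
  if (k == 1L) return(frames[[1L]])
  if (k == 2L) return((frames[[1L]] + frames[[2L]]) / 2)
  if (k == 3L) {
    a <- frames[[1L]]; b <- frames[[2L]]; c <- frames[[3L]]
    return(a + b + c - pmax(a, pmax(b, c)) - pmin(a, pmin(b, c)))
  }
  m <- matrix(unlist(frames), ncol = k)
  med <- apply(m, 1L, stats::median)
  matrix(med, nrow = nrow(frames[[1L]]), ncol = ncol(frames[[1L]]))
}

#' Auto-calibrate zone centers from sequentially flashed LEDs
#'
#' Reproduces the platform's automatic calibration: perimeter LEDs are lit
#' one at a time in index order; for each LED the camera frames are
#' thresholded and the bright region's centroid is recorded as that zone's
#' center. Per LED the detection uses the per-pixel median over
#' `frames_per_led` grabbed frames to suppress single-frame noise.
#'
#' @param set_led_fn Function `(led_index, on)` driving the (virtual) LED
#'   bank.
#' @param grab_frame_fn Function `()` returning the current camera frame.
#' @param n_leds Number of LEDs / zones to calibrate (default 32).
#' @param T Threshold intensity separating a lit LED from the dark
#'   platform.
#' @param frames_per_led Frames grabbed (and median-combined) per LED.
#' @param min_area Noise floor (pixels) below which a region is ignored.
#' @return `n_leds` x 2 matrix of zone centers (columns `x`, `y`), row k
#'   for LED k.
#' @export
autocalibrate <- function(set_led_fn, grab_frame_fn, n_leds = 32, T = 128,
                          frames_per_led = 3, min_area = 2) {
  n_leds <- as.integer(n_leds)
  if (is.na(n_leds) || n_leds < 1L) stop("n_leds must be >= 1", call. = FALSE)
  centers <- matrix(NA_real_, n_leds, 2, dimnames = list(NULL, c("x", "y")))
  for (k in seq_len(n_leds)) {
    set_led_fn(k, TRUE)
    frames <- lapply(seq_len(frames_per_led), function(i) to_gray(grab_frame_fn()))
    set_led_fn(k, FALSE)
    med <- median_frames(frames)
    regions <- find_regions(threshold_frame(med, T))
    regions <- regions[regions$area >= min_area, , drop = FALSE]
    if (nrow(regions) == 0L)
      stop(sprintf("calibration failure: no region detected for LED %d", k),
           call. = FALSE)
    if (nrow(regions) > 1L)
      stop(sprintf("calibration ambiguity: %d regions detected for LED %d",
                   nrow(regions), k), call. = FALSE)
    centers[k, ] <- c(regions$x[1L], regions$y[1L])
  }
  centers
}

#' Serialize and parse streaming position messages
#'
#' Tracking samples are streamed to the task engine as one-line JSON
#' documents with a fixed, versioned schema modeled on an OSC message:
#' address `"/position"`, payload
#' `[frame_index, x_norm, y_norm, angle_deg, valid]`. `parse_stream_message`
#' is the lossless inverse.
#'
#' @param sample List or one-row data frame with `frame_index`, `x`, `y`
#'   (pixels), `angle` (degrees or NA) and `valid`.
#' @param frame_size `(W, H)` in pixels, used to normalize the position.
#' @return `stream_message` returns a single JSON string;
#'   `parse_stream_message` returns a list with `frame_index`, `x_norm`,
#'   `y_norm`, `angle`, `valid`.
#' @export
stream_message <- function(sample, frame_size) {
  pn <- normalize_position(c(sample$x, sample$y), frame_size)
  ang <- if (is.null(sample$angle) || is.na(sample$angle)) 0 else as.numeric(sample$angle)
  msg <- list(address = "/position", version = 1L,
              payload = list(frame_index = as.integer(sample$frame_index),
                             x_norm = pn[1], y_norm = pn[2],
                             angle_deg = ang,
                             valid = as.integer(isTRUE(as.logical(sample$valid)))))
  as.character(jsonlite::toJSON(msg, auto_unbox = TRUE, digits = NA))
}

#' @rdname stream_message
#' @param msg JSON string from `stream_message`.
#' @export
parse_stream_message <- function(msg) {
  m <- jsonlite::fromJSON(msg)
  if (!identical(m$address, "/position") || !identical(as.integer(m$version), 1L))
    stop("unknown stream message schema", call. = FALSE)
  p <- m$payload
  list(frame_index = as.integer(p$frame_index), x_norm = as.numeric(p$x_norm),
       y_norm = as.numeric(p$y_norm), angle = as.numeric(p$angle_deg),
       valid = as.integer(p$valid) == 1L)
}
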