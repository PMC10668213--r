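test_that("thresholding is exact on synthetic intensities", {
  f <- matrix(10, 20, 20)
  expect_true(all(threshold_frame(f, 50) == 0L))
  expect_true(all(threshold_frame(f, 0) == 1L))

  blob <- matrix(20, 40, 40)
  blob[15:20, 8:13] <- 200
  b <- threshold_frame(blob, 100)
  expect_equal(which(b == 1L), which(blob == 200))

  col <- array(0, dim = c(5, 5, 3))
  col[, , 1] <- 240  # red-only marker; gray mean is 80
  expect_true(all(threshold_frame(col, 60) == 1L))
  expect_true(all(threshold_frame(col, 100) == 0L))
})

test_that("region analysis finds areas and centroids of synthetic squares", {
  b <- binary_square(40, 40, 20:24, 10:14)  # y rows 20..24, x cols 10..14
  r <- find_regions(b)
  expect_equal(nrow(r), 1L)
  expect_equal(r$area, 25L)
  expect_equal(c(r$x, r$y), c(12, 22))

  b2 <- b
  b2[30:32, 30:33] <- 1L
  r2 <- find_regions(b2)
  expect_equal(nrow(r2), 2L)

  expect_equal(nrow(find_regions(matrix(0L, 10, 10))), 0L)

  # diagonal touching pixels merge under 8-connectivity
  d <- matrix(0L, 5, 5)
  d[1, 1] <- d[2, 2] <- d[3, 3] <- 1L
  expect_equal(nrow(find_regions(d)), 1L)
})

test_that("region labeling matches an independent union-find oracle on noise", {
  for (seed in 1:4) {
    set.seed(seed)
    b <- matrix(as.integer(runif(2500) < 0.4), 50, 50)
    got <- find_regions(b)
    want <- oracle_region_stats(b)
    expect_equal(nrow(got), nrow(want))
    got <- got[order(got$y, got$x), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
    # area conservation: region areas sum to the foreground pixel count
    expect_equal(sum(got$area), sum(b))
  }
})

test_that("largest-region selection applies the noise floor and tie-breaks", {
  r <- data.frame(area = c(25L, 9L), x = c(5, 30), y = c(5, 30))
  expect_equal(largest_region(r)$area, 25L)
  expect_null(largest_region(data.frame(area = integer(0), x = numeric(0),
                                        y = numeric(0))))
  expect_null(largest_region(NULL))
  # below the floor: rejected
  expect_null(largest_region(data.frame(area = 3L, x = 1, y = 1), min_area = 5))
  # equal areas: smallest y, then x
  ties <- data.frame(area = c(10L, 10L, 10L), x = c(9, 2, 5), y = c(4, 4, 1))
  top <- largest_region(ties)
  expect_equal(c(top$x, top$y), c(5, 1))
})

test_that("position normalization round-trips within half a pixel", {
  expect_equal(normalize_position(c(320, 240), c(640, 480)), c(0.5, 0.5))
  expect_equal(normalize_position(c(0, 0), c(640, 480)), c(0, 0))
  expect_warning(out <- normalize_position(c(700, -5), c(640, 480)), "clamped")
  expect_equal(out, c(1, 0))
  set.seed(7)
  for (i in 1:50) {
    p <- c(runif(1, 0, 640), runif(1, 0, 480))
    back <- denormalize_position(normalize_position(p, c(640, 480)),
                                 c(640, 480))
    expect_lt(max(abs(back - p)), 0.5)
  }
})

test_that("head direction follows the rear-to-front vector in a y-up frame", {
  expect_equal(head_direction(c(10, 0), c(0, 0)),
               list(angle = 0, single_marker = FALSE))
  # front directly "up": smaller pixel y
  up <- head_direction(c(0, -10), c(0, 0))
  expect_equal(up$angle, 90)
  lf <- head_direction(c(-3, 0), c(0, 0))
  expect_equal(lf$angle, 180)
  # missing or coincident markers: 0 degrees with the single-marker flag
  expect_equal(head_direction(NULL, c(0, 0)),
               list(angle = 0, single_marker = TRUE))
  expect_equal(head_direction(c(5, 5), c(5, 5)),
               list(angle = 0, single_marker = TRUE))
})

test_that("stream messages round-trip losslessly and preserve order", {
  s <- list(frame_index = 42L, x = 123.456, y = 78.9, angle = 271.5,
            valid = TRUE)
  m <- stream_message(s, c(480, 480))
  back <- parse_stream_message(m)
  expect_equal(back$frame_index, 42L)
  expect_equal(back$x_norm, 123.456 / 480)
  expect_equal(back$y_norm, 78.9 / 480)
  expect_equal(back$angle, 271.5)
  expect_true(back$valid)

  # invalid sample: flag carried, position fields preserved
  s2 <- list(frame_index = 43L, x = 123.456, y = 78.9, angle = NA,
             valid = FALSE)
  b2 <- parse_stream_message(stream_message(s2, c(480, 480)))
  expect_false(b2$valid)
  expect_equal(b2$x_norm, 123.456 / 480)

  # in-process loopback of a 1000-sample stream: zero loss, order kept
  set.seed(12)
  xs <- runif(1000, 1, 479); ys <- runif(1000, 1, 479)
  msgs <- vapply(1:1000, function(i)
    stream_message(list(frame_index = i, x = xs[i], y = ys[i],
                        angle = 0, valid = TRUE), c(480, 480)),
    character(1))
  parsed <- lapply(msgs, parse_stream_message)
  expect_equal(vapply(parsed, `[[`, 1L, "frame_index"), 1:1000)
  expect_equal(vapply(parsed, `[[`, 1, "x_norm") * 480, xs, tolerance = 1e-12)
  expect_error(parse_stream_message('{"address":"/other","version":1}'),
               "schema")
})

test_that("auto-calibration recovers all LED positions in order", {
  lay <- perimeter_layout(16, center = c(120, 120), ring_radius = 90)
  scene <- sim_scene(lay, frame_size = c(240, 240))
  lit <- integer(0)
  centers <- autocalibrate(
    set_led_fn = function(k, on) lit <<- if (on) k else integer(0),
    grab_frame_fn = function() render_frame(scene, NULL, leds_on = lit),
    n_leds = 16, T = 128)
  expect_equal(nrow(centers), 16L)
  err <- sqrt(rowSums((centers - lay$positions)^2))
  expect_true(all(err < 1))
  # each returned center is nearest to its own true LED position
  for (k in 1:16) {
    d_all <- sqrt(rowSums((lay$positions -
                             matrix(centers[k, ], 16, 2, byrow = TRUE))^2))
    expect_equal(which.min(d_all), k)
  }

  # single LED
  one <- autocalibrate(function(k, on) lit <<- if (on) k else integer(0),
                       function() render_frame(scene, NULL, leds_on = lit),
                       n_leds = 1, T = 128)
  expect_equal(nrow(one), 1L)

  # an occluded LED is reported by index
  dark <- 7L
  expect_error(autocalibrate(
    function(k, on) lit <<- if (on && k != dark) k else integer(0),
    function() render_frame(scene, NULL, leds_on = lit),
    n_leds = 16, T = 128), "LED 7")

  # two simultaneous bright spots: ambiguity error
  expect_error(autocalibrate(
    function(k, on) lit <<- if (on) c(k, (k %% 16) + 1L) else integer(0),
    function() render_frame(scene, NULL, leds_on = lit),
    n_leds = 16, T = 128), "ambiguity")
})

test_that("the full pipeline recovers a rendered moving blob within a pixel", {
  lay <- perimeter_layout(8, center = c(120, 120), ring_radius = 100)
  scene <- sim_scene(lay, frame_size = c(240, 240))
  agent <- agent_model(list(c(40, 40), c(200, 80), c(120, 200)),
                       speed = 120, seed = 3)
  samples <- simulate_trajectory(agent, rate = 20, t_max = 4)
  frames <- render_frames(samples, scene)
  errs <- vapply(seq_along(frames), function(i) {
    tr <- track_frame(frames[[i]], T = 100, t = samples$t[i])
    sqrt((tr$x - samples$x[i])^2 + (tr$y - samples$y[i])^2)
  }, numeric(1))
  expect_lt(mean(errs), 1)
  # symmetric blob centroid lands within 0.51 px of its center
  still <- render_frame(scene, list(x = 120, y = 120, valid = TRUE))
  reg <- largest_region(find_regions(threshold_frame(still, 100)))
  expect_lt(max(abs(c(reg$x, reg$y) - c(120, 120))), 0.51)
})

test_that("two-marker rendering recovers the commanded heading within 2 degrees", {
  lay <- perimeter_layout(8, center = c(120, 120), ring_radius = 100)
  scene <- sim_scene(lay, frame_size = c(240, 240))
  for (h in c(0, 30, 90, 135, 222, 305)) {
    fr <- render_frame(scene, list(x = 120, y = 120, angle = h, valid = TRUE),
                       two_marker = TRUE)
    front <- largest_region(find_regions(threshold_frame(fr[, , 1], 100)))
    rear <- largest_region(find_regions(threshold_frame(fr[, , 3], 100)))
    hd <- head_direction(c(front$x, front$y), c(rear$x, rear$y))
    delta <- abs(((hd$angle - h + 180) %% 360) - 180)
    expect_lt(delta, 2)
  }
})
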