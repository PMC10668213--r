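simple_config <- function(zones, ...) {
  session_config(zones, reward_type = "liquid", ...)
}

straight_pass <- function(zone, margin = 60, rate = 30, speed = 80) {
  # samples crossing straight through the zone along x
  x0 <- zone$center[1] - zone$radius - margin
  x1 <- zone$center[1] + zone$radius + margin
  n <- ceiling((x1 - x0) / speed * rate)
  data.frame(t = seq_len(n) / rate,
             x = seq(x0, x1, length.out = n),
             y = zone$center[2], angle = 0, valid = TRUE)
}

test_that("a straight pass through a zone yields exactly one entry and one exit", {
  z <- zone_spec(7, c(200, 200), 25, hysteresis = 1.5)
  cfg <- simple_config(list(z))
  res <- run_engine(cfg, straight_pass(z))
  ee <- res$events[res$events$kind %in% c("zone_entry", "zone_exit"), ]
  expect_equal(ee$kind, c("zone_entry", "zone_exit"))
  expect_equal(ee$zone_id, c(7L, 7L))
  # TTL words on the log decode back to the event
  dec <- lapply(ee$ttl_word, decode_zone_event)
  expect_equal(vapply(dec, `[[`, 1L, "zone_id"), c(7L, 7L))
  expect_equal(vapply(dec, `[[`, "", "direction"), c("entry", "exit"))
})

test_that("dwell-delay gating withholds and then delivers the reward", {
  z <- zone_spec(1, c(100, 100), 30, role = "rewarded")
  mk <- function(occupy_s) {
    # far outside, inside the center for exactly occupy_s, far outside again
    # (occupancy is continuous from the entry sample, so the window is sharp)
    t_in <- seq(0.1, 1, by = 0.1)
    t_stay <- seq(1.1, 1 + occupy_s, by = 0.1)
    t_out <- seq(max(t_stay) + 0.1, max(t_stay) + 1, by = 0.1)
    data.frame(t = c(t_in, t_stay, t_out),
               x = c(rep(300, length(t_in)),
                     rep(100, length(t_stay)),
                     rep(300, length(t_out))),
               y = 100, angle = 0, valid = TRUE)
  }
  cfg <- session_config(list(z), rewarded_zone_ids = 1L,
                        reward_type = "stimulation", dwell_delay = 1.5)
  short <- run_engine(cfg, mk(1.0))
  expect_equal(sum(short$events$kind == "reward"), 0L)
  expect_equal(session_counters(short$state)$rewards, 0L)

  long <- run_engine(cfg, mk(2.0))
  expect_equal(sum(long$events$kind == "reward"), 1L)
  # stimulation rewards also log an animal-triggered stimulation
  expect_equal(sum(long$events$kind == "stim_animal"), 1L)
  rt <- long$events$t[long$events$kind == "reward"]
  entry_t <- long$events$t[long$events$kind == "zone_entry"][1]
  expect_gte(rt - entry_t, 1.5)
})

test_that("sequential arming rewards zones in list order with dwell 0", {
  zones <- ring_zones(4)
  order_ids <- c(1L, 3L, 2L, 4L)
  cfg <- session_config(zones, rewarded_zone_ids = order_ids,
                        reward_type = "liquid", dwell_delay = 0)
  wps <- lapply(order_ids, function(i) zones[[i]]$center)
  agent <- agent_model(c(list(c(240, 240)), wps), speed = 200,
                       jitter_sd = 0, dwell_at_waypoint = 0.2, seed = 5)
  samples <- simulate_trajectory(agent, rate = 30, t_max = 15)
  res <- run_engine(cfg, samples)
  rewards <- res$events[res$events$kind == "reward", ]
  expect_equal(rewards$zone_id, order_ids)
  expect_equal(session_counters(res$state)$rewards, 4L)
})

test_that("non-monotone timestamps are rejected", {
  z <- zone_spec(1, c(0, 0), 10)
  st <- engine_init(simple_config(list(z)))
  st <- engine_step(st, list(t = 1, x = 100, y = 100, valid = TRUE))$state
  expect_error(engine_step(st, list(t = 1, x = 100, y = 100, valid = TRUE)),
               class = "mazesim_rejected_sample")
  expect_error(engine_step(st, list(t = 0.5, x = 100, y = 100, valid = TRUE)),
               class = "mazesim_rejected_sample")
})

test_that("invalid samples freeze occupancy instead of fabricating exits", {
  z <- zone_spec(2, c(100, 100), 30)
  cfg <- simple_config(list(z))
  samples <- data.frame(
    t = (1:6) / 2,
    x = c(200, 100, 100, 100, 100, 200),
    y = 100, angle = 0,
    valid = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  # drop out while inside: no exit events during the gap
  res <- run_engine(cfg, samples)
  ee <- res$events[res$events$kind %in% c("zone_entry", "zone_exit"), ]
  expect_equal(ee$kind, c("zone_entry", "zone_exit"))
  expect_equal(session_counters(res$state)$invalid_samples, 2L)
})

test_that("next_cue advances the armed zone without rewarding, wrapping the list", {
  zones <- ring_zones(3)
  cfg <- session_config(zones, rewarded_zone_ids = c(1L, 2L, 3L),
                        reward_type = "liquid")
  st <- engine_init(cfg)
  expect_equal(st$armed_id, 1L)
  r1 <- next_cue(st, t = 1)
  expect_equal(r1$state$armed_id, 2L)
  expect_equal(r1$events$kind[1], "next_cue")
  r2 <- next_cue(r1$state, t = 2)
  r3 <- next_cue(r2$state, t = 3)
  expect_equal(r3$state$armed_id, 1L)  # wrapped
  expect_equal(session_counters(r3$state)$rewards, 0L)

  # single-element list stays armed but still logs the press
  cfg1 <- session_config(zones, rewarded_zone_ids = 2L, reward_type = "liquid")
  s1 <- engine_init(cfg1)
  rr <- next_cue(s1, t = 1)
  expect_equal(rr$state$armed_id, 2L)
  expect_equal(sum(rr$events$kind == "next_cue"), 1L)

  # no rewarded zones: no-op plus warning note
  cfg0 <- session_config(zones, reward_type = "none")
  s0 <- engine_init(cfg0)
  r0 <- next_cue(s0, t = 1)
  expect_true(is.na(r0$state$armed_id))
  expect_equal(r0$events$kind, "session_note")
})

test_that("randomized reward draws are uniform, seeded and reproducible", {
  zones <- lapply(1:32, function(i)
    zone_spec(i, c(100 + i, 100), 10, role = "rewarded"))
  cfg <- session_config(zones, rewarded_zone_ids = 1:32,
                        randomize_rewards = TRUE, reward_type = "liquid",
                        rng_seed = 99L)
  draw_n <- function(seed, n) {
    cfg$rng_seed <- seed
    st <- engine_init(cfg)
    out <- integer(n)
    for (i in seq_len(n)) {
      d <- draw_next_reward(st)
      st <- d$state
      out[i] <- d$zone_id
    }
    out
  }
  draws <- draw_n(99L, 9000)
  expect_true(all(sort(unique(draws)) == 1:32))
  # chi-square against uniform: 3 sigma on each cell count
  counts <- tabulate(draws, 32)
  expected <- 9000 / 32
  sigma <- sqrt(9000 * (1 / 32) * (31 / 32))
  expect_true(all(abs(counts - expected) <= 3.5 * sigma))
  expect_lt(suppressWarnings(chisq.test(counts)$statistic), qchisq(0.999, 31))
  # same seed twice: identical sequence
  expect_identical(draws, draw_n(99L, 9000))

  # single-element list always draws that id
  cfg7 <- session_config(list(zone_spec(7, c(0, 0), 10, role = "rewarded")),
                         rewarded_zone_ids = 7L, randomize_rewards = TRUE,
                         reward_type = "liquid", rng_seed = 3L)
  st7 <- engine_init(cfg7)
  expect_equal(draw_next_reward(st7)$zone_id, 7L)
})

test_that("random-lights sequences are uniform with-replacement draws", {
  s <- generate_random_lights_sequence(1:32, 900, seed = 11)
  expect_length(s, 900)
  expect_true(all(s %in% 1:32))
  expect_identical(s, generate_random_lights_sequence(1:32, 900, seed = 11))

  expect_equal(generate_random_lights_sequence(9L, 5, seed = 1),
               rep(9L, 5))

  big <- generate_random_lights_sequence(1:32, 1e4, seed = 2)
  mult <- tabulate(big, 32)
  expect_equal(mean(mult), 312.5)
  # multinomial spread: each count within 5 sigma of the mean
  sigma <- sqrt(1e4 * (1 / 32) * (31 / 32))
  expect_true(max(abs(mult - 312.5)) <= 5 * sigma)

  expect_error(generate_random_lights_sequence(integer(0), 5, 1), "non-empty")
  expect_error(generate_random_lights_sequence(1:3, 0, 1), "length")
})

test_that("session counters match the event log", {
  p <- load_preset("sequence_task", seed = 4)
  ses <- run_session(p, t_max = 45, seed = 4)
  cnt <- session_counters(ses$state)
  ev <- ses$events
  expect_equal(cnt$rewards, sum(ev$kind == "reward"))
  expect_equal(cnt$stim_animal, sum(ev$kind == "stim_animal"))
  entries <- table(factor(ev$zone_id[ev$kind == "zone_entry"],
                          levels = names(cnt$entries)))
  expect_equal(as.integer(entries), as.integer(cnt$entries))
  # fresh session: all zeros
  cnt0 <- session_counters(engine_init(p$config))
  expect_equal(cnt0$rewards, 0L)
  expect_true(all(cnt0$entries == 0L))
})

test_that("entry/exit strictly alternate per zone on random walks", {
  zones <- ring_zones(6, radius = 40)
  cfg <- session_config(zones, rewarded_zone_ids = c(1L, 4L),
                        reward_type = "liquid")
  for (seed in 1:3) {
    samples <- random_walk_samples(1000, seed = seed, step_sd = 25)
    res <- run_engine(cfg, samples)
    ee <- res$events[res$events$kind %in% c("zone_entry", "zone_exit"), ]
    for (zid in vapply(zones, `[[`, 1L, "id")) {
      kinds <- ee$kind[ee$zone_id == zid]
      if (length(kinds) == 0L) next
      expect_equal(kinds[1], "zone_entry")
      expect_true(all(kinds == rep(c("zone_entry", "zone_exit"),
                                   length.out = length(kinds))))
    }
  }
})

test_that("engine events equal a brute-force occupancy oracle on random walks", {
  zones <- ring_zones(5, radius = 35, role = "tracked")
  cfg <- session_config(zones, reward_type = "none")
  for (seed in c(2, 17)) {
    samples <- random_walk_samples(1000, seed = seed, step_sd = 30,
                                   dropout = 0.05)
    res <- run_engine(cfg, samples)
    got <- res$events[res$events$kind %in% c("zone_entry", "zone_exit"),
                      c("t", "zone_id", "kind")]
    got <- got[order(got$t, got$zone_id), ]
    want <- oracle_zone_events(zones, samples)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("rewards never exceed armed-zone entries; dwell-0 rewards equal armed entries", {
  zones <- ring_zones(4, radius = 40)
  cfg <- session_config(zones, rewarded_zone_ids = c(2L, 3L),
                        reward_type = "liquid", dwell_delay = 0)
  samples <- random_walk_samples(1000, seed = 8, step_sd = 30)
  st <- engine_init(cfg)
  logs <- list()
  armed_entries <- 0L
  for (i in seq_len(nrow(samples))) {
    armed_before <- st$armed_id
    inside_before <- st$inside
    res <- engine_step(st, samples[i, ])
    st <- res$state
    logs[[i]] <- res$events
    if (nrow(res$events) > 0L) {
      ent <- res$events$zone_id[res$events$kind == "zone_entry"]
      if (!is.na(armed_before) && armed_before %in% ent)
        armed_entries <- armed_entries + 1L
    }
    # single armed zone at every step
    expect_length(st$armed_id, 1L)
    expect_true(is.na(st$armed_id) ||
                  st$armed_id %in% cfg$rewarded_zone_ids)
  }
  ev <- do.call(rbind, logs)
  n_rewards <- sum(ev$kind == "reward")
  n_entries_rewarded <- sum(ev$kind == "zone_entry" &
                              ev$zone_id %in% cfg$rewarded_zone_ids)
  expect_lte(n_rewards, n_entries_rewarded)
  expect_equal(n_rewards, armed_entries)
})
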