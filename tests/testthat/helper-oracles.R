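# Independent brute-force oracles and fixture builders. These deliberately
# use different algorithms from the package implementation so that
# agreement is evidence, not tautology.

# --- connected components: two-pass row-scan labeling with union-find ----
# (the package uses seed-fill/BFS; this is an independent algorithm)
oracle_label_regions <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  link <- function(a, b2) {
    ra <- find(a); rb <- find(b2)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nxt <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (b[r, c] != 1L) next
      nb <- integer(0)
      # previously scanned 8-neighbors: (r-1, c-1..c+1), (r, c-1)
      if (r > 1L) {
        for (cc in max(1L, c - 1L):min(nc, c + 1L))
          if (labels[r - 1L, cc] > 0L) nb <- c(nb, labels[r - 1L, cc])
      }
      if (c > 1L && labels[r, c - 1L] > 0L) nb <- c(nb, labels[r, c - 1L])
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[r, c] <- nxt
      } else {
        m <- min(nb)
        labels[r, c] <- m
        for (o in nb) link(m, o)
      }
    }
  }
  # resolve equivalences
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    compact <- match(roots, sort(unique(roots)))
    idx <- labels > 0L
    labels[idx] <- compact[labels[idx]]
  }
  labels
}

oracle_region_stats <- function(b) {
  lab <- oracle_label_regions(b)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L)
    return(data.frame(area = integer(0), x = numeric(0), y = numeric(0)))
  out <- do.call(rbind, lapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    data.frame(area = nrow(w), x = mean(w[, 2]), y = mean(w[, 1]))
  }))
  out[order(out$y, out$x), ]
}

# --- zone occupancy event oracle ----------------------------------------
# Replays a sample stream per zone with a direct (non-incremental-engine)
# flag recursion and derives the entry/exit event sequence.
oracle_zone_events <- function(zones, samples) {
  rows <- list()
  for (z in zones) {
    inside <- FALSE
    for (i in seq_len(nrow(samples))) {
      if (!samples$valid[i]) next
      d <- sqrt((samples$x[i] - z$center[1])^2 + (samples$y[i] - z$center[2])^2)
      now <- d <= z$radius * (if (inside) z$hysteresis else 1)
      if (now != inside) {
        rows[[length(rows) + 1L]] <- data.frame(
          t = samples$t[i], zone_id = z$id,
          kind = if (now) "zone_entry" else "zone_exit")
        inside <- now
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(t = numeric(0), zone_id = integer(0), kind = character(0)))
  ev <- do.call(rbind, rows)
  ev[order(ev$t, ev$zone_id), ]
}

# --- lost-tracking gap oracle -------------------------------------------
oracle_max_invalid_gap <- function(samples) {
  worst <- 0
  i <- 1L
  n <- nrow(samples)
  while (i <= n) {
    if (!samples$valid[i]) {
      j <- i
      while (j < n && !samples$valid[j + 1L]) j <- j + 1L
      t0 <- if (i > 1L) samples$t[i - 1L] else samples$t[i]
      t1 <- if (j < n) samples$t[j + 1L] else samples$t[j]
      worst <- max(worst, t1 - t0)
      i <- j + 1L
    } else i <- i + 1L
  }
  worst
}

# --- criterion rule oracle ----------------------------------------------
oracle_criterion <- function(pcts, threshold, k, n) {
  m <- length(pcts)
  recent <- pcts[(m - n + 1L):m]
  sum(recent > threshold) >= k
}

# --- fixtures ------------------------------------------------------------
random_walk_samples <- function(n, seed, frame = c(480, 480), step_sd = 15,
                                rate = 30, dropout = 0) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  x[1] <- frame[1] / 2; y[1] <- frame[2] / 2
  for (i in 2:n) {
    x[i] <- min(max(x[i - 1] + rnorm(1, 0, step_sd), 1), frame[1])
    y[i] <- min(max(y[i - 1] + rnorm(1, 0, step_sd), 1), frame[2])
  }
  data.frame(t = seq_len(n) / rate, x = x, y = y, angle = 0,
             valid = runif(n) >= dropout)
}

ring_zones <- function(k = 6, radius = 25, role = "rewarded") {
  lay <- perimeter_layout(k, center = c(240, 240), ring_radius = 150)
  lapply(seq_len(k), function(i)
    zone_spec(i, lay$positions[i, ], radius = radius, hysteresis = 1.5,
              role = role))
}

binary_square <- function(nr, nc, rows, cols) {
  b <- matrix(0L, nr, nc)
  b[rows, cols] <- 1L
  b
}
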