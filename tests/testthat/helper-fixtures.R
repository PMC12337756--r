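# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; nothing is read from disk.

# straight eastward track at 1 fix/s, unit speed
straight_track <- function(n = 61, speed = 1) {
  trajectory(data.frame(t = 0:(n - 1), x = speed * (0:(n - 1)), y = 0))
}

# track with an interior stop: flight 1 m/s east, stop at [stop_start,
# stop_end] with jittered fixes around the landing position
track_with_stop <- function(n = 61, stop_start = 20, stop_end = 30,
                            jitter = 0.05, seed = 1, activity = "nectaring") {
  set.seed(seed)
  t <- 0:(n - 1)
  x <- ifelse(t <= stop_start, t,                    # flight in
       ifelse(t <= stop_end,
              stop_start + rnorm(n, 0, jitter),      # stationary cloud
              stop_start + (t - stop_end)))          # flight out
  y <- ifelse(t > stop_start & t <= stop_end, rnorm(n, 0, jitter), 0)
  list(traj = trajectory(data.frame(t = t, x = x, y = y)),
       events = data.frame(start_s = stop_start, end_s = stop_end,
                           activity = activity))
}

# objective of the geometric median
sumdist <- function(p, pts) sum(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))

# independent oracle: coarse-to-fine grid search; valid because the
# objective is convex, final spacing <= res
grid_median_oracle <- function(pts, res = 0.001) {
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  repeat {
    gx <- seq(lo[1], hi[1], length.out = 41)
    gy <- seq(lo[2], hi[2], length.out = 41)
    grid <- as.matrix(expand.grid(gx, gy))
    vals <- sqrt(outer(grid[, 1], pts[, 1], "-")^2 +
                   outer(grid[, 2], pts[, 2], "-")^2)
    best <- grid[which.min(rowSums(vals)), ]
    sp <- max(gx[2] - gx[1], gy[2] - gy[1], 1e-12)
    if (sp <= res) return(best)
    lo <- best - 2 * sp; hi <- best + 2 * sp
  }
}

# per-second enumeration of time-budget shares from an event log
budget_oracle <- function(events, t0, t1) {
  secs <- t0:(t1 - 1)
  stopped <- rep(FALSE, length(secs))
  act <- rep(NA_character_, length(secs))
  for (i in seq_len(nrow(events))) {
    inside <- secs >= events$start_s[i] & secs < events$end_s[i]
    stopped <- stopped | inside
    act[inside] <- events$activity[i]
  }
  c(stopping = mean(stopped),
    nectaring = mean(!is.na(act) & act == "nectaring"),
    resting = mean(!is.na(act) & act == "resting"))
}

# random star-shaped simple polygon (fan triangulation from the center is
# exact, giving an independent area oracle)
star_polygon <- function(n = 12, seed = 1) {
  set.seed(seed)
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 20, 120)
  cbind(r * cos(ang), r * sin(ang))
}

fan_area_oracle <- function(m) {
  n <- nrow(m)
  sum(vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    abs(m[i, 1] * m[j, 2] - m[j, 1] * m[i, 2]) / 2
  }, numeric(1)))
}
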