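test_that("segment geometry matches an independent trigonometric recomputation", {
  # unit steps due east: no turning, c = 1, b = 0
  g <- segment_geometry(cbind(0:5, 0))
  expect_equal(g$turning_angles, rep(0, 4))
  expect_equal(g$c, 1)
  expect_equal(g$b, 0)
  expect_equal(g$p, 1)

  # unit steps alternating +-90 degrees: c = 0, b = 0
  zig <- rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2), c(3, 2))
  g <- segment_geometry(zig)
  expect_equal(g$c, 0, tolerance = 1e-12)
  expect_equal(g$b, 0, tolerance = 1e-12)

  # random walk vs. brute-force recomputation of steps and angles
  set.seed(3)
  for (rep in 1:5) {
    xy <- cbind(cumsum(rnorm(50)), cumsum(rnorm(50)))
    g <- segment_geometry(xy)
    steps <- numeric(); angs <- numeric()
    for (i in 1:49) steps[i] <- sqrt(sum((xy[i + 1, ] - xy[i, ])^2))
    for (i in 2:49) {
      h1 <- atan2(xy[i, 2] - xy[i - 1, 2], xy[i, 1] - xy[i - 1, 1])
      h2 <- atan2(xy[i + 1, 2] - xy[i, 2], xy[i + 1, 1] - xy[i, 1])
      a <- h2 - h1
      while (a <= -pi) a <- a + 2 * pi
      while (a > pi) a <- a - 2 * pi
      angs[i - 1] <- a
    }
    expect_equal(g$step_lengths, steps, tolerance = 1e-12)
    expect_equal(g$turning_angles, angs, tolerance = 1e-12)
    expect_equal(g$c, mean(cos(angs)), tolerance = 1e-12)
    expect_equal(g$b, sqrt(mean((steps - mean(steps))^2)) / mean(steps),
                 tolerance = 1e-12)
  }

  # duplicate fixes collapse before angle computation
  dup <- rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0))
  expect_equal(segment_geometry(dup)$turning_angles, 0)
  expect_error(segment_geometry(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("corrected sinuosity evaluates its closed form", {
  expect_equal(sinuosity(list(p = 1, c = 0, b = 0)), 2)
  expect_equal(sinuosity(list(p = 4, c = 0, b = 0)), 1)
  expect_equal(sinuosity(list(p = 1, c = 0.5, b = 0)), 2 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(sinuosity(list(p = 1, c = 1, b = 0)), 0)   # straight limit
  expect_error(sinuosity(list(p = 1e-9, c = -0.999999, b = 0)), NA)
})

test_that("sinuosity is monotone in c and p and obeys the scale law", {
  set.seed(8)
  for (rep in 1:50) {
    p <- runif(1, 0.2, 5); b <- runif(1, 0, 1)
    cs <- sort(runif(2, -0.9, 0.99))
    expect_gt(sinuosity(list(p = p, c = cs[1], b = b)),
              sinuosity(list(p = p, c = cs[2], b = b)))
    ps <- sort(runif(2, 0.2, 5))
    cc <- runif(1, -0.9, 0.99)
    expect_gt(sinuosity(list(p = ps[1], c = cc, b = b)),
              sinuosity(list(p = ps[2], c = cc, b = b)))
  }

  # scaling coordinates by k scales sinuosity by k^(-1/2), speed by k
  set.seed(9)
  xy <- cbind(cumsum(rnorm(80)), cumsum(rnorm(80)))
  for (k in c(0.25, 4, 9)) {
    s1 <- sinuosity(segment_geometry(xy))
    s2 <- sinuosity(segment_geometry(k * xy))
    expect_equal(s2, s1 * k^(-0.5), tolerance = 1e-10)
  }
  tr1 <- straight_track(31, speed = 1)
  tr3 <- straight_track(31, speed = 3)
  pt1 <- consolidate(tr1, stop_events(data.frame(start_s = numeric(),
                                                 end_s = numeric(),
                                                 activity = character())))
  pt3 <- consolidate(tr3, data.frame(start_s = numeric(),
                                     end_s = numeric(),
                                     activity = character()))
  expect_equal(flight_speed(pt3), 3 * flight_speed(pt1))
})

test_that("weighted sinuosity is the length-weighted mean", {
  g <- segment_geometry(cbind(0:10, 0))
  expect_equal(weighted_sinuosity(list(g), 10), sinuosity(g))
  # Sin 1.0 over 30 m and Sin 2.0 over 10 m -> 1.25
  s1 <- list(p = 4, c = 0, b = 0)   # Sin = 1
  s2 <- list(p = 1, c = 0, b = 0)   # Sin = 2
  expect_equal(weighted_sinuosity(list(s1, s2), c(30, 10)), 1.25)
  # arithmetic oracle on random sets
  set.seed(10)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    segs <- replicate(k, list(p = runif(1, 0.5, 3), c = runif(1, -0.5, 0.9),
                              b = runif(1, 0, 0.8)), simplify = FALSE)
    w <- runif(k, 1, 50)
    sins <- vapply(segs, sinuosity, numeric(1))
    expect_equal(weighted_sinuosity(segs, w), sum(w * sins) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("flight speed excludes stop and gap time", {
  # 50 m flown in 50 flying seconds around a 10-s stop -> 1 m/s
  tw <- track_with_stop(n = 61, stop_start = 20, stop_end = 30, jitter = 0)
  pt <- consolidate(tw$traj, tw$events)
  expect_equal(flight_speed(pt), 1, tolerance = 1e-9)
  # gross definition divides by the full retained span
  expect_equal(flight_speed(pt, definition = "gross"), 50 / 60,
               tolerance = 1e-9)
  # adding a stop leaves flying speed unchanged
  tr <- straight_track(61)
  pt0 <- consolidate(tr, data.frame(start_s = numeric(), end_s = numeric(),
                                    activity = character()))
  expect_equal(flight_speed(pt), flight_speed(pt0), tolerance = 1e-9)
})

test_that("time budget matches per-second enumeration and truth", {
  # 600 s track; 300 s stopped of which 120 nectaring, 60 resting
  tr <- straight_track(601)
  ev <- data.frame(start_s = c(50, 200, 400, 520),
                   end_s = c(170, 260, 490, 550),
                   activity = c("nectaring", "resting", "basking",
                                "oviposition"))
  pt <- consolidate(tr, ev)
  tb <- time_budget(pt)
  expect_equal(unname(tb["stopping"]), 0.5)
  expect_equal(unname(tb["nectaring"]), 0.2)
  expect_equal(unname(tb["resting"]), 0.1)
  expect_equal(tb, budget_oracle(ev, 0, 600))

  # no stops -> all zero
  pt0 <- consolidate(tr, data.frame(start_s = numeric(), end_s = numeric(),
                                    activity = character()))
  expect_equal(unname(time_budget(pt0)), c(0, 0, 0))

  # stopping >= nectaring + resting always
  set.seed(12)
  for (rep in 1:10) {
    sim <- simulate_track(track_sim_config(n_steps = 120, seed = rep))
    pt <- consolidate(sim$trajectory, sim$events)
    tb <- time_budget(pt)
    expect_lte(tb["nectaring"] + tb["resting"], tb["stopping"] + 1e-12)
    expect_lte(tb["stopping"], 1)
  }
})

test_that("movement summary assembles the per-individual row", {
  tw <- track_with_stop()
  s <- movement_summary(consolidate(tw$traj, tw$events))
  expect_named(s, c("individual_id", "species", "sex", "site_id",
                    "duration_s", "path_m", "flight_speed", "stopping",
                    "nectaring", "resting", "sinuosity", "n_stops",
                    "n_segments"))
  expect_equal(s$n_stops, 1)
  expect_equal(s$duration_s, 60)
})
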