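test_that("degenerate walks behave: zero duration, zero speed", {
  ar <- arena(1, 1)
  one <- generate_random_walk(ar, duration = 0, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$x, one$y), c(0.5, 0.5))

  still <- generate_random_walk(ar, duration = 5, speed_range = c(0, 0),
                                seed = 2)
  expect_true(all(still$x == 0.5) && all(still$y == 0.5))
})

test_that("roam under the study conditions stays in bounds at study scale", {
  ar <- arena(10, 10)
  traj <- generate_random_walk(ar, duration = 10000, dt = 0.1, seed = 3)
  expect_equal(nrow(traj), 100001L)
  expect_true(all(traj$x >= 0 & traj$x <= 10 & traj$y >= 0 & traj$y <= 10))
  applied <- traj$speed[-nrow(traj)]
  expect_true(all(applied >= 0 & applied <= 0.5))
  expect_true(all(traj$heading > -pi & traj$heading <= pi))
  expect_true(all(abs(diff(traj$t) - 0.1) < 1e-9))
})

test_that("generation is reproducible for a fixed seed and varies across seeds", {
  ar <- arena(2, 2)
  a <- generate_random_walk(ar, duration = 20, seed = 11)
  b <- generate_random_walk(ar, duration = 20, seed = 11)
  c <- generate_random_walk(ar, duration = 20, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$x, c$x)))
})

test_that("invalid walk arguments are rejected", {
  expect_error(generate_random_walk(arena(1, 1), duration = 1, dt = 0),
               "dt")
  expect_error(generate_random_walk(arena(1, 1), duration = 1,
                                    speed_range = c(-0.1, 0.5)),
               "speed_range")
  expect_error(arena(0, 1), "width")
})

test_that("zero-noise odometry reproduces the path bitwise", {
  traj <- generate_random_walk(arena(2, 2), duration = 60, seed = 4)
  odo <- simulate_odometry(traj, 0, 0, seed = 9)
  expect_identical(odo$x, traj$x)
  expect_identical(odo$y, traj$y)
})

test_that("odometry error grows with time under noise (Monte-Carlo envelope)", {
  traj <- generate_random_walk(arena(5, 5), duration = 200, seed = 5)
  n <- nrow(traj)
  early <- integer(0)
  err_early <- err_late <- numeric(0)
  for (s in 1:20) {
    odo <- simulate_odometry(traj, 0.1, 0.05, seed = 100 + s)
    e <- sqrt((odo$x - traj$x)^2 + (odo$y - traj$y)^2)
    err_early <- c(err_early, mean(e[seq_len(n %/% 4)]))
    err_late <- c(err_late, mean(e[(3 * n %/% 4):n]))
  }
  expect_gt(mean(err_late), mean(err_early))
  expect_gte(mean(err_late > err_early), 0.8)
})

test_that("odometry is deterministic for a fixed seed", {
  traj <- generate_random_walk(arena(2, 2), duration = 30, seed = 6)
  a <- simulate_odometry(traj, 0.2, 0.1, seed = 77)
  b <- simulate_odometry(traj, 0.2, 0.1, seed = 77)
  expect_identical(a, b)
})

test_that("boundary events fire per segment entry with correct geometry", {
  ar <- arena(4, 4)
  # trajectory pinned at the centre: no events
  centre <- tibble::tibble(t = seq(0, 5, 0.1), x = 2, y = 2,
                           speed = 0, heading = 0)
  expect_equal(nrow(detect_boundary_events(centre, ar)), 0L)

  # straight run to the middle of the east wall: exactly one event there
  east <- straight_trajectory(0.4, 0, duration = 8.5, start = c(0.5, 1.5))
  ev <- detect_boundary_events(east, ar, sensing_distance = 0.2,
                               segment_length = 1)
  segs <- gridpath:::boundary_segments(ar, 1)
  east_ids <- segs$segment_id[segs$x0 == 4 & segs$x1 == 4]
  expect_equal(nrow(ev), 1L)
  expect_true(ev$segment_id %in% east_ids)
  expect_equal(ev$cx, 4, tolerance = 1e-9)
  expect_equal(ev$cy, 1.5, tolerance = 1e-9)

  # path through a corner band: events on two adjacent perimeter segments
  corner <- straight_trajectory(0.4, -pi / 4, duration = 7,
                                start = c(2, 2))
  ev2 <- detect_boundary_events(corner, ar, sensing_distance = 0.25,
                                segment_length = 1)
  expect_gte(length(unique(ev2$segment_id)), 2L)
})

test_that("trajectory files round-trip exactly and reject malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  traj <- generate_random_walk(arena(1, 1), duration = 2, seed = 8)
  write_trajectory(traj, f)
  expect_identical(read_trajectory(f), traj)

  # empty series round-trips to empty
  empty <- traj[0, ]
  write_trajectory(empty, f)
  expect_equal(nrow(read_trajectory(f)), 0L)

  # non-monotone time is rejected with the offending line
  bad <- traj[c(1, 3, 2), ]
  readr::write_csv(bad, f)
  expect_error(read_trajectory(f), "Line 4")

  # events round-trip
  ev <- tibble::tibble(t = c(1, 2), segment_id = c(3L, 7L),
                       cx = c(0, 1.5), cy = c(0.25, 0))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_boundary_events(ev, f2)
  expect_identical(read_boundary_events(f2), ev)
})
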