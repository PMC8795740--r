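test_that("weight kernel is zero at the origin and never positive", {
  expect_equal(stripe_weight_kernel(0, lambda = 20), 0)
  x <- seq(-60, 60, by = 0.25)
  expect_true(all(stripe_weight_kernel(x, lambda = 20) <= 0))
  expect_true(all(stripe_weight_kernel(x, lambda = 7) <= 0))
})

test_that("kernel minimum sits at the analytic location (dense-scan oracle)", {
  lambda <- 20
  beta <- 3 / lambda^2
  gamma <- 1.035 * beta
  x <- seq(0, 3 * lambda, by = 0.001)
  scan_min <- x[which.min(stripe_weight_kernel(x, lambda))]
  analytic <- sqrt(log(gamma / beta) / (gamma - beta))
  expect_equal(scan_min, analytic, tolerance = 0.001 / analytic)
})

test_that("weight matrices are all-inhibitory and validated", {
  W <- build_weight_matrix(120, lambda = 24, k = 1)
  expect_true(max(W) <= 0)
  W2 <- build_weight_matrix(180, lambda = 60, k = 6)
  expect_true(max(W2) <= 0)
  expect_error(build_weight_matrix(120, lambda = 0), "lambda")
  expect_error(build_weight_matrix(50, lambda = 20), "3 \\* lambda")
})

test_that("forward input is uniform at rest and sign-split under drive", {
  pl <- stripe_plate(n_cells = 120, lambda = 24, k = 1,
                     tau = 0.01, dt = 0.001)
  expect_equal(forward_input(pl, c(0, 0)), rep(1, 120))
  # motion orthogonal to the preferred direction leaves the drive flat
  expect_equal(forward_input(pl, c(0, 0.4)), rep(1, 120))
  # motion along theta splits by preference sign
  B <- forward_input(pl, c(0.5, 0))
  expect_equal(B, 1 + pl$alpha * 0.5 * pl$e)
})

test_that("euler step keeps rates non-negative and enforces stability bound", {
  pl <- small_relaxed_plate()
  expect_error(step_dynamics(pl, dt = pl$tau), "tau / 5")
  pl2 <- step_dynamics(pl, velocity = c(0.5, 0), n_steps = 50)
  expect_true(min(pl2$s) >= 0)
  # positive uniform drive lifts an all-zero plate
  pl$s <- numeric(pl$n_cells)
  pl3 <- step_dynamics(pl, n_steps = 100)
  expect_gt(sum(pl3$s), 0)
})

test_that("pattern forms quickly and is stationary at zero velocity", {
  res <- relax_to_pattern(
    stripe_plate(n_cells = 120, lambda = 24, k = 1, tau = 0.01, dt = 0.001),
    seed = 5
  )
  expect_lte(res$formation_time, 1)
  expect_equal(gridpath:::profile_period(res$plate$s), 24, tolerance = 0.1)

  # zero-velocity drift below 0.01 cells/s over 10 s
  pl <- res$plate
  p0 <- estimate_phase(pl)
  pl <- step_dynamics(pl, n_steps = 10000) # 10 s at dt = 1 ms
  drift <- abs(wrap_phase_diff(estimate_phase(pl) - p0, pl$lambda)) / 10
  expect_lt(drift, 0.01)
})

test_that("late-stage relaxation profiles are essentially identical", {
  pl <- stripe_plate(n_cells = 120, lambda = 24, k = 1,
                     tau = 0.01, dt = 0.001)
  pl$s <- withr::with_seed(11, runif(120, 0, 0.01))
  st <- gridpath:::can_run_cpp(pl$W, pl$s, pl$e, pl$alpha, numeric(50),
                               pl$dt, pl$tau, 10L)
  expect_gt(cor(st[, 45], st[, 50]), 0.99) # 450 ms vs 500 ms
})

test_that("phase readout is an exact matched filter", {
  pos <- 0:119
  lam <- 24
  expect_equal(estimate_phase(1 + cos(2 * pi * (pos - 7.25) / lam), lambda = lam),
               7.25, tolerance = 1e-6)
  prof <- 1 + cos(2 * pi * pos / lam)
  rolled <- prof[c(120, 1:119)] # shift by one cell
  d <- wrap_phase_diff(estimate_phase(rolled, lambda = lam) -
                         estimate_phase(prof, lambda = lam), lam)
  expect_equal(d, 1, tolerance = 1e-6)
  expect_error(estimate_phase(rep(1, 120), lambda = lam), "flat")
})

test_that("phase unwrapping continues across branch cuts", {
  lam <- 20
  true_track <- seq(0, 95, by = 0.8)
  wrapped <- true_track %% lam
  expect_equal(unwrap_phase(wrapped, lam), true_track)
  down <- seq(30, -42, by = -1.3)
  unw <- unwrap_phase(down %% lam, lam)
  expect_equal(diff(unw), diff(down), tolerance = 1e-9)
})

test_that("constant drive advances the phase linearly", {
  pl <- default_relaxed_plate()
  traj <- straight_trajectory(0.3, 0, duration = 15)
  out <- run_plate(pl, traj)
  sel <- 21:151 # discard the spin-up transient
  fit <- lm(out$track$phase_unwrapped[sel] ~ traj$t[sel])
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_gt(abs(coef(fit)[2]), 1) # the pattern really flows
})

test_that("motion orthogonal to the preferred direction leaves phase put", {
  pl <- default_relaxed_plate()
  traj <- straight_trajectory(0.4, pi / 2, duration = 10)
  out <- run_plate(pl, traj)
  drift <- abs(out$track$phase_unwrapped[101] - out$track$phase_unwrapped[1]) / 10
  expect_lt(drift, 0.01)
})

test_that("calibration recovers the closed-form gain on a straight run", {
  pl <- default_relaxed_plate()
  traj <- straight_trajectory(0.3, 0, duration = 40)
  out <- run_plate(pl, traj)
  direct <- (traj$x[401] - traj$x[51]) /
    (out$track$phase_unwrapped[401] - out$track$phase_unwrapped[51])
  cal <- calibrate_displacement_gain(pl, traj)
  expect_equal(cal$gain, direct, tolerance = 0.02)
  expect_gt(cal$r, 0.999)
})

test_that("calibration rejects trajectories that span too little phase", {
  pl <- default_relaxed_plate()
  tiny <- straight_trajectory(0.01, 0, duration = 2)
  expect_error(calibrate_displacement_gain(pl, tiny), "too short")
})

test_that("set_plate_period rescales velocity input to the requested period", {
  cal <- calibrated_reduced()
  pl <- set_plate_period(cal$plate, 2)
  expect_equal(pl$gain * pl$lambda, 2)
  traj <- straight_trajectory(0.4, 0, duration = 10)
  out <- run_plate(pl, traj)
  # 4 m of travel = 2 periods of phase at a 2 m period
  adv <- out$track$phase_unwrapped[101] - out$track$phase_unwrapped[1]
  expect_equal(abs(adv) * abs(pl$gain), 4, tolerance = 0.1)
})

test_that("a single cell's spatial field is periodic along theta only", {
  cal <- calibrated_reduced()
  pl <- cal$plate
  L <- pl$lambda * abs(pl$gain)
  m <- rate_map(pl, xlim = c(0, 3 * L), ylim = c(0, 3 * L),
                resolution = L / 20)
  z <- matrix(m$rate[order(m$y, m$x)], length(unique(m$x)))
  # strong periodic structure along x (theta = 0), constant along y
  expect_lt(max(apply(z, 1, stats::sd)), 1e-9) # constant along y
  expect_gt(max(apply(z, 2, stats::sd)), 0.01) # banded along x
  # band spacing equals the physical period L
  prof <- z[, 1]
  xs <- sort(unique(m$x))
  acf1 <- stats::acf(prof, lag.max = length(prof) - 1, plot = FALSE)$acf[, 1, 1]
  peak <- which.max(acf1[-(1:10)]) + 10 - 1 # first non-trivial peak
  expect_equal(xs[peak + 1] - xs[1], L, tolerance = 0.15 * L)
})
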