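#' Difference-of-Gaussians weight kernel for stripe plates
#'
#' The lateral-inhibition profile `W0(x) = exp(-gamma * x^2) - exp(-beta * x^2)`
#' used to wire a stripe plate. With the defaults `beta = 3 / lambda^2` and
#' `gamma = 1.035 * beta` (so `gamma > beta`), `W0(x) <= 0` everywhere: the
#' kernel is purely inhibitory, weakest at distance 0 and at large distance,
#' strongest at an intermediate ring — the "Mexican hat" that lets a
#' Turing-type instability carve a periodic pattern of period `lambda` out of
#' uniform drive.
#'
#' @param x Distance in cell units (any numeric vector).
#' @param lambda Pattern period in cells (`> 0`).
#' @param beta,gamma Kernel decay parameters in 1/cells^2; defaults follow the
#'   `beta = 3 / lambda^2`, `gamma = 1.035 * beta` convention.
#'
#' @return Numeric vector of weights, all `<= 0` when `gamma > beta`.
#' @examples
#' stripe_weight_kernel(0, lambda = 20) # exactly 0
#' @export
stripe_weight_kernel <- function(x, lambda, beta = 3 / lambda^2,
                                 gamma = 1.035 * beta) {
  if (lambda <= 0) abort("`lambda` must be > 0.")
  exp(-gamma * x^2) - exp(-beta * x^2)
}

# Signed distance i - j on a ring of n cells, wrapped to (-n/2, n/2].
ring_distance <- function(i, j, n) {
  d <- (i - j) %% n
  d - n * (d > n / 2)
}

# Ratio between the fastest-growing pattern period and the kernel's nominal
# wavelength, from the argmax of the kernel's Fourier transform with
# gamma = g * beta, beta = 3 / lambda_kernel^2:
#   q*^2 = 18 * log(g) * g / (g - 1) / lambda_kernel^2
kernel_mode_factor <- function(gamma_ratio = 1.035) {
  g <- gamma_ratio
  2 * pi / sqrt(18 * log(g) * g / (g - 1))
}

#' Build the recurrent weight matrix of a stripe plate
#'
#' `W[i, j] = W0(d(i, j) - k * e[j])` where `d` is the signed ring distance in
#' cell units and `e[j] = +/-1` is the preferred-direction sign of the
#' presynaptic cell, alternating with cell parity (left/right neighbours
#' prefer opposite directions). The offset `k` shifts each cell's outgoing
#' inhibition towards its preferred direction; paired with velocity-modulated
#' drive this makes the stationary stripe pattern flow.
#'
#' On a one-dimensional ring this kernel needs two adjustments that the
#' two-dimensional neighbourhood sum provides for free in sheet models:
#' an overall amplitude `w0_scale` large enough that the recurrent gain of
#' the pattern-forming mode exceeds 1 (otherwise the uniform state is
#' linearly stable and no stripes form), and a conversion between the
#' requested pattern period and the kernel's nominal wavelength, because the
#' fastest-growing mode of this kernel sits at `~1.4685` times its nominal
#' wavelength. `build_weight_matrix()` takes the desired *pattern* period
#' `lambda` and applies both internally.
#'
#' @param n_cells Number of cells (`>= 3 * lambda`, at least three pattern
#'   periods on the ring).
#' @param lambda Desired pattern period in cells (`> 0`).
#' @param k Weight offset in cells (`>= 0`).
#' @param w0_scale Amplitude applied to the kernel; default 40.
#'
#' @return An `n_cells x n_cells` matrix, every entry `<= 0`.
#' @examples
#' W <- build_weight_matrix(60, lambda = 20, k = 1)
#' max(W) <= 0
#' @export
build_weight_matrix <- function(n_cells, lambda, k = 1, w0_scale = 40) {
  if (lambda <= 0) abort("`lambda` must be > 0.")
  if (k < 0) abort("`k` must be >= 0.")
  if (n_cells < 3 * lambda) {
    abort("`n_cells` must be >= 3 * lambda (three pattern periods on the plate).")
  }
  n_cells <- as.integer(n_cells)
  e <- preferred_signs(n_cells)
  i <- matrix(seq_len(n_cells) - 1L, n_cells, n_cells)
  j <- t(i)
  d <- ring_distance(i, j, n_cells)
  w0_scale * stripe_weight_kernel(
    d - k * matrix(e, n_cells, n_cells, byrow = TRUE),
    lambda = lambda / kernel_mode_factor()
  )
}

# +1 for even cells (0-based), -1 for odd: interleaved preferred signs.
preferred_signs <- function(n_cells) {
  rep_len(c(1, -1), n_cells)
}

#' Stripe-cell continuous attractor plate
#'
#' A one-dimensional ring of stripe cells obeying
#' `tau * ds/dt + s = f(W s + B)` with rectifier `f(x) = max(x, 0)`,
#' all-inhibitory recurrent weights from [build_weight_matrix()], and
#' velocity-modulated drive `B_i = 1 + alpha * e_i * v_proj` where `v_proj`
#' is the agent velocity projected onto the plate's preferred direction
#' `theta`. With `k` and `alpha` both nonzero the periodic firing pattern
#' flows at a speed proportional to `v_proj`, so the (unwrapped) pattern phase
#' path-integrates displacement along `theta`.
#'
#' Internal positions are in cell units; meters enter only through the
#' displacement gain obtained from [calibrate_displacement_gain()] (or set via
#' [set_plate_period()]).
#'
#' @param n_cells Number of cells; default 360.
#' @param lambda Pattern period in cells; default 60 (six periods on the
#'   default plate). Accurate path integration needs a dense sampling of the
#'   period (~30 cells, i.e. 15 per preference sign): discreteness pinning,
#'   which sticks the pattern at low drive and at movement reversals, falls
#'   off steeply with cells-per-period.
#' @param theta Preferred movement direction in radians (the direction of
#'   motion that drives the phase; stripe bands in 2-D run perpendicular to
#'   it).
#' @param k Weight offset in cells; default 6 ("relatively tiny" against
#'   `lambda`: a tenth of the period, large enough to escape discreteness
#'   pinning at low drive).
#' @param alpha Velocity-drive coupling (s/m); together with `k` it sets the
#'   plate's phase speed per m/s.
#' @param tau Rate time constant in seconds; default 0.003 (a fast effective
#'   population time constant keeps the transient left by each stepwise
#'   velocity-command change small; formation studies customarily use 0.01).
#' @param dt Euler integration step in seconds; default 0.0006 (must satisfy
#'   `dt <= tau / 5`).
#' @param velocity_scale Dimensionless scaling applied to the velocity
#'   projection before it enters the drive; used to realise different
#'   physical periods from one calibrated plate (see [set_plate_period()]).
#' @param w0_scale Weight-kernel amplitude (see [build_weight_matrix()]).
#'
#' @return An object of class `gp_stripe_plate`.
#' @examples
#' plate <- stripe_plate(n_cells = 60, lambda = 20)
#' @export
stripe_plate <- function(n_cells = 360L, lambda = 60, theta = 0, k = 6,
                         alpha = 0.06, tau = 0.003, dt = 0.0006,
                         velocity_scale = 1, w0_scale = 40) {
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (dt > tau / 5 + 1e-12) {
    abort("`dt` must be <= tau / 5 for a stable forward-Euler integration.")
  }
  W <- build_weight_matrix(n_cells, lambda, k, w0_scale)
  n_cells <- as.integer(n_cells)
  structure(
    list(
      n_cells = n_cells, lambda = lambda, theta = theta, k = k, alpha = alpha,
      tau = tau, dt = dt, velocity_scale = velocity_scale, w0_scale = w0_scale,
      e = preferred_signs(n_cells), W = W,
      s = numeric(n_cells), relaxed = FALSE, gain = NA_real_
    ),
    class = "gp_stripe_plate"
  )
}

#' @export
print.gp_stripe_plate <- function(x, ...) {
  cat(sprintf(
    "<stripe plate: %d cells, lambda = %g cells, theta = %.1f deg%s%s>\n",
    x$n_cells, x$lambda, x$theta * 180 / pi,
    if (x$relaxed) ", pattern formed" else ", unrelaxed",
    if (is.na(x$gain)) "" else sprintf(", gain = %.4g m/cell", x$gain)
  ))
  invisible(x)
}

# Scalar drive of a plate for a velocity 2-vector (m/s).
plate_projection <- function(plate, velocity) {
  plate$velocity_scale *
    (velocity[1] * cos(plate$theta) + velocity[2] * sin(plate$theta))
}

#' Forward input vector of a stripe plate
#'
#' `B_i = 1 + alpha * e_i * v_proj`: uniform unit drive plus a signed
#' velocity modulation, positive for cells preferring the movement direction
#' and negative for the interleaved opposite-preference cells. Zero or
#' orthogonal velocity gives `B_i = 1` for every cell.
#'
#' @param plate A [stripe_plate()].
#' @param velocity Length-2 velocity vector in m/s.
#'
#' @return Numeric vector of length `n_cells`.
#' @export
forward_input <- function(plate, velocity = c(0, 0)) {
  check_plate(plate)
  1 + plate$alpha * plate$e * plate_projection(plate, velocity)
}

check_plate <- function(plate) {
  if (!inherits(plate, "gp_stripe_plate")) {
    abort("`plate` must be created with stripe_plate().")
  }
  invisible(plate)
}

#' Advance the stripe-plate dynamics
#'
#' Forward-Euler update `s <- s + (dt / tau) * (-s + f(W s + B))`, repeated
#' `n_steps` times with the drive held constant. Rates remain non-negative.
#'
#' @inheritParams forward_input
#' @param dt Euler step in seconds; defaults to the plate's `dt` and must
#'   satisfy `dt <= tau / 5`.
#' @param n_steps Number of Euler steps to take.
#' @param inject Optional additive input vector (length `n_cells`), e.g. a
#'   boundary-cell corrective drive; defaults to none.
#'
#' @return The updated plate.
#' @export
step_dynamics <- function(plate, velocity = c(0, 0), dt = plate$dt,
                          n_steps = 1L, inject = NULL) {
  check_plate(plate)
  if (dt > plate$tau / 5 + 1e-12) {
    abort("`dt` must be <= tau / 5 for a stable forward-Euler integration.")
  }
  inject <- inject %||% numeric(plate$n_cells)
  if (length(inject) != plate$n_cells) abort("`inject` length must match the plate.")
  plate$s <- as.vector(can_step_cpp(
    plate$W, plate$s, plate$e, plate$alpha,
    plate_projection(plate, velocity), inject, dt, plate$tau,
    as.integer(n_steps)
  ))
  plate
}

# Dominant spatial period (cells) of a rate profile, by FFT peak.
profile_period <- function(s) {
  n <- length(s)
  spec <- Mod(fft(s - mean(s)))[2:(floor(n / 2) + 1)]
  if (all(spec == 0)) return(NA_real_)
  n / which.max(spec)
}

#' Relax a noise-seeded plate into its stripe pattern
#'
#' Integrates the plate from a small random initial state under zero velocity
#' until a periodic stripe pattern has formed: the rate profile's dominant
#' spatial period matches `lambda` within 10% and the profile change over a
#' 50 ms window falls below `tolerance` (relative to the profile maximum).
#' Pattern formation is spontaneous — a Turing-type instability of the
#' all-inhibitory recurrent weights under uniform drive.
#'
#' @inheritParams forward_input
#' @param max_duration Give up after this much simulated time (seconds).
#' @param noise_amplitude Initial rates are drawn uniformly from
#'   `[0, noise_amplitude]`.
#' @param seed Integer seed for the initial state.
#' @param tolerance Relative profile-change tolerance for stability.
#' @param retries Additional attempts with re-drawn initial noise when the
#'   plate settles into the wrong wavenumber or fails to stabilise (finite
#'   rings occasionally seed a competing mode); 0 reports the first attempt
#'   as-is.
#'
#' @return A list with elements `plate` (relaxed, with the formed pattern as
#'   its state) and `formation_time` (seconds, the first time both criteria
#'   held).
#' @examples
#' res <- relax_to_pattern(stripe_plate(n_cells = 60), seed = 1)
#' res$formation_time
#' @export
relax_to_pattern <- function(plate, max_duration = 2, noise_amplitude = 0.01,
                             seed = 1L, tolerance = 0.01, retries = 0L) {
  check_plate(plate)
  if (retries > 0L) {
    for (a in 0:retries) {
      out <- tryCatch(
        relax_to_pattern(plate, max_duration = max_duration,
                         noise_amplitude = noise_amplitude,
                         seed = seed + 7919L * a, tolerance = tolerance,
                         retries = 0L),
        error = function(e) NULL
      )
      if (!is.null(out)) return(out)
    }
    abort(sprintf("No stable stripe pattern formed in %d attempts.", retries + 1L))
  }
  plate$s <- withr::with_seed(seed, runif(plate$n_cells, 0, noise_amplitude))
  check_every <- 0.01 # s
  nsub <- max(1L, as.integer(round(check_every / plate$dt)))
  n_checks <- as.integer(ceiling(max_duration / check_every))
  states <- can_run_cpp(
    plate$W, plate$s, plate$e, plate$alpha,
    numeric(n_checks), plate$dt, plate$tau, nsub
  )
  lag <- as.integer(round(0.05 / check_every)) # 50 ms window
  for (i in seq_len(n_checks)) {
    if (i <= lag) next
    s_now <- states[, i]
    per <- profile_period(s_now)
    stable <- max(abs(s_now - states[, i - lag])) <=
      tolerance * max(s_now, 1e-12)
    if (!is.na(per) && abs(per - plate$lambda) <= 0.1 * plate$lambda && stable) {
      plate$s <- s_now
      plate$relaxed <- TRUE
      return(list(plate = plate, formation_time = i * check_every))
    }
  }
  abort(sprintf("No stable stripe pattern formed within %g s.", max_duration))
}

#' Pattern phase of a stripe plate
#'
#' Population-vector readout of the periodic rate profile:
#' `phase = (lambda / 2 pi) * Arg(sum_i s_i * exp(2 pi i * pos_i / lambda))`,
#' mapped to `[0, lambda)`. The phase tracks the pattern as it flows, so
#' consecutive calls can be unwrapped ([unwrap_phase()]) into a cumulative
#' displacement code.
#'
#' @param plate A [stripe_plate()], or a numeric rate profile if `lambda` is
#'   given.
#' @param lambda Pattern period in cells (only when `plate` is a raw profile).
#'
#' @return Phase in cell units, in `[0, lambda)`.
#' @examples
#' pos <- 0:59
#' estimate_phase(1 + cos(2 * pi * (pos - 7.25) / 20), lambda = 20)
#' @export
estimate_phase <- function(plate, lambda = NULL) {
  if (inherits(plate, "gp_stripe_plate")) {
    s <- plate$s
    lambda <- plate$lambda
  } else {
    s <- plate
    if (is.null(lambda)) abort("`lambda` is required for a raw rate profile.")
  }
  phase_of_profile(s, lambda)
}

phase_of_profile <- function(s, lambda) {
  n <- length(s)
  z <- sum(s * exp(2i * pi * (seq_len(n) - 1L) / lambda))
  if (Mod(z) < 1e-9 * max(sum(abs(s)), 1e-12)) {
    abort("Phase undefined: rate profile is flat at period lambda.")
  }
  pmod(Arg(z) * lambda / (2 * pi), lambda)
}

#' Unwrap a periodic phase track
#'
#' Nearest-branch continuation: each consecutive phase difference is wrapped
#' to `(-lambda/2, lambda/2]` before accumulating, turning a `[0, lambda)`
#' phase series into a cumulative track. Requires per-sample phase motion
#' below half a period.
#'
#' @param phase Numeric vector of phases in cell units.
#' @param lambda Pattern period in cells.
#'
#' @return Numeric vector, same length, starting at `phase[1]`.
#' @export
unwrap_phase <- function(phase, lambda) {
  if (length(phase) <= 1L) return(phase)
  d <- diff(phase)
  d <- d - lambda * round(d / lambda)
  phase[1] + c(0, cumsum(d))
}

#' Drive a stripe plate along a trajectory
#'
#' Projects each trajectory step's velocity onto the plate's preferred
#' direction (the signal the head-direction ring carries for that direction)
#' and integrates the plate dynamics across the step, recording the pattern
#' phase at every sample.
#'
#' @inheritParams forward_input
#' @param traj A trajectory tibble (see [generate_random_walk()]).
#'
#' @return A list with `plate` (final state) and `track`, a tibble with
#'   columns `t`, `proj` (drive in m/s), `phase` (cells, wrapped) and
#'   `phase_unwrapped` (cells, cumulative).
#' @export
run_plate <- function(plate, traj, record_splits = 10L) {
  check_plate(plate)
  check_trajectory(traj)
  n <- nrow(traj)
  if (n < 2L) abort("`traj` must have at least 2 samples.")
  dt_samp <- diff(traj$t)
  if (max(abs(dt_samp - dt_samp[1])) > 1e-9) {
    abort("`traj` must be uniformly sampled.")
  }
  # Phase is recorded `record_splits` times per trajectory sample so that
  # unwrapping stays well below the half-period-per-record limit even for
  # fast pattern flow; the returned track keeps the trajectory's own grid.
  record_splits <- max(1L, as.integer(record_splits))
  nsub <- max(1L, as.integer(ceiling(dt_samp[1] / plate$dt / record_splits - 1e-9)))
  # Euler step adjusted so record_splits * nsub steps tile the sample exactly
  dt_eff <- dt_samp[1] / (record_splits * nsub)
  if (dt_eff > plate$tau / 5 * 1.0001) {
    abort("Trajectory sampling too coarse for the plate's Euler step.")
  }
  proj <- plate$velocity_scale * traj$speed[-n] * cos(traj$heading[-n] - plate$theta)
  states <- can_run_cpp(plate$W, plate$s, plate$e, plate$alpha,
                        rep(proj, each = record_splits),
                        dt_eff, plate$tau, nsub)
  w <- exp(2i * pi * (seq_len(plate$n_cells) - 1L) / plate$lambda)
  z <- as.vector(t(states) %*% w)
  phase0 <- phase_of_profile(plate$s, plate$lambda)
  phase_fine <- unwrap_phase(
    c(phase0, pmod(Arg(z) * plate$lambda / (2 * pi), plate$lambda)),
    plate$lambda
  )
  keep <- 1L + record_splits * (0:(n - 1L))
  phase_unwrapped <- phase_fine[keep]
  plate$s <- states[, ncol(states)]
  list(
    plate = plate,
    track = tibble(
      t = traj$t,
      proj = c(proj, proj[length(proj)]),
      phase = pmod(phase_unwrapped, plate$lambda),
      phase_unwrapped = phase_unwrapped
    )
  )
}

#' Calibrate the displacement gain of a stripe plate
#'
#' Drives the plate along a calibration trajectory, regresses the true
#' displacement along the plate's preferred direction on the unwrapped
#' pattern phase (ordinary least squares), and stores the slope — meters per
#' cell of phase shift — on the plate. The correlation and the maximum
#' absolute residual of the regression line quantify how linearly the plate
#' path-integrates.
#'
#' @inheritParams run_plate
#'
#' @return An object of class `gp_calibration`: a list with the calibrated
#'   `plate`, `gain` (m/cell), `period` (`lambda * |gain|`, the physical
#'   stripe period in meters), `r` (Pearson correlation), `max_residual`
#'   (meters), `n` (samples), and `data` (tibble with `t`, `displacement`,
#'   `phase`, `fitted`, `residual`). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' \donttest{
#' pl <- relax_to_pattern(stripe_plate(), seed = 1)$plate
#' roam <- generate_random_walk(arena(1, 1), duration = 60, seed = 2)
#' cal <- calibrate_displacement_gain(pl, roam)
#' glance(cal)
#' }
#' @export
calibrate_displacement_gain <- function(plate, traj) {
  check_plate(plate)
  if (!plate$relaxed) {
    abort("Calibrate a relaxed plate: run relax_to_pattern() first.")
  }
  res <- run_plate(plate, traj)
  disp <- (traj$x - traj$x[1]) * cos(plate$theta) +
    (traj$y - traj$y[1]) * sin(plate$theta)
  phase <- res$track$phase_unwrapped - res$track$phase_unwrapped[1]
  if (sum(abs(diff(phase))) < 5 * plate$lambda) {
    abort("Calibration trajectory too short: needs >= 5 pattern periods of motion along theta.")
  }
  fit <- lm(disp ~ phase)
  gain <- unname(coef(fit)[2])
  resid <- disp - as.vector(predict(fit))
  plate <- res$plate
  plate$gain <- gain
  structure(
    list(
      plate = plate, gain = gain, period = abs(gain) * plate$lambda,
      r = abs(cor(disp, phase)), max_residual = max(abs(resid)),
      n = length(disp),
      data = tibble(
        t = traj$t, displacement = disp, phase = phase,
        fitted = as.vector(predict(fit)), residual = resid
      )
    ),
    class = "gp_calibration"
  )
}

#' @export
print.gp_calibration <- function(x, ...) {
  cat(sprintf(
    "<stripe-plate calibration: gain = %.5g m/cell (period %.3g m), r = %.5f, max |residual| = %.4g m, n = %d>\n",
    x$gain, x$period, x$r, x$max_residual, x$n
  ))
  invisible(x)
}

#' Set the physical period of a calibrated plate
#'
#' Rescales the plate's velocity input so that one pattern period `lambda`
#' corresponds to `period` meters of travel along `theta`. Requires a
#' calibrated displacement gain; the stored gain is updated to
#' `period / lambda`.
#'
#' @inheritParams forward_input
#' @param period Desired physical stripe period in meters (`> 0`).
#'
#' @return The rescaled plate.
#' @export
set_plate_period <- function(plate, period) {
  check_plate(plate)
  stopifnot_scalar_number(period, "period", positive = TRUE)
  if (is.na(plate$gain)) {
    abort("Plate has no calibrated gain; run calibrate_displacement_gain() first.")
  }
  plate$velocity_scale <- plate$velocity_scale * plate$gain * plate$lambda / period
  plate$gain <- period / plate$lambda
  plate
}
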