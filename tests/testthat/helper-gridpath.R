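# Shared fixtures. Relaxed/calibrated plates are cached per session because
# several test files need one and relaxation is the slow step.

.gp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .gp_cache)) {
    assign(key, force(expr), envir = .gp_cache)
  }
  get(key, envir = .gp_cache)
}

# A small relaxed plate for dynamics tests (formation geometry).
small_relaxed_plate <- function() {
  cached("small_plate", relax_to_pattern(
    stripe_plate(n_cells = 120, lambda = 24, k = 1, tau = 0.01, dt = 0.001),
    seed = 42
  )$plate)
}

# The default integration plate, relaxed.
default_relaxed_plate <- function() {
  cached("default_plate", relax_to_pattern(stripe_plate(), seed = 42,
    retries = 4L)$plate)
}

# A relaxed + calibrated reduced plate (the geometry the long-roam studies
# use), with its calibration object.
calibrated_reduced <- function() {
  cached("calibrated_reduced", {
    pl <- stripe_plate(n_cells = 180, lambda = 60, k = 6,
                       tau = 0.01, dt = 0.002)
    run_phase_linearity(seed = 7, duration = 60, plate = pl)
  })
}

# Wrap a phase difference to (-lambda/2, lambda/2].
wrap_phase_diff <- function(d, lambda) {
  d - lambda * round(d / lambda)
}

# Constant-velocity trajectory along a fixed heading.
straight_trajectory <- function(speed, heading, duration, dt = 0.1,
                                start = c(0, 0)) {
  t <- seq(0, duration, by = dt)
  tibble::tibble(
    t = t,
    x = start[1] + speed * t * cos(heading),
    y = start[2] + speed * t * sin(heading),
    speed = speed,
    heading = heading
  )
}
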