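#' Stripe-pattern formation study
#'
#' Relaxes noise-seeded stripe plates to their periodic pattern across many
#' seeds and reports the formation-time distribution. The plate geometry
#' follows the formation experiment: 120 cells, time constant 10 ms, Euler
#' step 1 ms, small positive uniform initial noise, zero velocity.
#'
#' @param n_seeds Number of independent initialisations.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param n_cells,lambda,k,w0_scale,tau,dt Plate parameters (see
#'   [stripe_plate()]).
#' @param max_duration,noise_amplitude Passed to [relax_to_pattern()].
#'
#' @return An object of class `gp_formation_study`: `runs` is a tibble with
#'   columns `seed`, `formation_ms` (NA when no stable pattern formed within
#'   `max_duration`); [glance()] yields `median_ms`, `max_ms`, `n_failed`,
#'   `n_seeds`.
#' @export
run_stripe_formation <- function(n_seeds = 20L, seed = 1L,
                                 n_cells = 120L, lambda = 24, k = 1,
                                 w0_scale = 40, tau = 0.01, dt = 0.001,
                                 max_duration = 2, noise_amplitude = 0.01) {
  plate <- stripe_plate(n_cells = n_cells, lambda = lambda, k = k,
                        w0_scale = w0_scale, tau = tau, dt = dt)
  runs <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    ft <- tryCatch(
      relax_to_pattern(plate, max_duration = max_duration,
                       noise_amplitude = noise_amplitude,
                       seed = seed + i - 1L)$formation_time,
      error = function(e) NA_real_
    )
    tibble(seed = seed + i - 1L, formation_ms = ft * 1000)
  })
  structure(list(runs = runs,
                 config = list(n_cells = n_cells, lambda = lambda, k = k,
                               w0_scale = w0_scale, tau = tau, dt = dt,
                               noise_amplitude = noise_amplitude,
                               max_duration = max_duration, seed = seed)),
            class = "gp_formation_study")
}

#' @export
print.gp_formation_study <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<stripe formation study: %d seeds, median %.0f ms, max %.0f ms, %d failed>\n",
    g$n_seeds, g$median_ms, g$max_ms, g$n_failed
  ))
  invisible(x)
}

#' Phase-displacement linearity experiment
#'
#' The stripe-cell path-integration benchmark: relax a plate, drive it with
#' a random roam in a small arena (speeds uniform in (0, 0.5) m/s), and
#' regress true displacement along the plate's preferred direction on the
#' unwrapped pattern phase. Returns the calibration object carrying the
#' correlation, the maximum regression residual, and the fitted displacement
#' gain.
#'
#' @param seed Seed for the pattern initialisation; the roam uses `seed + 1`.
#' @param duration Roam duration in seconds.
#' @param roam_arena Arena for the roam; default 1 m x 1 m.
#' @param plate A [stripe_plate()]; default plate if `NULL`.
#'
#' @return A `gp_calibration` (see [calibrate_displacement_gain()]).
#' @export
run_phase_linearity <- function(seed = 1L, duration = 120,
                                roam_arena = arena(1, 1), plate = NULL) {
  plate <- plate %||% stripe_plate()
  plate <- relax_to_pattern(plate, seed = seed, retries = 4L)$plate
  roam <- generate_random_walk(roam_arena, duration = duration, seed = seed + 1L)
  calibrate_displacement_gain(plate, roam)
}

# Build one relaxed, calibrated plate and clone it across orientations with
# the requested physical period. The displacement gain is a property of the
# plate dynamics, not of its orientation, so one calibration serves all
# directions.
make_calibrated_plates <- function(thetas, period, seed = 1L, plate = NULL,
                                   calib_duration = 60) {
  cal <- run_phase_linearity(seed = seed, duration = calib_duration,
                             plate = plate)
  base <- cal$plate
  plates <- purrr::map(thetas, function(th) {
    p <- base
    p$theta <- th
    set_plate_period(p, period)
  })
  list(plates = plates, calibration = cal)
}

#' Multi-scale decoding accuracy study
#'
#' Monte-Carlo sweep of decoding error against the number of nested grid
#' scales and the number of cells per module: Poisson counts are drawn for
#' random positions and decoded with 1..`n_scales` modules (periods in a
#' geometric progression from `lambda0`), reporting the RMS position error
#' per condition. Error decreases both with more scales and with more cells.
#'
#' @param cells_side Vector of module sizes (cells per side).
#' @param n_scales Maximum number of scales.
#' @param n_trials Positions per condition.
#' @param lambda0 Coarsest grid period in meters.
#' @param ratio Scale ratio between neighbouring modules.
#' @param window Poisson observation window in seconds.
#' @param n_max,kappa Module tuning parameters.
#' @param seed Seed for positions and counts.
#'
#' @return A tibble with columns `cells_side`, `n_scales`, `rmse`,
#'   `n_trials`.
#' @export
run_multiscale_study <- function(cells_side = c(50L, 100L), n_scales = 4L,
                                 n_trials = 200L, lambda0 = 10, ratio = 1.5,
                                 window = 1, n_max = 10, kappa = 3,
                                 seed = 1L) {
  out <- purrr::map_dfr(cells_side, function(m) {
    modules <- purrr::map(0:(n_scales - 1L), function(s) {
      grid_module(lambda0 / ratio^s, cells_side = m, n_max = n_max,
                  kappa = kappa)
    })
    err <- matrix(NA_real_, n_trials, n_scales)
    withr::with_seed(seed, {
      xs <- cbind(runif(n_trials, -lambda0 / 4, lambda0 / 4),
                  runif(n_trials, -lambda0 / 4, lambda0 / 4))
      for (i in seq_len(n_trials)) {
        counts <- purrr::map(modules, function(mod) {
          rpois(mod$M, grid_expected_rates(mod, xs[i, ]) * window)
        })
        for (L in seq_len(n_scales)) {
          d <- decode_multiscale(counts[1:L], modules[1:L])
          err[i, L] <- sqrt(sum((d$x - xs[i, ])^2))
        }
      }
    })
    tibble(
      cells_side = m,
      n_scales = seq_len(n_scales),
      rmse = sqrt(colMeans(err^2)),
      n_trials = n_trials
    )
  })
  out
}

#' Noise robustness of the grid-code position decode
#'
#' Encodes a fixed position in a single grid module, perturbs the expected
#' activation with zero-mean Gaussian noise of amplitude 0/10/20% (and any
#' other requested levels) of the peak activation, decodes, and reports the
#' displacement of the estimate — the position expression is only weakly
#' disturbed.
#'
#' @param noise_levels Noise standard deviations as fractions of the peak
#'   activation `n_max * window`.
#' @param position Encoded position in meters.
#' @param lambda Grid period in meters.
#' @param cells_side,n_max,kappa Module parameters.
#' @param window Observation window in seconds.
#' @param n_trials Perturbation draws per level.
#' @param seed Seed.
#'
#' @return A tibble with columns `noise`, `median_displacement`,
#'   `q90_displacement`, `median_error` (all meters).
#' @export
run_noise_robustness <- function(noise_levels = c(0, 0.1, 0.2),
                                 position = c(-3, -3), lambda = 10,
                                 cells_side = 50L, n_max = 10, kappa = 3,
                                 window = 1, n_trials = 50L, seed = 1L) {
  mod <- grid_module(lambda, cells_side = cells_side, n_max = n_max,
                     kappa = kappa)
  mu <- grid_expected_rates(mod, position) * window
  base <- decode_single_module(mu, mod)
  amp <- n_max * window
  purrr::map_dfr(noise_levels, function(lv) {
    disp <- err <- numeric(n_trials)
    withr::with_seed(seed + round(lv * 1000), {
      for (i in seq_len(n_trials)) {
        r <- pmax(mu + rnorm(length(mu), 0, lv * amp), 0)
        d <- decode_single_module(r, mod)
        disp[i] <- sqrt(sum((d$x - base$x)^2))
        err[i] <- sqrt(sum((d$x - position)^2))
      }
    })
    tibble(
      noise = lv,
      median_displacement = median(disp),
      q90_displacement = quantile(disp, 0.9),
      median_error = median(err)
    )
  })
}

# Decode a 2-D position track from three plates' unwrapped phase tracks:
# each plate reports displacement gain * dphi along its direction, and the
# three projections recombine through (2/3) sum d_l u_l.
phases_to_positions <- function(tracks, plates, origin) {
  stopifnot(length(tracks) == 3L, length(plates) == 3L)
  n <- nrow(tracks[[1]])
  xy <- matrix(0, n, 2)
  for (l in 1:3) {
    d <- plates[[l]]$gain *
      (tracks[[l]]$phase_unwrapped - tracks[[l]]$phase_unwrapped[1])
    u <- c(cos(plates[[l]]$theta), sin(plates[[l]]$theta))
    xy <- xy + (2 / 3) * outer(d, u)
  }
  sweep(xy, 2, as.numeric(origin), "+")
}

#' Boundary-correction comparison study
#'
#' The long-roam drift experiment: an agent roams a walled arena for
#' `duration` seconds while its stripe plates are driven by noisy odometry
#' commands. Three paths are compared against ground truth: the plates with
#' boundary-cell learning and corrective injection at wall contacts, the
#' same plates without correction, and the raw dead-reckoned odometry.
#' With correction the error stays bounded by the drift accrued between wall
#' contacts; without it both other paths drift without bound.
#'
#' @param n_seeds Independent roams.
#' @param duration Roam duration per seed in seconds.
#' @param roam_arena Arena; default 2 m x 2 m.
#' @param period Physical stripe period in meters for the plates.
#' @param speed_noise_sd,heading_noise_sd Odometry noise (see
#'   [simulate_odometry()]).
#' @param segment_length,sensing_distance,intensity Boundary-memory
#'   parameters (see [boundary_memory()]); regions must be short relative to
#'   the physical period or the remembered average washes out.
#' @param injection_duration Corrective injection window per band entry, in
#'   seconds.
#' @param n_cells,lambda,k,tau,dt Plate size parameters; the defaults use a
#'   reduced plate to keep the study fast.
#' @param report_every Error series are reported at this time spacing
#'   (seconds).
#' @param seed Base seed.
#'
#' @return A list with `series` (tibble `seed`, `t`, `method`, `error`) and
#'   `summary` (tibble per seed and method: `rmse`, `final_error`,
#'   `late_mean` over the last quarter, `early_mean` over the first quarter
#'   after initial contacts).
#' @export
run_boundary_comparison <- function(n_seeds = 10L, duration = 1000,
                                    roam_arena = arena(2, 2), period = 2,
                                    speed_noise_sd = 0.2,
                                    heading_noise_sd = 0.1,
                                    segment_length = 0.1,
                                    sensing_distance = 0.1, intensity = 1000,
                                    injection_duration = 0.1,
                                    n_cells = 180L, lambda = 60, k = 6,
                                    tau = 0.02, dt = 0.004,
                                    report_every = 10, seed = 1L) {
  base_plate <- stripe_plate(n_cells = n_cells, lambda = lambda, k = k,
                             tau = tau, dt = dt)
  cal <- make_calibrated_plates(pi / 6 + c(0, 2, 4) * pi / 6, period,
                                seed = seed, plate = base_plate)
  plates <- cal$plates
  series <- list()
  summary <- list()
  for (i in seq_len(n_seeds)) {
    sd_i <- seed + 1000L + i
    truth <- generate_random_walk(roam_arena, duration = duration,
                                  seed = sd_i)
    odo <- simulate_odometry(truth, speed_noise_sd, heading_noise_sd,
                             seed = sd_i + 1L)
    tracks_corr <- vector("list", 3)
    tracks_raw <- vector("list", 3)
    for (l in 1:3) {
      mem <- boundary_memory(roam_arena, plates[[l]]$n_cells,
                             segment_length = segment_length,
                             sensing_distance = sensing_distance,
                             intensity = intensity)
      rb <- run_plate_with_boundary(plates[[l]], mem, odo, positions = truth,
                                    learn = TRUE, correct = TRUE,
                                    injection_duration = injection_duration)
      tracks_corr[[l]] <- rb$track
      tracks_raw[[l]] <- run_plate(plates[[l]], odo)$track
    }
    origin <- c(truth$x[1], truth$y[1])
    xy_corr <- phases_to_positions(tracks_corr, plates, origin)
    xy_raw <- phases_to_positions(tracks_raw, plates, origin)
    keep <- seq(1, nrow(truth), by = max(1L, as.integer(report_every / diff(truth$t[1:2]))))
    err <- function(xy) sqrt((xy[, 1] - truth$x)^2 + (xy[, 2] - truth$y)^2)
    e_corr <- err(xy_corr)
    e_raw <- err(xy_raw)
    e_odo <- sqrt((odo$x - truth$x)^2 + (odo$y - truth$y)^2)
    series[[i]] <- tibble(
      seed = sd_i,
      t = rep(truth$t[keep], 3),
      method = rep(c("corrected", "uncorrected", "odometry"),
                   each = length(keep)),
      error = c(e_corr[keep], e_raw[keep], e_odo[keep])
    )
    qtr <- function(e, which) {
      n <- length(e)
      idx <- if (which == "early") seq_len(n %/% 4) + n %/% 8 else (n - n %/% 4):n
      mean(e[idx])
    }
    summary[[i]] <- tibble(
      seed = sd_i,
      method = c("corrected", "uncorrected", "odometry"),
      rmse = c(sqrt(mean(e_corr^2)), sqrt(mean(e_raw^2)), sqrt(mean(e_odo^2))),
      final_error = c(e_corr[length(e_corr)], e_raw[length(e_raw)],
                      e_odo[length(e_odo)]),
      early_mean = c(qtr(e_corr, "early"), qtr(e_raw, "early"), qtr(e_odo, "early")),
      late_mean = c(qtr(e_corr, "late"), qtr(e_raw, "late"), qtr(e_odo, "late"))
    )
  }
  list(
    series = dplyr::bind_rows(series),
    summary = dplyr::bind_rows(summary),
    calibration = cal$calibration
  )
}

#' End-to-end spatial-cognition run
#'
#' The full pipeline at desk scale: a random roam in a walled arena is
#' encoded by the head-direction ring, integrated by three stripe plates per
#' grid scale (periods in a geometric progression from `lambda0`), corrected
#' at wall contacts through boundary-cell memories, assembled into grid-cell
#' populations, and read out both continuously (from the unwrapped stripe
#' phases) and at checkpoints by the multi-scale maximum-likelihood decoder,
#' ending in a place-cell response. A noisy dead-reckoned odometry path is
#' produced for comparison.
#'
#' @param duration Roam duration in seconds.
#' @param roam_arena Arena; default 10 m x 10 m.
#' @param lambda0 Coarsest grid period in meters (should cover the arena).
#' @param ratio Scale ratio.
#' @param n_scales Number of grid scales.
#' @param cells_side Cells per side of each decoded grid module.
#' @param speed_noise_sd,heading_noise_sd Odometry noise fed to the plates.
#' @param boundary_correction Enable boundary learning/correction.
#' @param segment_length,sensing_distance,intensity Boundary parameters.
#' @param n_cells,lambda,k,tau,dt Plate parameters (reduced-size default).
#' @param decode_every Checkpoint spacing in seconds for the ML decode.
#' @param n_max,kappa Decoder module parameters.
#' @param place_spacing,place_delta2 Place-cell field grid parameters;
#'   `place_delta2` defaults to `(lambda_min / 10)^2` m^2.
#' @param start Roam start position; the default near the arena corner keeps
#'   the exploration in the boundary area, so wall contacts (and hence
#'   boundary-cell learning and correction) occur from the beginning.
#' @param roam_band Width in meters of the boundary band the roam is
#'   confined to (the agent explores the boundary area of the arena); NULL
#'   roams the whole arena.
#' @param seed Base seed.
#' @param outdir If non-NULL, writes the trajectory, odometry, decoded path
#'   and boundary events there as delimited text.
#'
#' @return A list: `trajectory`, `odometry`, `decoded` (tibble `t`,
#'   `x_true`, `y_true`, `x_hat`, `y_hat`, `error`), `checkpoints` (tibble
#'   with the ML decode per checkpoint), `place` (place-cell response at the
#'   final checkpoint), `errors` (named list of [error_statistics()] for the
#'   attractor path and odometry), `config`.
#' @export
run_full_cognition <- function(duration = 500, roam_arena = arena(10, 10),
                               lambda0 = 10, ratio = 1.5, n_scales = 3L,
                               cells_side = 50L,
                               speed_noise_sd = 0.2, heading_noise_sd = 0.1,
                               boundary_correction = TRUE,
                               segment_length = 0.5, sensing_distance = 0.2,
                               intensity = 1000,
                               n_cells = 180L, lambda = 60, k = 6,
                               tau = 0.01, dt = 0.002,
                               decode_every = 50, n_max = 10, kappa = 3,
                               place_spacing = 1, place_delta2 = NULL,
                               start = c(1, 1), roam_band = 1.5,
                               seed = 1L, outdir = NULL) {
  lambdas <- lambda0 / ratio^(0:(n_scales - 1L))
  place_delta2 <- place_delta2 %||% (min(lambdas) / 10)^2
  base_plate <- stripe_plate(n_cells = n_cells, lambda = lambda, k = k,
                             tau = tau, dt = dt)
  thetas <- pi / 6 + c(0, 2, 4) * pi / 6
  cal <- make_calibrated_plates(thetas, lambdas[1], seed = seed,
                                plate = base_plate)

  truth <- generate_random_walk(roam_arena, duration = duration,
                                seed = seed + 10L, start = start,
                                exclude_interior = roam_band)
  odo <- simulate_odometry(truth, speed_noise_sd, heading_noise_sd,
                           seed = seed + 11L)
  events <- detect_boundary_events(truth, roam_arena,
                                   sensing_distance = sensing_distance,
                                   segment_length = segment_length)

  # one plate per (scale, direction); scale m realises period lambdas[m]
  plates <- list()
  tracks <- list()
  for (m in seq_len(n_scales)) {
    for (l in 1:3) {
      p <- cal$plates[[l]]
      p <- set_plate_period(p, lambdas[m])
      idx <- (m - 1L) * 3L + l
      if (boundary_correction) {
        mem <- boundary_memory(roam_arena, p$n_cells,
                               segment_length = segment_length,
                               sensing_distance = sensing_distance,
                               intensity = intensity)
        rb <- run_plate_with_boundary(p, mem, odo, positions = truth)
        plates[[idx]] <- rb$plate
        tracks[[idx]] <- rb$track
      } else {
        rp <- run_plate(p, odo)
        plates[[idx]] <- rp$plate
        tracks[[idx]] <- rp$track
      }
    }
  }

  origin <- c(truth$x[1], truth$y[1])
  # continuous readout from the finest scale's plates (largest phase gain)
  fin <- (n_scales - 1L) * 3L + 1:3
  xy <- phases_to_positions(tracks[fin], plates[fin], origin)
  decoded <- tibble(
    t = truth$t, x_true = truth$x, y_true = truth$y,
    x_hat = xy[, 1], y_hat = xy[, 2],
    error = sqrt((xy[, 1] - truth$x)^2 + (xy[, 2] - truth$y)^2)
  )

  # checkpoint ML decode from assembled grid populations
  modules <- purrr::map(lambdas, grid_module, cells_side = cells_side,
                        n_max = n_max, kappa = kappa)
  dt_samp <- diff(truth$t[1:2])
  ck_idx <- seq(1, nrow(truth), by = max(1L, as.integer(decode_every / dt_samp)))
  ck <- purrr::map_dfr(ck_idx, function(i) {
    rates <- purrr::map(seq_len(n_scales), function(m) {
      pls <- plates[(m - 1L) * 3L + 1:3]
      # plate states at checkpoint i are only stored for the final time;
      # assemble from the phase tracks instead: shift the stored profile to
      # the tracked phase at t_i
      pls <- purrr::map2(pls, tracks[(m - 1L) * 3L + 1:3], function(p, tr) {
        shift <- tr$phase_unwrapped[i] - tr$phase_unwrapped[nrow(tr)]
        prof <- interp_periodic(p$s, (seq_len(p$n_cells) - 1L) - shift)
        p$s <- prof
        p
      })
      superpose_stripes(pls, modules[[m]])
    })
    est <- decode_multiscale(rates, modules)
    tibble(
      t = truth$t[i], x_true = truth$x[i], y_true = truth$y[i],
      x_ml = est$x[1], y_ml = est$x[2], decodable = est$decodable
    )
  })
  # align the ML decode's arbitrary common offset (pattern phase origin) on
  # the first checkpoint, and resolve each estimate's lattice branch with the
  # continuous phase readout
  # the decoded pattern's phase origin is arbitrary; anchor it on the known
  # start position (dead reckoning initialises the same way)
  A0 <- modules[[1]]$A
  off <- c(ck$x_ml[1] - truth$x[1], ck$y_ml[1] - truth$y[1])
  ck$x_ml <- ck$x_ml - off[1]
  ck$y_ml <- ck$y_ml - off[2]
  for (j in seq_len(nrow(ck))) {
    ref <- c(decoded$x_hat[ck_idx[j]], decoded$y_hat[ck_idx[j]])
    v <- c(ck$x_ml[j], ck$y_ml[j]) - ref
    v <- lattice_min_image(v, A0)
    ck$x_ml[j] <- ref[1] + v[1]
    ck$y_ml[j] <- ref[2] + v[2]
  }
  ck$error <- sqrt((ck$x_ml - ck$x_true)^2 + (ck$y_ml - ck$y_true)^2)

  fields <- place_field_grid(roam_arena, spacing = place_spacing)
  place <- place_response(fields,
                          c(ck$x_ml[nrow(ck)], ck$y_ml[nrow(ck)]),
                          delta2 = place_delta2)

  errors <- list(
    bionic = error_statistics(truth, dplyr::rename(decoded,
                                                   x = "x_hat", y = "y_hat")[, c("t", "x", "y")]),
    odometry = error_statistics(truth, odo[, c("t", "x", "y")])
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(truth, file.path(outdir, "trajectory.csv"))
    write_trajectory(odo, file.path(outdir, "odometry.csv"))
    write_boundary_events(events, file.path(outdir, "boundary_events.csv"))
    readr::write_csv(decoded, file.path(outdir, "decoded.csv"))
    readr::write_csv(ck, file.path(outdir, "checkpoints.csv"))
  }

  list(
    trajectory = truth, odometry = odo, events = events, decoded = decoded,
    checkpoints = ck, place = place, errors = errors,
    calibration = cal$calibration,
    config = list(
      duration = duration, arena = roam_arena, lambda0 = lambda0,
      ratio = ratio, n_scales = n_scales, cells_side = cells_side,
      speed_noise_sd = speed_noise_sd, heading_noise_sd = heading_noise_sd,
      boundary_correction = boundary_correction, seed = seed,
      plate = list(n_cells = n_cells, lambda = lambda, k = k, tau = tau,
                   dt = dt)
    )
  )
}
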