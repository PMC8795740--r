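#' Boundary-cell memory for a stripe plate
#'
#' Boundary cells fire when the agent is within sensing distance of a
#' perimeter region of the arena. On the first visit to a region the
#' time-averaged stripe-cell firing profile is memorised as synaptic weights
#' from that boundary cell onto the plate (`W_id`, the occupancy-averaged
#' rate of cell `i` over the visit, scaled by `1/N`). On later visits the
#' remembered profile is injected back into the plate dynamics
#' ([corrective_step()]), pulling the pattern phase towards the remembered
#' phase for that region and cancelling accumulated path-integration drift.
#'
#' @param arena An [arena()].
#' @param n_cells Number of cells on the plate this memory corrects.
#' @param segment_length Target perimeter region length in meters.
#' @param sensing_distance Wall sensing distance in meters.
#' @param intensity Activation intensity `c` of an active boundary cell;
#'   it must exceed the pattern's inhibition depth divided by the learned
#'   weight scale to re-activate suppressed cells; the default snaps a
#'   quarter-period offset back within tens of milliseconds, comfortably
#'   inside a 500 ms contact.
#'
#' @return An object of class `gp_boundary_memory` with the region table,
#'   the `n_cells x n_regions` weight matrix `W` (non-negative, nonzero only
#'   for visited regions), and a `learned` flag per region.
#' @export
boundary_memory <- function(arena, n_cells, segment_length = 1,
                            sensing_distance = 0.2, intensity = 1000) {
  if (!inherits(arena, "gp_arena")) abort("`arena` must be created with arena().")
  stopifnot_scalar_number(sensing_distance, "sensing_distance", positive = TRUE)
  stopifnot_scalar_number(intensity, "intensity", positive = TRUE)
  segs <- boundary_segments(arena, segment_length)
  n_cells <- as.integer(n_cells)
  structure(
    list(
      arena = arena, segments = segs, n_regions = nrow(segs),
      N = n_cells,
      W = matrix(0, n_cells, nrow(segs)),
      learned = rep(FALSE, nrow(segs)),
      intensity = intensity,
      sensing_distance = sensing_distance,
      segment_length = segment_length
    ),
    class = "gp_boundary_memory"
  )
}

#' @export
print.gp_boundary_memory <- function(x, ...) {
  cat(sprintf(
    "<boundary memory: %d perimeter regions (%g m arena walls), %d learned, intensity %g>\n",
    x$n_regions, x$segment_length, sum(x$learned), x$intensity
  ))
  invisible(x)
}

#' Boundary-cell activations at a position
#'
#' Region `d` is active (value `c`, the memory's intensity) when the position
#' lies within the sensing distance of its perimeter segment, else 0. Near a
#' corner two adjacent regions are active at once.
#'
#' @param memory A [boundary_memory()].
#' @param position Length-2 position in meters.
#'
#' @return Numeric vector `B_d` of length `n_regions`, values in
#'   `{0, intensity}`.
#' @export
activate_boundary_cells <- function(memory, position) {
  if (!inherits(memory, "gp_boundary_memory")) {
    abort("`memory` must be a boundary_memory().")
  }
  position <- as.numeric(position)
  s <- memory$segments
  d <- point_segment_distance(position[1], position[2], s$x0, s$y0, s$x1, s$y1)
  memory$intensity * (d$dist <= memory$sensing_distance)
}

#' Learn boundary weights from a region visit
#'
#' Stores `W_id = mean_t(rate_i(t)) / N` over the rate samples collected
#' while the agent was inside region `d`'s sensing band — the discrete
#' occupancy average of the firing integral over the region. Only the first
#' visit is learned unless `update = TRUE`.
#'
#' @param memory A [boundary_memory()].
#' @param region Region index.
#' @param rate_samples Matrix of plate rates, `n_cells x n_samples` (a single
#'   vector is accepted).
#' @param update Overwrite an already-learned region?
#'
#' @return The updated memory.
#' @export
learn_boundary_weights <- function(memory, region, rate_samples,
                                   update = FALSE) {
  if (!inherits(memory, "gp_boundary_memory")) {
    abort("`memory` must be a boundary_memory().")
  }
  if (region < 1 || region > memory$n_regions) abort("Unknown region index.")
  if (is.null(rate_samples) || length(rate_samples) == 0L) {
    abort("No rate samples collected for this visit.")
  }
  if (is.null(dim(rate_samples))) rate_samples <- matrix(rate_samples, ncol = 1L)
  if (nrow(rate_samples) != memory$N) {
    abort("`rate_samples` rows must match the plate's cell count.")
  }
  if (memory$learned[region] && !update) {
    return(memory)
  }
  memory$W[, region] <- rowMeans(rate_samples) / memory$N
  memory$learned[region] <- TRUE
  memory
}

#' Stripe-plate step with boundary-cell corrective input
#'
#' The plate dynamics extended with the remembered boundary drive:
#' `tau ds/dt + s = f(W s + B + sum_d W_id B_d)`. With all activations zero
#' this is exactly [step_dynamics()]; with an active, learned region the
#' injected profile pulls the pattern phase towards the phase remembered for
#' that region (drift beyond half a period aliases to the wrong branch and
#' cannot be corrected).
#'
#' @inheritParams step_dynamics
#' @param memory A [boundary_memory()] for this plate.
#' @param activations Boundary activation vector `B_d` from
#'   [activate_boundary_cells()].
#'
#' @return The updated plate.
#' @export
corrective_step <- function(plate, memory, activations, velocity = c(0, 0),
                            dt = plate$dt, n_steps = 1L) {
  if (!inherits(memory, "gp_boundary_memory")) {
    abort("`memory` must be a boundary_memory().")
  }
  if (length(activations) != memory$n_regions) {
    abort("`activations` length must equal the number of regions.")
  }
  inject <- as.vector(memory$W %*% activations)
  step_dynamics(plate, velocity = velocity, dt = dt, n_steps = n_steps,
                inject = inject)
}

#' Drive a plate along a trajectory with boundary learning and correction
#'
#' Integrates the plate sample by sample. The drive comes from the
#' trajectory's speed/heading commands (for a drifting run, pass the noisy
#' odometry series); wall sensing uses `positions` — the agent's actual
#' position (ground truth), as an onboard rangefinder would. While inside an
#' unlearned region's band the plate rates are collected and memorised on
#' exit; inside a learned region's band the remembered profile is injected
#' (when `correct = TRUE`), implementing the drift-correction loop.
#'
#' Corrective injection is applied for a fixed window (`injection_duration`)
#' at each entry into a learned region's band: the strong remembered drive
#' snaps the pattern to the remembered phase within tens of milliseconds,
#' and the phase track is bridged across the injection window by
#' nearest-branch continuation (a correction is only valid for drift below
#' half a period; beyond that it aliases to the wrong branch).
#'
#' @inheritParams run_plate
#' @param memory A [boundary_memory()] sized for this plate.
#' @param positions Optional tibble/matrix with the true `x`, `y` per sample;
#'   defaults to the trajectory's own positions.
#' @param learn,correct Enable first-visit learning / corrective injection.
#' @param snapshot_learning Memorise only the profile at the first sample of
#'   the visit instead of the occupancy average (a sharper reference when
#'   the band is wide relative to the pattern period).
#' @param max_learn_samples Cap on the number of rate samples averaged per
#'   region visit; a long wandering first visit would otherwise smear the
#'   remembered phase over the path travelled in-band.
#' @param injection_duration Length of each corrective injection window in
#'   seconds (rounded up to whole trajectory samples).
#' @param record_splits Phase records per trajectory sample (see
#'   [run_plate()]); records inside an injection window are skipped so the
#'   snap transient cannot corrupt the unwrapped track.
#'
#' @return A list with `plate`, `memory`, and `track` (tibble `t`, `phase`,
#'   `phase_unwrapped`, `injected` flag).
#' @export
run_plate_with_boundary <- function(plate, memory, traj, positions = NULL,
                                    learn = TRUE, correct = TRUE,
                                    injection_duration = 0.1,
                                    snapshot_learning = FALSE,
                                    max_learn_samples = 5L,
                                    record_splits = 2L) {
  check_plate(plate)
  check_trajectory(traj)
  if (!inherits(memory, "gp_boundary_memory")) {
    abort("`memory` must be a boundary_memory().")
  }
  if (memory$N != plate$n_cells) {
    abort("`memory` was built for a different plate size.")
  }
  n <- nrow(traj)
  if (n < 2L) abort("`traj` must have at least 2 samples.")
  dt_samp <- diff(traj$t)
  if (max(abs(dt_samp - dt_samp[1])) > 1e-9) {
    abort("`traj` must be uniformly sampled.")
  }
  pos <- if (is.null(positions)) {
    cbind(traj$x, traj$y)
  } else if (is.data.frame(positions)) {
    cbind(positions$x, positions$y)
  } else {
    as_xy_matrix(positions, "positions")
  }
  if (nrow(pos) != n) abort("`positions` must have one row per trajectory sample.")

  record_splits <- max(1L, as.integer(record_splits))
  nsub <- max(1L, as.integer(ceiling(dt_samp[1] / plate$dt / record_splits - 1e-9)))
  dt_eff <- dt_samp[1] / (record_splits * nsub)
  if (dt_eff > plate$tau / 5 * 1.0001) {
    abort("Trajectory sampling too coarse for the plate's Euler step.")
  }
  proj <- plate$velocity_scale * traj$speed * cos(traj$heading - plate$theta)

  visit_samples <- vector("list", memory$n_regions)
  n_rec <- (n - 1L) * record_splits + 1L
  phase_fine <- numeric(n_rec)
  rec_valid <- rep(TRUE, n_rec)
  phase_fine[1] <- phase_of_profile(plate$s, plate$lambda)
  injected <- logical(n)
  s <- plate$s
  zero <- numeric(plate$n_cells)
  w <- exp(2i * pi * (seq_len(plate$n_cells) - 1L) / plate$lambda)
  active_prev <- rep(FALSE, memory$n_regions)
  inj_samples <- max(1L, as.integer(ceiling(injection_duration / dt_samp[1] - 1e-9)))
  inj_left <- 0L
  in_corrected_band <- FALSE

  for (i in seq_len(n - 1L)) {
    act <- activate_boundary_cells(memory, pos[i, ])
    on <- act > 0
    live <- on & memory$learned
    if (correct) {
      if (any(live) && !in_corrected_band) {
        # entry into a learned band: trigger one injection window
        inj_left <- inj_samples
        in_corrected_band <- TRUE
      } else if (!any(live)) {
        in_corrected_band <- FALSE
      }
    }
    inject <- zero
    if (inj_left > 0L && any(live)) {
      inject <- as.vector(memory$W[, live, drop = FALSE] %*% act[live])
      injected[i] <- TRUE
      inj_left <- inj_left - 1L
    }
    for (r in seq_len(record_splits)) {
      s <- as.vector(can_step_cpp(plate$W, s, plate$e, plate$alpha, proj[i],
                                  inject, dt_eff, plate$tau, nsub))
      ri <- (i - 1L) * record_splits + r + 1L
      z <- sum(s * w)
      phase_fine[ri] <- pmod(Arg(z) * plate$lambda / (2 * pi), plate$lambda)
      # drop mid-snap records (keep the final record of an injected sample
      # only when the snap has settled, i.e. the window's last sample)
      if (injected[i] && !(inj_left == 0L && r == record_splits)) {
        rec_valid[ri] <- FALSE
      }
    }
    if (learn) {
      cap <- if (snapshot_learning) 1L else max_learn_samples
      for (d in which(on & !memory$learned)) {
        if (length(visit_samples[[d]]) < cap) {
          visit_samples[[d]] <- c(visit_samples[[d]], list(s))
        }
      }
      # a visit ends when the band is left: consolidate the averaged profile
      ended <- which(active_prev & !on)
      for (d in ended) {
        if (!memory$learned[d] && length(visit_samples[[d]]) > 0) {
          memory <- learn_boundary_weights(
            memory, d, do.call(cbind, visit_samples[[d]])
          )
          visit_samples[[d]] <- list()
        }
      }
    }
    active_prev <- on
  }
  if (learn) {
    for (d in which(active_prev & !memory$learned)) {
      if (length(visit_samples[[d]]) > 0) {
        memory <- learn_boundary_weights(
          memory, d, do.call(cbind, visit_samples[[d]])
        )
      }
    }
  }
  plate$s <- s
  # unwrap over valid records only, then place values back on the full grid
  pu <- rep(NA_real_, n_rec)
  pu[rec_valid] <- unwrap_phase(phase_fine[rec_valid], plate$lambda)
  # samples whose end record was skipped inherit the last valid value
  pu <- cummax_na_fill(pu)
  keep <- 1L + record_splits * (0:(n - 1L))
  track <- tibble(
    t = traj$t,
    phase = pmod(pu[keep], plate$lambda),
    phase_unwrapped = pu[keep],
    injected = injected
  )
  list(plate = plate, memory = memory, track = track)
}

# carry the last non-NA value forward (first entries are never NA here)
cummax_na_fill <- function(x) {
  idx <- cumsum(!is.na(x))
  x[!is.na(x)][pmax(idx, 1L)]
}
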