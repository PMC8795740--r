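#' Rectangular arena
#'
#' A bounded rectangular arena with its origin at the lower-left corner, the
#' environment in which all synthetic trajectories live. Boundary segments and
#' boundary-cell regions are defined on its perimeter.
#'
#' @param width,height Arena dimensions in meters; both must be positive.
#'
#' @return An object of class `gp_arena` with fields `width` and `height`.
#' @examples
#' arena(10, 10)
#' @export
arena <- function(width, height) {
  stopifnot_scalar_number(width, "width", positive = TRUE)
  stopifnot_scalar_number(height, "height", positive = TRUE)
  structure(list(width = width, height = height), class = "gp_arena")
}

#' @export
print.gp_arena <- function(x, ...) {
  cat(sprintf("<arena %g m x %g m, origin at lower-left>\n", x$width, x$height))
  invisible(x)
}

in_arena <- function(x, y, arena) {
  x >= 0 & x <= arena$width & y >= 0 & y <= arena$height
}

#' Generate a random-roam trajectory
#'
#' Simulates an agent roaming a bounded arena: at each time step the speed is
#' drawn uniformly from `speed_range` and the heading is incremented by a
#' uniform draw from `heading_step_range`, imitating a rat's irregular free
#' exploration. Steps that would leave the arena trigger a uniform resampling
#' of the heading until the step stays inside, so the speed distribution is
#' unaffected by wall handling.
#'
#' Row `i` holds the position at `t[i]` together with the speed/heading
#' command applied over `[t[i], t[i+1])`; the final row repeats the last
#' command. Dead-reckoning the commands therefore reproduces the positions
#' exactly (see [simulate_odometry()]).
#'
#' @param arena An [arena()].
#' @param duration Total simulated time in seconds (`>= 0`).
#' @param dt Time step in seconds (`> 0`).
#' @param speed_range Length-2 numeric, the uniform speed range in m/s.
#' @param heading_step_range Length-2 numeric, the uniform per-step heading
#'   increment range in radians.
#' @param seed Integer seed; identical seeds give identical series.
#' @param start Optional length-2 start position in meters; defaults to the
#'   arena centre.
#' @param exclude_interior Optional margin in meters: when set, the roam is
#'   confined to the band within this distance of the perimeter (the
#'   "boundary area"), with steps into the interior resampled like wall
#'   hits.
#'
#' @return A tibble with columns `t`, `x`, `y`, `speed`, `heading` (heading in
#'   `(-pi, pi]`, counter-clockwise from the +x axis).
#' @examples
#' traj <- generate_random_walk(arena(1, 1), duration = 10, seed = 1)
#' head(traj)
#' @export
generate_random_walk <- function(arena, duration, dt = 0.1,
                                 speed_range = c(0, 0.5),
                                 heading_step_range = c(-pi / 2, pi / 2),
                                 seed = 1L, start = NULL,
                                 exclude_interior = NULL) {
  if (!inherits(arena, "gp_arena")) abort("`arena` must be created with arena().")
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0) {
    abort("`duration` must be a single number >= 0.")
  }
  if (length(speed_range) != 2L || any(speed_range < 0) || diff(speed_range) < 0) {
    abort("`speed_range` must be an increasing interval within [0, Inf).")
  }
  if (length(heading_step_range) != 2L || diff(heading_step_range) < 0) {
    abort("`heading_step_range` must be an increasing interval.")
  }
  start <- start %||% c(arena$width / 2, arena$height / 2)
  if (!all(in_arena(start[1], start[2], arena))) abort("`start` lies outside the arena.")
  valid <- function(x, y) {
    ok <- in_arena(x, y, arena)
    if (!is.null(exclude_interior)) {
      m <- exclude_interior
      inner <- x > m & x < arena$width - m & y > m & y < arena$height - m
      ok <- ok & !inner
    }
    ok
  }
  if (!valid(start[1], start[2])) abort("`start` lies inside the excluded interior.")

  n_steps <- as.integer(round(duration / dt))
  n <- n_steps + 1L
  x <- y <- speed <- heading <- numeric(n)
  withr::with_seed(seed, {
    x[1] <- start[1]
    y[1] <- start[2]
    h <- runif(1, -pi, pi)
    if (n_steps == 0L) {
      speed[1] <- 0
      heading[1] <- wrap_angle(h)
    } else {
      for (i in seq_len(n_steps)) {
        v <- runif(1, speed_range[1], speed_range[2])
        h <- wrap_angle(h + runif(1, heading_step_range[1], heading_step_range[2]))
        nx <- x[i] + v * dt * cos(h)
        ny <- y[i] + v * dt * sin(h)
        tries <- 0L
        while (!valid(nx, ny) && tries < 100L) {
          h <- runif(1, -pi, pi)
          nx <- x[i] + v * dt * cos(h)
          ny <- y[i] + v * dt * sin(h)
          tries <- tries + 1L
        }
        if (!valid(nx, ny)) {
          # pathological case: stay put for this step
          nx <- x[i]
          ny <- y[i]
        }
        speed[i] <- v
        heading[i] <- h
        x[i + 1] <- nx
        y[i + 1] <- ny
      }
      speed[n] <- speed[n - 1L]
      heading[n] <- heading[n - 1L]
    }
  })
  tibble(
    t = seq(0, by = dt, length.out = n),
    x = x, y = y, speed = speed, heading = heading
  )
}

check_trajectory <- function(traj, arg = "traj") {
  need <- c("t", "x", "y", "speed", "heading")
  if (!is.data.frame(traj) || !all(need %in% names(traj))) {
    abort(sprintf("`%s` must have columns %s.", arg, paste(need, collapse = ", ")))
  }
  if (nrow(traj) > 1L && any(diff(traj$t) <= 0)) {
    bad <- which(diff(traj$t) <= 0)[1] + 1L
    abort(sprintf("`%s` has non-increasing time at row %d.", arg, bad))
  }
  invisible(traj)
}

#' Dead-reckoned odometry baseline
#'
#' Re-integrates a trajectory's per-step speed and heading commands after
#' independent Gaussian perturbation, producing the drifting path a wheel
#' encoder/compass odometer would report. With zero noise the output equals
#' the input path exactly, so this doubles as the noiseless dead-reckoning
#' consistency check.
#'
#' @param traj A trajectory tibble from [generate_random_walk()].
#' @param speed_noise_sd Standard deviation of the multiplicative speed
#'   perturbation, as a fraction of each step's speed (`>= 0`).
#' @param heading_noise_sd Standard deviation of the additive heading
#'   perturbation in radians (`>= 0`).
#' @param seed Integer seed.
#'
#' @return A trajectory tibble of the same length whose `x`, `y` are the
#'   dead-reckoned positions and whose `speed`, `heading` are the perturbed
#'   commands.
#' @examples
#' truth <- generate_random_walk(arena(2, 2), duration = 10, seed = 1)
#' odo <- simulate_odometry(truth, 0.1, 0.05, seed = 2)
#' @export
simulate_odometry <- function(traj, speed_noise_sd = 0.1,
                              heading_noise_sd = 0.05, seed = 1L) {
  check_trajectory(traj)
  if (speed_noise_sd < 0 || heading_noise_sd < 0) {
    abort("Noise standard deviations must be >= 0.")
  }
  n <- nrow(traj)
  if (n == 0L) abort("`traj` is empty.")
  speed <- traj$speed
  heading <- traj$heading
  if (speed_noise_sd > 0 || heading_noise_sd > 0) {
    withr::with_seed(seed, {
      speed <- pmax(0, speed * (1 + rnorm(n, 0, speed_noise_sd)))
      heading <- wrap_angle(heading + rnorm(n, 0, heading_noise_sd))
    })
  }
  x <- y <- numeric(n)
  x[1] <- traj$x[1]
  y[1] <- traj$y[1]
  if (n > 1L) {
    dt <- diff(traj$t)
    # a uniformly sampled series integrates with the exact scalar step, and
    # the running sum mirrors the generator's sequential updates so that a
    # zero-noise dead-reckoning reproduces the generator bitwise (cumsum's
    # extended-precision accumulator would not)
    if (max(abs(dt - dt[1])) < 1e-9) dt <- rep(dt[1], n - 1L)
    for (i in 2:n) {
      x[i] <- x[i - 1L] + speed[i - 1L] * dt[i - 1L] * cos(heading[i - 1L])
      y[i] <- y[i - 1L] + speed[i - 1L] * dt[i - 1L] * sin(heading[i - 1L])
    }
  }
  tibble(t = traj$t, x = x, y = y, speed = speed, heading = heading)
}

# Perimeter segments of an arena, walked counter-clockwise from the origin.
# `segment_length` is a target; the perimeter is divided evenly into
# round(perimeter / segment_length) segments (at least 4).
boundary_segments <- function(arena, segment_length = 1) {
  per <- 2 * (arena$width + arena$height)
  n_seg <- as.integer(round(per / segment_length))
  if (n_seg < 4L) {
    abort("`segment_length` must divide the perimeter into at least 4 segments.")
  }
  s0 <- (seq_len(n_seg) - 1L) * per / n_seg
  s1 <- seq_len(n_seg) * per / n_seg
  p0 <- perimeter_point(s0, arena)
  p1 <- perimeter_point(s1, arena)
  tibble(
    segment_id = seq_len(n_seg),
    x0 = p0$x, y0 = p0$y, x1 = p1$x, y1 = p1$y
  )
}

# Map perimeter arclength (CCW from the origin) to a point.
perimeter_point <- function(s, arena) {
  w <- arena$width
  h <- arena$height
  per <- 2 * (w + h)
  s <- pmod(s, per)
  x <- y <- numeric(length(s))
  b <- s < w
  x[b] <- s[b]; y[b] <- 0
  r <- s >= w & s < w + h
  x[r] <- w; y[r] <- s[r] - w
  tp <- s >= w + h & s < 2 * w + h
  x[tp] <- w - (s[tp] - w - h); y[tp] <- h
  l <- s >= 2 * w + h
  x[l] <- 0; y[l] <- h - (s[l] - 2 * w - h)
  list(x = x, y = y)
}

# Distance from points to one segment, plus the nearest point on the segment.
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0
  vy <- y1 - y0
  len2 <- vx^2 + vy^2
  tt <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  cx <- x0 + tt * vx
  cy <- y0 + tt * vy
  list(dist = sqrt((px - cx)^2 + (py - cy)^2), cx = cx, cy = cy)
}

#' Detect boundary-contact events along a trajectory
#'
#' Splits the arena perimeter into equal segments and emits one event each
#' time the trajectory enters the sensing band (distance below
#' `sensing_distance`) of a segment, as an ultrasonic rangefinder would report
#' wall contact. A pass through a corner band yields events on both adjacent
#' segments.
#'
#' @inheritParams simulate_odometry
#' @param arena The [arena()] the trajectory lives in.
#' @param sensing_distance Wall sensing distance in meters (`> 0`).
#' @param segment_length Target perimeter segment length in meters; the
#'   perimeter is divided evenly into at least 4 segments.
#'
#' @return A tibble with columns `t`, `segment_id`, `cx`, `cy` (the contact
#'   point on the segment), ordered by time.
#' @examples
#' traj <- generate_random_walk(arena(2, 2), duration = 60, seed = 1)
#' detect_boundary_events(traj, arena(2, 2))
#' @export
detect_boundary_events <- function(traj, arena, sensing_distance = 0.2,
                                   segment_length = 1) {
  check_trajectory(traj)
  stopifnot_scalar_number(sensing_distance, "sensing_distance", positive = TRUE)
  segs <- boundary_segments(arena, segment_length)
  out <- purrr::pmap_dfr(segs, function(segment_id, x0, y0, x1, y1) {
    d <- point_segment_distance(traj$x, traj$y, x0, y0, x1, y1)
    active <- d$dist <= sensing_distance
    entry <- which(active & !dplyr::lag(active, default = FALSE))
    tibble(
      t = traj$t[entry], segment_id = segment_id,
      cx = d$cx[entry], cy = d$cy[entry]
    )
  })
  dplyr::arrange(out, .data$t, .data$segment_id)
}

#' Read and write trajectory and boundary-event files
#'
#' Trajectories are exchanged as UTF-8 comma-delimited text with a header row
#' naming the columns `t,x,y,speed,heading`; boundary events use
#' `t,segment_id,cx,cy`. Doubles are written with enough digits to
#' round-trip exactly.
#'
#' @param traj,events The tibble to write.
#' @param path File path.
#'
#' @return `read_trajectory()` / `read_boundary_events()` return the parsed
#'   tibble; malformed files (missing columns, non-monotone time) raise an
#'   error naming the offending line. The writers return the input invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' traj <- generate_random_walk(arena(1, 1), duration = 1, seed = 1)
#' write_trajectory(traj, f)
#' identical(read_trajectory(f), traj)
#' @export
write_trajectory <- function(traj, path) {
  check_trajectory(traj)
  cols <- c("t", "x", "y", "speed", "heading")
  # print with 17 significant digits so every double round-trips exactly
  chr <- purrr::map_dfc(traj[, cols], function(v) sprintf("%.17g", v))
  names(chr) <- cols
  readr::write_csv(chr, path, quote = "none")
  invisible(traj)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  # parse as text and convert with R's correctly rounded strtod so that
  # write_trajectory()'s 17-digit output round-trips bit for bit
  traj <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("t", "x", "y", "speed", "heading")
  if (!all(need %in% names(traj))) {
    abort(sprintf(
      "Line 1 of '%s': header must name columns %s.",
      path, paste(need, collapse = ", ")
    ))
  }
  traj <- tibble(
    t = as.numeric(traj$t), x = as.numeric(traj$x), y = as.numeric(traj$y),
    speed = as.numeric(traj$speed), heading = as.numeric(traj$heading)
  )
  if (anyNA(traj$t)) {
    abort(sprintf("Line %d of '%s': malformed numeric field.",
                  which(is.na(traj$t))[1] + 1L, path))
  }
  if (nrow(traj) > 1L && any(diff(traj$t) <= 0)) {
    bad <- which(diff(traj$t) <= 0)[1] + 1L
    abort(sprintf("Line %d of '%s': time is not strictly increasing.", bad + 1L, path))
  }
  traj
}

#' @rdname write_trajectory
#' @export
write_boundary_events <- function(events, path) {
  need <- c("t", "segment_id", "cx", "cy")
  if (!is.data.frame(events) || !all(need %in% names(events))) {
    abort("`events` must have columns t, segment_id, cx, cy.")
  }
  chr <- tibble(
    t = sprintf("%.17g", events$t),
    segment_id = sprintf("%d", as.integer(events$segment_id)),
    cx = sprintf("%.17g", events$cx),
    cy = sprintf("%.17g", events$cy)
  )
  readr::write_csv(chr, path, quote = "none")
  invisible(events)
}

#' @rdname write_trajectory
#' @export
read_boundary_events <- function(path) {
  ev <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("t", "segment_id", "cx", "cy")
  if (!all(need %in% names(ev))) {
    abort(sprintf(
      "Line 1 of '%s': header must name columns %s.",
      path, paste(need, collapse = ", ")
    ))
  }
  tibble(t = as.numeric(ev$t), segment_id = as.integer(ev$segment_id),
         cx = as.numeric(ev$cx), cy = as.numeric(ev$cy))
}
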