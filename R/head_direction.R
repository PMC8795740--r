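#' Head-direction cell ring
#'
#' Head-direction cells are arranged on a ring, each with a preferred angle;
#' the population signal jointly encodes the agent's heading and speed. The
#' ring here is a feedforward encoder: cell `i` carries the signed
#' velocity-modulation signal `speed * cos(theta_i - heading)`, which
#' downstream stripe plates use as their velocity drive (their own transfer
#' function rectifies).
#'
#' @param n_cells Number of cells on the ring (`>= 3`); preferred angles are
#'   uniformly spaced on `[0, 2*pi)`.
#'
#' @return An object of class `gp_hd_ring` with fields `n_cells` and `angles`.
#' @examples
#' ring <- head_direction_ring(36)
#' @export
head_direction_ring <- function(n_cells = 36L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 3) {
    abort("`n_cells` must be a single integer >= 3.")
  }
  n_cells <- as.integer(n_cells)
  structure(
    list(n_cells = n_cells, angles = 2 * pi * (seq_len(n_cells) - 1L) / n_cells),
    class = "gp_hd_ring"
  )
}

#' @export
print.gp_hd_ring <- function(x, ...) {
  cat(sprintf("<head-direction ring, %d cells>\n", x$n_cells))
  invisible(x)
}

#' Encode speed and heading on the head-direction ring
#'
#' Cell `i`'s signal is `speed * cos(theta_i - heading)`: maximal for the cell
#' whose preferred angle matches the heading, negative for cells facing the
#' opposite way. The signal is deliberately left unrectified; it is a signed
#' velocity projection, not a firing rate.
#'
#' @param ring A [head_direction_ring()].
#' @param speed Speed in m/s (`>= 0`).
#' @param heading Heading in radians.
#'
#' @return A numeric vector of length `n_cells`.
#' @examples
#' ring <- head_direction_ring(4)
#' encode_velocity(ring, 0.5, 0)
#' @export
encode_velocity <- function(ring, speed, heading) {
  if (!inherits(ring, "gp_hd_ring")) abort("`ring` must be a head_direction_ring().")
  stopifnot_scalar_number(speed, "speed")
  if (speed < 0) abort("`speed` must be >= 0.")
  stopifnot_scalar_number(heading, "heading")
  speed * cos(ring$angles - heading)
}

#' Decode speed and heading from ring signals
#'
#' Population-vector readout: the argument of `sum(rates * exp(1i * theta))`
#' recovers the heading and its modulus (scaled by `2 / n_cells`) the speed.
#' Exact for signals produced by [encode_velocity()]. Used as the module's
#' round-trip oracle.
#'
#' @param ring A [head_direction_ring()] with at least 3 cells.
#' @param rates Numeric vector of per-cell signals.
#'
#' @return A one-row tibble with columns `speed`, `heading`, and `defined`
#'   (`FALSE`, with `heading = NA`, when all signals are zero).
#' @examples
#' ring <- head_direction_ring(36)
#' decode_ring(ring, encode_velocity(ring, 0.3, 1.0))
#' @export
decode_ring <- function(ring, rates) {
  if (!inherits(ring, "gp_hd_ring")) abort("`ring` must be a head_direction_ring().")
  if (length(rates) != ring$n_cells) abort("`rates` length must match the ring.")
  z <- sum(rates * exp(1i * ring$angles))
  if (all(rates == 0) || Mod(z) < 1e-12) {
    return(tibble(speed = 0, heading = NA_real_, defined = FALSE))
  }
  tibble(
    speed = 2 * Mod(z) / ring$n_cells,
    heading = Arg(z),
    defined = TRUE
  )
}

#' Project ring signals onto a preferred direction
#'
#' Returns the signed velocity projection `speed * cos(heading - theta)`
#' carried by the ring population for an arbitrary direction `theta` — the
#' quantity a stripe plate oriented at `theta` consumes as its drive.
#'
#' @inheritParams decode_ring
#' @param theta Direction in radians.
#'
#' @return A single number, m/s.
#' @export
hd_project <- function(ring, rates, theta) {
  if (!inherits(ring, "gp_hd_ring")) abort("`ring` must be a head_direction_ring().")
  if (length(rates) != ring$n_cells) abort("`rates` length must match the ring.")
  sum(rates * cos(ring$angles - theta)) * 2 / ring$n_cells
}
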