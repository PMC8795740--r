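#' Grid-cell module (one spatial scale)
#'
#' A population of grid cells sharing one period `lambda` and orientation but
#' differing in spatial phase. The closed-form tuning is the periodic
#' (von Mises) analogue of a Gaussian bump repeated on a hexagonal lattice:
#' three plane waves 60 degrees apart,
#' `Omega(x) = n_max * exp[(kappa/3) * sum_l (cos(omega * k_l . x) - 1)]`
#' with wave number `omega = 2*pi/lambda` and unit wave vectors
#' `k_l = (cos(phi_l), sin(phi_l))`, `phi_l = -pi/6 + l*pi/3 + orientation`.
#' Cell phase offsets `c_j` tile one unit cell of the lattice on a regular
#' `cells_side x cells_side` grid.
#'
#' The direct (firing-field) lattice conjugate to these waves is spanned by
#' `a1 = a*(1, 0)` and `a2 = a*(1/2, sqrt(3)/2)` (rotated with
#' `orientation`), with lattice constant `a = 2*lambda/sqrt(3)`.
#'
#' @param lambda Grid period in meters (`> 0`).
#' @param cells_side Cells per side of the phase-offset grid; the module has
#'   `cells_side^2` cells.
#' @param n_max Maximum expected firing rate in Hz.
#' @param kappa Concentration (tuning sharpness), dimensionless.
#' @param orientation Rotation of the whole module in radians; wave
#'   directions default to 30, 90, 150 degrees.
#'
#' @return An object of class `gp_grid_module` with fields `lambda`, `omega`,
#'   `K` (3 x 2 wave vectors), `A` (2 x 2 lattice basis, columns `a1`, `a2`),
#'   `c` (M x 2 phase offsets in meters), `M`, `n_max`, `kappa`.
#' @examples
#' mod <- grid_module(0.5, cells_side = 10)
#' @export
grid_module <- function(lambda, cells_side = 50L, n_max = 10, kappa = 3,
                        orientation = 0) {
  stopifnot_scalar_number(lambda, "lambda", positive = TRUE)
  stopifnot_scalar_number(n_max, "n_max", positive = TRUE)
  if (kappa < 0) abort("`kappa` must be >= 0.")
  m <- as.integer(cells_side)
  if (m < 1L) abort("`cells_side` must be >= 1.")
  phi <- -pi / 6 + (1:3) * pi / 3 + orientation
  K <- cbind(cos(phi), sin(phi))
  a <- 2 * lambda / sqrt(3)
  rot <- matrix(c(cos(orientation), sin(orientation),
                  -sin(orientation), cos(orientation)), 2, 2)
  A <- rot %*% (a * cbind(c(1, 0), c(1 / 2, sqrt(3) / 2)))
  pq <- as.matrix(expand.grid(p = (0:(m - 1)) / m, q = (0:(m - 1)) / m))
  offsets <- pq %*% t(A)
  structure(
    list(
      lambda = lambda, omega = 2 * pi / lambda, phi = phi, K = K, A = A,
      c = unname(offsets), M = m * m, cells_side = m,
      n_max = n_max, kappa = kappa, orientation = orientation
    ),
    class = "gp_grid_module"
  )
}

#' @export
print.gp_grid_module <- function(x, ...) {
  cat(sprintf(
    "<grid module: lambda = %g m, %d cells (%d x %d), n_max = %g Hz, kappa = %g>\n",
    x$lambda, x$M, x$cells_side, x$cells_side, x$n_max, x$kappa
  ))
  invisible(x)
}

as_xy_matrix <- function(x, name = "x") {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 2L) abort(sprintf("`%s` must be a 2-vector or an n x 2 matrix.", name))
    x <- matrix(x, 1L, 2L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) abort(sprintf("`%s` must have two columns (x, y).", name))
  x
}

#' Von Mises grid-cell tuning
#'
#' Expected firing rate of a grid cell with phase offset `c` at position(s)
#' `x`. Always in `(0, n_max]`, equal to `n_max` exactly on the cell's firing
#' lattice `c + p*a1 + q*a2` and everywhere when `kappa = 0`.
#'
#' @param module A [grid_module()].
#' @param x Position in meters: a 2-vector or an `n x 2` matrix.
#' @param center Phase offset of the cell in meters (2-vector); default the
#'   origin.
#'
#' @return Numeric vector of expected rates (Hz), one per row of `x`.
#' @examples
#' mod <- grid_module(0.5)
#' von_mises_rate(mod, c(0, 0)) # n_max at the field centre
#' @export
von_mises_rate <- function(module, x, center = c(0, 0)) {
  if (!inherits(module, "gp_grid_module")) abort("`module` must be a grid_module().")
  x <- as_xy_matrix(x)
  d <- sweep(x, 2, as.numeric(center))
  ph <- module$omega * (d %*% t(module$K)) # n x 3
  module$n_max * exp(module$kappa / 3 * rowSums(cos(ph) - 1))
}

#' Expected rates of every cell in a module
#'
#' `Omega_j(x) = Omega(x - c_j)` for all `M` phase offsets.
#'
#' @inheritParams von_mises_rate
#' @param x A single position (2-vector).
#'
#' @return Numeric vector of length `M`.
#' @export
grid_expected_rates <- function(module, x) {
  if (!inherits(module, "gp_grid_module")) abort("`module` must be a grid_module().")
  x <- as.numeric(x)
  if (length(x) != 2L) abort("`x` must be a single 2-vector position.")
  d <- sweep(module$c, 2, x) # c_j - x; cos is even so sign is immaterial
  ph <- module$omega * (d %*% t(module$K))
  module$n_max * exp(module$kappa / 3 * rowSums(cos(ph) - 1))
}

#' Poisson spike-count observation of a grid module
#'
#' Independent Poisson draws with mean `Omega_j(x) * window` per cell — the
#' noisy population observation the maximum-likelihood decoder consumes.
#'
#' @inheritParams grid_expected_rates
#' @param window Observation window in seconds (`> 0`).
#' @param seed Integer seed.
#'
#' @return Integer vector of counts, length `M`.
#' @export
sample_poisson_rates <- function(module, x, window = 1, seed = 1L) {
  stopifnot_scalar_number(window, "window", positive = TRUE)
  mu <- grid_expected_rates(module, x) * window
  withr::with_seed(seed, rpois(length(mu), mu))
}

#' Assemble grid-cell rates from three stripe plates
#'
#' Grid firing is the superposition of three stripe-cell band responses with
#' preferred directions 60 degrees apart: the rate of the grid cell with
#' phase offset `c_j` is the rectified sum of each plate's rate profile read
#' out at plate position `(k_l . c_j) / gain_l` (cells). As the plates' phases
#' flow with the agent's velocity, the assembled hexagonal pattern translates
#' with it.
#'
#' @param plates List of three calibrated, relaxed [stripe_plate()]s whose
#'   orientations are 60 degrees apart and whose physical periods
#'   (`lambda * gain`) agree.
#' @param offsets Phase offsets in meters: an `M x 2` matrix, or a
#'   [grid_module()] whose `c` field supplies them.
#'
#' @return Numeric vector of `M` grid rates.
#' @export
superpose_stripes <- function(plates, offsets) {
  if (!is.list(plates) || length(plates) != 3L) {
    abort("`plates` must be a list of three stripe plates.")
  }
  purrr::walk(plates, check_plate)
  th <- vapply(plates, function(p) p$theta, numeric(1))
  dth <- sort(pmod(th - th[1], pi))
  if (max(abs(dth - c(0, pi / 3, 2 * pi / 3))) > 1e-6) {
    abort("Plate orientations must be 60 degrees apart.")
  }
  gains <- vapply(plates, function(p) p$gain, numeric(1))
  if (anyNA(gains)) abort("All plates must have a calibrated displacement gain.")
  periods <- vapply(plates, function(p) p$lambda * abs(p$gain), numeric(1))
  if (diff(range(periods)) > 1e-6 * mean(periods)) {
    abort("Plates must share one physical period (lambda * gain).")
  }
  if (is.matrix(offsets) || is.data.frame(offsets)) {
    offs <- as_xy_matrix(offsets, "offsets")
  } else if (inherits(offsets, "gp_grid_module")) {
    offs <- offsets$c
  } else {
    abort("`offsets` must be an M x 2 matrix or a grid_module().")
  }
  out <- rep(0, nrow(offs))
  for (p in plates) {
    u <- c(cos(p$theta), sin(p$theta))
    pos <- (offs %*% u) / p$gain # cells along the plate
    out <- out + interp_periodic(p$s, as.vector(pos))
  }
  pmax(out, 0)
}

#' Expected-rate map over a region
#'
#' Evaluates a rate field on a regular raster for visualisation and
#' autocorrelation analysis: the von Mises tuning of one grid cell
#' (`gp_grid_module` method), the banded field of a stripe plate's current
#' pattern (`gp_stripe_plate` method, needs a calibrated gain), or the
#' rectified sum of three plates (list method).
#'
#' @param object A [grid_module()], a calibrated [stripe_plate()], or a list
#'   of three such plates.
#' @param xlim,ylim Extent in meters.
#' @param resolution Raster step in meters.
#' @param ... Passed to methods; the grid-module method accepts `center`,
#'   the cell's phase offset.
#'
#' @return A tibble with columns `x`, `y`, `rate`.
#' @export
rate_map <- function(object, xlim, ylim = xlim, resolution = NULL, ...) {
  UseMethod("rate_map")
}

rate_map_grid <- function(xlim, ylim, resolution) {
  xs <- seq(xlim[1], xlim[2], by = resolution)
  ys <- seq(ylim[1], ylim[2], by = resolution)
  tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
}

#' @rdname rate_map
#' @export
rate_map.gp_grid_module <- function(object, xlim, ylim = xlim,
                                    resolution = NULL, center = c(0, 0), ...) {
  resolution <- resolution %||% (object$lambda / 25)
  g <- rate_map_grid(xlim, ylim, resolution)
  g$rate <- von_mises_rate(object, as.matrix(g), center = center)
  g
}

#' @rdname rate_map
#' @export
rate_map.gp_stripe_plate <- function(object, xlim, ylim = xlim,
                                     resolution = NULL, ...) {
  if (is.na(object$gain)) abort("Plate needs a calibrated gain for a spatial map.")
  resolution <- resolution %||% (object$lambda * abs(object$gain) / 25)
  g <- rate_map_grid(xlim, ylim, resolution)
  u <- c(cos(object$theta), sin(object$theta))
  pos <- (as.matrix(g) %*% u) / object$gain
  g$rate <- interp_periodic(object$s, as.vector(pos))
  g
}

#' @rdname rate_map
#' @export
rate_map.list <- function(object, xlim, ylim = xlim, resolution = NULL, ...) {
  if (length(object) != 3L) abort("Expected a list of three stripe plates.")
  maps <- purrr::map(object, rate_map, xlim = xlim, ylim = ylim,
                     resolution = resolution %||%
                       (object[[1]]$lambda * abs(object[[1]]$gain) / 25))
  out <- maps[[1]]
  out$rate <- pmax(maps[[1]]$rate + maps[[2]]$rate + maps[[3]]$rate, 0)
  out
}

#' Spatial autocorrelation of a rate map
#'
#' FFT-based autocorrelation of a raster rate map (as returned by
#' [rate_map()]), the standard tool for exposing hexagonal structure: a grid
#' field shows six peaks 60 degrees apart on a ring at the grid period.
#'
#' @param map A tibble with columns `x`, `y`, `rate` on a regular raster.
#'
#' @return A tibble with columns `dx`, `dy`, `ac` (correlation at that lag).
#' @export
autocorrelate_map <- function(map) {
  xs <- sort(unique(map$x))
  ys <- sort(unique(map$y))
  z <- matrix(map$rate[order(map$y, map$x)], length(xs), length(ys))
  z <- z - mean(z)
  f <- fft(z)
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / length(z)
  ac <- ac / ac[1, 1]
  nx <- length(xs)
  ny <- length(ys)
  sx <- xs[2] - xs[1]
  sy <- ys[2] - ys[1]
  ix <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  iy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  tibble(
    dx = rep(ix * sx, times = ny),
    dy = rep(iy * sy, each = nx),
    ac = as.vector(ac)
  )
}

# Local maxima of an autocorrelation away from the origin; used to check
# hexagonal structure. Returns peaks sorted by radius.
autocorr_peaks <- function(ac, min_radius, max_radius, top = 6L) {
  sel <- ac[sqrt(ac$dx^2 + ac$dy^2) >= min_radius &
              sqrt(ac$dx^2 + ac$dy^2) <= max_radius, ]
  sel <- sel[order(-sel$ac), ]
  peaks <- sel[0, ]
  for (i in seq_len(nrow(sel))) {
    if (nrow(peaks) >= top) break
    if (nrow(peaks) == 0 ||
        min(sqrt((peaks$dx - sel$dx[i])^2 + (peaks$dy - sel$dy[i])^2)) >
          min_radius / 2) {
      peaks <- rbind(peaks, sel[i, ])
    }
  }
  peaks
}
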