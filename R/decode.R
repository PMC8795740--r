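#' Maximum-likelihood position decode from one grid module
#'
#' Population-vector decode of a grid module's counts: for each of the three
#' wave directions the argument of `Z_l = sum_j n_j * exp(1i * omega * k_l . c_j)`
#' gives the projection `mu_l = omega^-1 * arg(Z_l)` of position on that
#' direction (modulo the period, branch in `(-lambda/2, lambda/2]`), and the
#' three projections recombine as `x_hat = (2/3) * sum_l mu_l * k_l`, which
#' is exact because the three unit wave vectors 60 degrees apart satisfy
#' `sum_l k_l k_l' = (3/2) I`.
#'
#' Because the three projections are redundant (`k_1 - k_2 + k_3 = 0`), their
#' wrapped branches must be mutually consistent (`mu_1 - mu_2 + mu_3 = 0`
#' modulo nothing); when independent wrapping breaks this, the decoder
#' re-branches the largest projections until consistency is restored, so the
#' estimate is always exact modulo the firing lattice.
#'
#' @param rates Numeric vector of `M` non-negative counts or rates.
#' @param module The [grid_module()] that generated them.
#'
#' @return An object of class `gp_decode` with fields `x` (the 2-vector
#'   estimate, defined modulo the lattice), `mu` (the three projections in
#'   meters), `decodable` (FALSE when counts are zero or a direction's
#'   population vector vanishes), and `lambda`.
#' @examples
#' mod <- grid_module(1, cells_side = 20)
#' decode_single_module(grid_expected_rates(mod, c(0.2, -0.1)), mod)
#' @export
decode_single_module <- function(rates, module) {
  if (!inherits(module, "gp_grid_module")) abort("`module` must be a grid_module().")
  if (length(rates) != module$M) abort("`rates` length must equal the module's cell count.")
  if (any(rates < 0)) abort("`rates` must be non-negative.")
  tot <- sum(rates)
  out <- structure(
    list(x = c(NA_real_, NA_real_), mu = rep(NA_real_, 3),
         decodable = FALSE, lambda = module$lambda),
    class = "gp_decode"
  )
  if (tot == 0) return(out)
  ph <- module$omega * (module$c %*% t(module$K)) # M x 3
  Z <- colSums(rates * exp(1i * ph))
  if (any(Mod(Z) < 1e-9 * tot)) return(out)
  lam <- module$lambda
  mu <- Arg(Z) / module$omega # in (-lambda/2, lambda/2]
  # restore branch consistency of the redundant third projection
  for (it in 1:6) {
    M0 <- round((mu[1] - mu[2] + mu[3]) / lam)
    if (M0 == 0) break
    sgn <- sign(M0)
    cand <- c(mu[1] - sgn * lam, mu[2] + sgn * lam, mu[3] - sgn * lam)
    l <- which.min(abs(cand))
    mu[l] <- cand[l]
  }
  out$mu <- mu
  out$x <- as.numeric((2 / 3) * t(module$K) %*% mu)
  out$decodable <- TRUE
  out
}

#' @export
print.gp_decode <- function(x, ...) {
  if (x$decodable) {
    cat(sprintf("<decode: x = (%.4f, %.4f) m (mod lattice, lambda = %g m)>\n",
                x$x[1], x$x[2], x$lambda))
  } else {
    cat("<decode: undecodable (zero or degenerate population activity)>\n")
  }
  invisible(x)
}

# Lattice translates p*a1 + q*a2 for p, q in -r..r.
lattice_translates <- function(A, r) {
  pq <- as.matrix(expand.grid(p = -r:r, q = -r:r))
  pq %*% t(A)
}

# Minimum-image convention on the hex lattice: representative of v modulo
# the lattice with the smallest norm.
lattice_min_image <- function(v, A) {
  pq <- solve(A, v)
  base <- A %*% round(pq)
  cand <- sweep(lattice_translates(A, 1), 2, as.numeric(v - base), "-")
  best <- which.min(rowSums(cand^2))
  -as.numeric(cand[best, ])
}

#' Dense-lattice posterior over position
#'
#' Evaluates the log joint posterior of position given Poisson grid-cell
#' counts on a dense raster,
#' `log p(x | n) = const + sum_m (kappa_m/3) sum_j sum_l n_jm * cos(omega_m * k_l . (x - c_jm))`,
#' normalises it over the raster, and returns its argmax. This is the
#' brute-force ground truth that the closed-form single- and multi-scale
#' decoders are checked against.
#'
#' @param rates A numeric vector (single module) or a list of vectors, one
#'   per module.
#' @param modules A [grid_module()] or list of them, matching `rates`.
#' @param resolution Raster step in meters; default `lambda_min / 100`.
#' @param xlim,ylim Search extent; defaults to one fundamental domain of the
#'   coarsest module's lattice centred at the origin.
#'
#' @return A list with `field` (tibble `x`, `y`, `log_posterior`,
#'   `posterior`), `argmax` (2-vector), `ambiguous` (TRUE for a flat posterior
#'   or ties beyond one raster step), and `resolution`.
#' @export
posterior_oracle <- function(rates, modules, resolution = NULL,
                             xlim = NULL, ylim = NULL) {
  if (inherits(modules, "gp_grid_module")) modules <- list(modules)
  if (!is.list(rates)) rates <- list(rates)
  if (length(rates) != length(modules)) {
    abort("`rates` and `modules` must have the same length.")
  }
  lam0 <- max(vapply(modules, function(m) m$lambda, numeric(1)))
  lam_min <- min(vapply(modules, function(m) m$lambda, numeric(1)))
  resolution <- resolution %||% (lam_min / 100)
  a <- 2 * lam0 / sqrt(3)
  xlim <- xlim %||% c(-a / 2, a / 2)
  ylim <- ylim %||% c(-lam0 / 2, lam0 / 2)
  g <- rate_map_grid(xlim, ylim, resolution)
  X <- as.matrix(g)
  logp <- rep(0, nrow(X))
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    n <- rates[[i]]
    if (length(n) != mod$M) abort("Rate vector length must match its module.")
    ph_c <- mod$omega * (mod$c %*% t(mod$K))
    Z <- colSums(n * exp(-1i * ph_c)) # one complex amplitude per direction
    ph_x <- mod$omega * (X %*% t(mod$K))
    logp <- logp + (mod$kappa / 3) *
      rowSums(Re(exp(1i * ph_x) * matrix(Z, nrow(X), 3, byrow = TRUE)))
  }
  flat <- diff(range(logp)) < 1e-9
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  imax <- which.max(logp)
  near <- which(logp > max(logp) - 1e-9)
  tied <- FALSE
  if (length(near) > 1L) {
    dmax <- max(sqrt((g$x[near] - g$x[imax])^2 + (g$y[near] - g$y[imax])^2))
    tied <- dmax > 2 * resolution
  }
  list(
    field = tibble(x = g$x, y = g$y, log_posterior = logp, posterior = p),
    argmax = c(g$x[imax], g$y[imax]),
    ambiguous = flat || tied,
    resolution = resolution
  )
}

#' Combine per-scale position solutions (weighted and recursive forms)
#'
#' Two algebraically equivalent readouts of the multi-scale maximum
#' likelihood solution from per-scale branch solutions `delta_m`:
#' the closed weighted average
#' `x_ML = sum_m M_m s_m^2 delta_m / sum_m M_m s_m^2` with scale ratios
#' `s_m = lambda_0 / lambda_m`, and the coarse-to-fine recursion
#' `x_{L+1} = x_L + [lambda_L^-2 / sum_{m<=L} lambda_m^-2] * (delta_L - x_L)`
#' (stated for equal cell counts; the recursion here carries `M_m` in its
#' weights so both forms agree in general).
#'
#' @param delta An `L x 2` matrix of per-scale solutions (meters), coarse
#'   first.
#' @param lambda Numeric vector of the `L` grid periods, decreasing.
#' @param M Cell counts per scale; default equal.
#' @param method `"recursive"` or `"weighted"`.
#'
#' @return A 2-vector estimate.
#' @export
combine_scale_estimates <- function(delta, lambda,
                                    M = rep(1, length(lambda)),
                                    method = c("recursive", "weighted")) {
  method <- match.arg(method)
  delta <- as_xy_matrix(delta, "delta")
  L <- length(lambda)
  if (nrow(delta) != L || length(M) != L) {
    abort("`delta`, `lambda` and `M` must describe the same number of scales.")
  }
  if (L > 1 && any(diff(lambda) >= 0)) abort("`lambda` must be strictly decreasing.")
  if (method == "weighted") {
    s <- lambda[1] / lambda
    w <- M * s^2
    as.numeric(colSums(delta * w) / sum(w))
  } else {
    x <- delta[1, ]
    if (L > 1) {
      for (l in 2:L) {
        w <- M[l] * lambda[l]^-2 / sum(M[1:l] * lambda[1:l]^-2)
        x <- x + w * (delta[l, ] - x)
      }
    }
    as.numeric(x)
  }
}

#' Multi-scale maximum-likelihood position decode
#'
#' Coarse-to-fine readout of nested grid modules: the coarsest module (whose
#' period covers the workspace) anchors a unique estimate `x_0`; each finer
#' module's estimate is defined only modulo its lattice, so the branch
#' nearest the running estimate is selected and pulled in with weight
#' `lambda_L^-2 / sum_{m<=L} lambda_m^-2` (inverse-variance weighting of
#' scales). Branch offsets near half a period are flagged as ambiguous.
#'
#' @param rates List of count vectors, one per module, coarse first.
#' @param modules List of [grid_module()]s with strictly decreasing periods
#'   and a common orientation.
#'
#' @return An object of class `gp_decode_multiscale`: `x` (final estimate),
#'   `trace` (tibble with one row per scale: `scale`, `lambda`, the branch
#'   solution `delta_x`, `delta_y`, the applied correction and running
#'   estimate), `decodable`, `ambiguous`.
#' @export
decode_multiscale <- function(rates, modules) {
  if (inherits(modules, "gp_grid_module")) modules <- list(modules)
  if (!is.list(rates)) rates <- list(rates)
  if (length(rates) != length(modules)) {
    abort("`rates` and `modules` must have the same length.")
  }
  lam <- vapply(modules, function(m) m$lambda, numeric(1))
  if (length(lam) > 1 && any(diff(lam) >= 0)) {
    abort("`modules` must be ordered coarse to fine (strictly decreasing period).")
  }
  L <- length(modules)
  est <- decode_single_module(rates[[1]], modules[[1]])
  trace <- tibble(
    scale = 0L, lambda = lam[1],
    delta_x = est$x[1], delta_y = est$x[2],
    corr_x = 0, corr_y = 0,
    x_est = est$x[1], y_est = est$x[2]
  )
  out <- structure(
    list(x = est$x, trace = trace, decodable = est$decodable, ambiguous = FALSE),
    class = "gp_decode_multiscale"
  )
  if (!est$decodable) return(out)
  x <- est$x
  ambiguous <- FALSE
  if (L > 1) {
    for (l in 2:L) {
      dl <- decode_single_module(rates[[l]], modules[[l]])
      if (!dl$decodable) {
        out$decodable <- FALSE
        return(out)
      }
      r <- ceiling(lam[1] / lam[l]) + 1L
      cand <- sweep(lattice_translates(modules[[l]]$A, r), 2, dl$x, "+")
      d2 <- rowSums(sweep(cand, 2, x)^2)
      best <- which.min(d2)
      delta <- as.numeric(cand[best, ])
      off <- delta - x
      if (sqrt(sum(off^2)) > 0.45 * lam[l]) ambiguous <- TRUE
      w <- lam[l]^-2 / sum(lam[1:l]^-2)
      corr <- w * off
      x <- x + corr
      trace <- dplyr::bind_rows(trace, tibble(
        scale = l - 1L, lambda = lam[l],
        delta_x = delta[1], delta_y = delta[2],
        corr_x = corr[1], corr_y = corr[2],
        x_est = x[1], y_est = x[2]
      ))
    }
  }
  out$x <- x
  out$trace <- trace
  out$ambiguous <- ambiguous
  out
}

#' @export
print.gp_decode_multiscale <- function(x, ...) {
  if (x$decodable) {
    cat(sprintf("<multi-scale decode: x = (%.4f, %.4f) m over %d scales%s>\n",
                x$x[1], x$x[2], nrow(x$trace),
                if (x$ambiguous) ", branch ambiguity flagged" else ""))
  } else {
    cat("<multi-scale decode: undecodable>\n")
  }
  invisible(x)
}

#' Place-cell fields and responses
#'
#' A place cell responds with `R_i = exp(-||x - r_i0||^2 / delta2)`: 1 at its
#' field centre `r_i0`, strictly decreasing with distance, `exp(-1)` at
#' distance `sqrt(delta2)`. `place_field_grid()` lays field centres on a
#' regular grid over an arena; `place_response()` evaluates the population
#' response at a decoded position, turning the grid-code estimate into the
#' single-peaked place-cell map.
#'
#' @param arena An [arena()].
#' @param spacing Field-centre spacing in meters.
#'
#' @return `place_field_grid()`: a tibble with columns `id`, `x0`, `y0`.
#' @export
place_field_grid <- function(arena, spacing = 0.5) {
  stopifnot_scalar_number(spacing, "spacing", positive = TRUE)
  xs <- seq(spacing / 2, arena$width - spacing / 2, by = spacing)
  ys <- seq(spacing / 2, arena$height - spacing / 2, by = spacing)
  g <- tidyr::expand_grid(y0 = ys, x0 = xs)[, c("x0", "y0")]
  dplyr::mutate(g, id = dplyr::row_number(), .before = 1)
}

#' @rdname place_field_grid
#' @param fields A tibble of field centres with columns `x0`, `y0` (and
#'   optionally `id`).
#' @param x_hat Position estimate, a 2-vector in meters.
#' @param delta2 Field width parameter in m^2 (`> 0`).
#' @return `place_response()`: the `fields` tibble with a `response` column.
#' @export
place_response <- function(fields, x_hat, delta2 = 0.1) {
  stopifnot_scalar_number(delta2, "delta2", positive = TRUE)
  if (!all(c("x0", "y0") %in% names(fields))) {
    abort("`fields` must have columns x0, y0.")
  }
  x_hat <- as.numeric(x_hat)
  d2 <- (fields$x0 - x_hat[1])^2 + (fields$y0 - x_hat[2])^2
  dplyr::mutate(fields, response = exp(-d2 / delta2))
}

#' Decoding-error statistics against ground truth
#'
#' Per-sample Euclidean error between a decoded path and the true
#' trajectory, its running envelope, and the 2-D error scatter (centroid and
#' spread) — the summaries used to compare the attractor-decoded path with a
#' drifting odometry baseline.
#'
#' @param true_traj,decoded_traj Tibbles with columns `t`, `x`, `y` on the
#'   same time base.
#'
#' @return An object of class `gp_error_stats`: `data` is a tibble with
#'   columns `t`, `dx`, `dy`, `error`, `envelope` (running maximum);
#'   [glance()] yields `rmse`, `mean_error`, `max_error`, `final_error`,
#'   `centroid_x`, `centroid_y`, `spread`.
#' @export
error_statistics <- function(true_traj, decoded_traj) {
  for (nm in c("t", "x", "y")) {
    if (!nm %in% names(true_traj) || !nm %in% names(decoded_traj)) {
      abort("Both series need columns t, x, y.")
    }
  }
  if (nrow(true_traj) != nrow(decoded_traj) ||
      max(abs(true_traj$t - decoded_traj$t)) > 1e-9) {
    abort("Series are misaligned: time bases differ.")
  }
  dx <- decoded_traj$x - true_traj$x
  dy <- decoded_traj$y - true_traj$y
  err <- sqrt(dx^2 + dy^2)
  structure(
    list(
      data = tibble(
        t = true_traj$t, dx = dx, dy = dy, error = err,
        envelope = cummax(err)
      )
    ),
    class = "gp_error_stats"
  )
}

#' @export
print.gp_error_stats <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<error stats: rmse %.4g m, max %.4g m, final %.4g m, centroid (%.3g, %.3g) m>\n",
    g$rmse, g$max_error, g$final_error, g$centroid_x, g$centroid_y
  ))
  invisible(x)
}
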