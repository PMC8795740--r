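# Broom-style tidiers for the package's result objects.

#' @export
tidy.gp_calibration <- function(x, ...) {
  x$data
}

#' @export
glance.gp_calibration <- function(x, ...) {
  tibble(
    gain = x$gain, period = x$period, r = x$r,
    max_residual = x$max_residual, n = x$n
  )
}

#' @export
tidy.gp_formation_study <- function(x, ...) {
  x$runs
}

#' @export
glance.gp_formation_study <- function(x, ...) {
  tibble(
    median_ms = median(x$runs$formation_ms, na.rm = TRUE),
    max_ms = suppressWarnings(max(x$runs$formation_ms, na.rm = TRUE)),
    n_failed = sum(is.na(x$runs$formation_ms)),
    n_seeds = nrow(x$runs)
  )
}

#' @export
tidy.gp_decode <- function(x, ...) {
  tibble(
    direction = 1:3, mu = x$mu,
    x = x$x[1], y = x$x[2], decodable = x$decodable
  )
}

#' @export
tidy.gp_decode_multiscale <- function(x, ...) {
  x$trace
}

#' @export
glance.gp_decode_multiscale <- function(x, ...) {
  tibble(
    x = x$x[1], y = x$x[2], n_scales = nrow(x$trace),
    decodable = x$decodable, ambiguous = x$ambiguous
  )
}

#' @export
tidy.gp_error_stats <- function(x, ...) {
  x$data
}

#' @export
glance.gp_error_stats <- function(x, ...) {
  d <- x$data
  tibble(
    rmse = sqrt(mean(d$error^2)),
    mean_error = mean(d$error),
    max_error = max(d$error),
    final_error = d$error[nrow(d)],
    centroid_x = mean(d$dx),
    centroid_y = mean(d$dy),
    spread = mean(sqrt((d$dx - mean(d$dx))^2 + (d$dy - mean(d$dy))^2))
  )
}
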