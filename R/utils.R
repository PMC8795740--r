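# Internal helpers shared across modules.

# Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Positive modulo: result in [0, m).
pmod <- function(x, m) {
  out <- x %% m
  out[out == m] <- 0
  out
}

# Evaluate a periodic profile at fractional positions by linear interpolation.
# `values` are samples at integer positions 0..n-1 with period n.
interp_periodic <- function(values, at) {
  n <- length(values)
  at <- pmod(at, n)
  i0 <- floor(at)
  frac <- at - i0
  i0 <- as.integer(i0) %% n
  i1 <- (i0 + 1L) %% n
  values[i0 + 1L] * (1 - frac) + values[i1 + 1L] * frac
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
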