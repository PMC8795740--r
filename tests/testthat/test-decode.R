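test_that("projection reconstruction identity holds to machine precision", {
  mod <- grid_module(1, cells_side = 5)
  withr::with_seed(1, {
    for (i in 1:50) {
      u <- runif(2, -5, 5)
      mu <- as.vector(mod$K %*% u)
      expect_equal(as.numeric((2 / 3) * t(mod$K) %*% mu), u,
                   tolerance = 1e-10)
    }
  })
})

test_that("noise-free decoding is exact at the origin and accurate in the cell", {
  mod <- grid_module(1, cells_side = 20)
  d0 <- decode_single_module(grid_expected_rates(mod, c(0, 0)), mod)
  expect_true(d0$decodable)
  expect_equal(d0$x, c(0, 0), tolerance = 1e-9)

  withr::with_seed(2, {
    for (i in 1:25) {
      x <- runif(2, -0.4, 0.4)
      d <- decode_single_module(grid_expected_rates(mod, x), mod)
      expect_lt(sqrt(sum((d$x - x)^2)), 0.02 * mod$lambda)
    }
  })
})

test_that("degenerate population activity is flagged, not decoded", {
  mod <- grid_module(1, cells_side = 10)
  expect_false(decode_single_module(rep(0, mod$M), mod)$decodable)
  # uniform counts: population vectors vanish
  expect_false(decode_single_module(rep(3, mod$M), mod)$decodable)
  expect_error(decode_single_module(rep(-1, mod$M), mod), "non-negative")
})

test_that("posterior oracle normalises, flags flat fields, matches the decoder", {
  mod <- grid_module(1, cells_side = 15)
  flat <- posterior_oracle(rep(2, mod$M), mod, resolution = 0.05)
  expect_true(flat$ambiguous)
  expect_equal(sum(flat$field$posterior), 1, tolerance = 1e-9)

  withr::with_seed(3, {
    for (i in 1:10) {
      x <- runif(2, -0.3, 0.3)
      r <- grid_expected_rates(mod, x)
      po <- posterior_oracle(r, mod, resolution = 0.01)
      d <- decode_single_module(r, mod)
      expect_false(po$ambiguous)
      expect_lt(max(abs(po$argmax - d$x)), po$resolution + 1e-9)
    }
  })
})

test_that("branch-consistent decoding stays on the lattice away from the centre", {
  mod <- grid_module(1, cells_side = 20)
  withr::with_seed(4, {
    for (i in 1:25) {
      x <- runif(2, -1.5, 1.5) # well outside the central projection branch
      d <- decode_single_module(grid_expected_rates(mod, x), mod)
      err <- gridpath:::lattice_min_image(d$x - x, mod$A)
      expect_lt(sqrt(sum(err^2)), 0.02 * mod$lambda)
    }
  })
})

test_that("weighted and recursive multi-scale combinations agree exactly", {
  withr::with_seed(5, {
    for (i in 1:50) {
      L <- sample(2:5, 1)
      lam <- 10 / 1.5^(0:(L - 1))
      delta <- matrix(rnorm(2 * L, sd = 2), L, 2)
      a <- combine_scale_estimates(delta, lam, method = "weighted")
      b <- combine_scale_estimates(delta, lam, method = "recursive")
      expect_equal(a, b, tolerance = 1e-10)
    }
  })
  # identical per-scale solutions are a fixed point of the recursion
  delta <- matrix(rep(c(1.2, -0.7), each = 4), 4, 2)
  expect_equal(
    combine_scale_estimates(delta, 10 / 1.5^(0:3), method = "recursive"),
    c(1.2, -0.7)
  )
})

test_that("two-scale refinement weight matches the direct arithmetic form", {
  lam <- c(10, 10 / 1.5)
  delta <- rbind(c(2, 1), c(2.5, 0.4))
  got <- combine_scale_estimates(delta, lam, method = "recursive")
  w1 <- lam[2]^-2 / (lam[1]^-2 + lam[2]^-2)
  expect_equal(got, delta[1, ] + w1 * (delta[2, ] - delta[1, ]),
               tolerance = 1e-12)
})

test_that("multi-scale decoding refines towards the truth, flags bad input", {
  lams <- 4 / 1.5^(0:2)
  mods <- lapply(lams, grid_module, cells_side = 15)
  withr::with_seed(6, {
    for (i in 1:10) {
      x <- runif(2, -0.8, 0.8)
      rates <- lapply(mods, grid_expected_rates, x = x)
      est <- decode_multiscale(rates, mods)
      expect_true(est$decodable)
      expect_equal(nrow(est$trace), 3L)
      expect_lt(sqrt(sum((est$x - x)^2)), 0.02 * lams[3])
    }
  })
  expect_error(decode_multiscale(list(1, 2), rev(mods)[1:2]), "coarse to fine")
})

test_that("decoding error vanishes as the observation window grows", {
  mod <- grid_module(2, cells_side = 20)
  x <- c(0.31, -0.44)
  err_for <- function(window, seed) {
    n <- sample_poisson_rates(mod, x, window = window, seed = seed)
    d <- decode_single_module(n, mod)
    sqrt(sum((d$x - x)^2))
  }
  short <- sapply(1:30, err_for, window = 0.5)
  long <- sapply(1:30, err_for, window = 50)
  expect_lt(mean(long), mean(short) / 3)
})

test_that("more cells mean lower decoding error (Poisson sampling)", {
  x <- c(0.2, 0.35)
  rms_for <- function(m) {
    mod <- grid_module(2, cells_side = m)
    e <- sapply(1:40, function(s) {
      n <- sample_poisson_rates(mod, x, window = 1, seed = s)
      d <- decode_single_module(n, mod)
      sum((d$x - x)^2)
    })
    sqrt(mean(e))
  }
  expect_gt(rms_for(10), rms_for(30))
})

test_that("place responses are single-peaked gaussian bumps", {
  fields <- place_field_grid(arena(4, 4), spacing = 1)
  expect_equal(nrow(fields), 16L)
  resp <- place_response(fields, c(1.5, 2.5), delta2 = 0.25)
  at_centre <- place_response(tibble::tibble(x0 = 1.5, y0 = 2.5),
                              c(1.5, 2.5), delta2 = 0.25)
  expect_equal(at_centre$response, 1)
  at_delta <- place_response(tibble::tibble(x0 = 0, y0 = 0), c(0.5, 0),
                             delta2 = 0.25)
  expect_equal(at_delta$response, exp(-1))
  # strictly decreasing with distance
  d <- sqrt((fields$x0 - 1.5)^2 + (fields$y0 - 2.5)^2)
  expect_true(all(diff(resp$response[order(d)]) <= 1e-12))
})

test_that("error statistics summarise per-sample errors and reject misalignment", {
  truth <- tibble::tibble(t = 0:10 / 2, x = 1:11 / 3, y = sin(1:11))
  same <- error_statistics(truth, truth)
  expect_true(all(same$data$error == 0))

  shifted <- dplyr::mutate(truth, x = x + 0.1)
  es <- error_statistics(truth, shifted)
  expect_true(all(abs(es$data$error - 0.1) < 1e-12))
  g <- glance(es)
  expect_equal(g$centroid_x, 0.1)
  expect_equal(g$centroid_y, 0)
  expect_equal(g$max_error, 0.1)

  bad <- dplyr::mutate(truth, t = t + 0.25)
  expect_error(error_statistics(truth, bad), "misaligned")
})
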