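test_that("module geometry: unit wave vectors 60 degrees apart, (3/2)I closure", {
  mod <- grid_module(0.5, cells_side = 10)
  expect_equal(rowSums(mod$K^2), rep(1, 3))
  ang <- atan2(mod$K[, 2], mod$K[, 1])
  expect_equal(diff(ang), rep(pi / 3, 2))
  expect_equal(t(mod$K) %*% mod$K, diag(2) * 3 / 2, ignore_attr = TRUE)
  expect_equal(nrow(unique(round(mod$c, 12))), mod$M) # offsets distinct
  # lattice basis is conjugate to the waves: omega * K %*% a_j in 2*pi*Z
  ph <- mod$omega * mod$K %*% mod$A
  expect_equal(ph / (2 * pi), round(ph / (2 * pi)), tolerance = 1e-9)
})

test_that("von Mises tuning peaks at the field centre and is lattice periodic", {
  mod <- grid_module(0.5, cells_side = 5, n_max = 10, kappa = 3)
  cc <- c(0.17, -0.08)
  expect_equal(von_mises_rate(mod, cc, center = cc), 10)
  flat <- grid_module(0.5, cells_side = 5, n_max = 10, kappa = 0)
  xs <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  expect_equal(von_mises_rate(flat, xs), rep(10, 20))
  # periodicity under any lattice translate
  withr::with_seed(4, {
    for (i in 1:20) {
      x <- runif(2, -1, 1)
      T <- mod$A %*% sample(-2:2, 2, replace = TRUE)
      expect_equal(von_mises_rate(mod, x + as.numeric(T)),
                   von_mises_rate(mod, x), tolerance = 1e-9)
    }
  })
  # boundedness
  r <- von_mises_rate(mod, cbind(runif(200, -2, 2), runif(200, -2, 2)))
  expect_true(all(r > 0 & r <= 10 + 1e-12))
})

test_that("poisson sampling matches its mean and is seed-stable", {
  mod <- grid_module(1, cells_side = 8, n_max = 5, kappa = 2)
  x <- c(0.3, 0.1)
  mu <- grid_expected_rates(mod, x)
  expect_true(all(sample_poisson_rates(mod, c(1e6, 1e6) * 0 + x, window = 1e-9,
                                       seed = 1) == 0))
  # empirical mean of many draws within 3 standard errors for the top cell
  j <- which.max(mu)
  draws <- vapply(1:2000, function(s) {
    sample_poisson_rates(mod, x, window = 2, seed = s)[j]
  }, numeric(1))
  se <- sqrt(mu[j] * 2 / 2000)
  expect_lt(abs(mean(draws) - mu[j] * 2), 3 * se)
  expect_identical(sample_poisson_rates(mod, x, seed = 99),
                   sample_poisson_rates(mod, x, seed = 99))
})

test_that("superposing three plates yields a hexagonal firing lattice", {
  cal <- calibrated_reduced()
  thetas <- pi / 6 + c(0, 2, 4) * pi / 6
  plates <- lapply(thetas, function(th) {
    p <- cal$plate
    p$theta <- th
    set_plate_period(p, 0.5)
  })
  mod <- grid_module(0.5, cells_side = 30)
  rates <- superpose_stripes(plates, mod)
  expect_true(all(rates >= 0))
  expect_equal(length(rates), mod$M)

  # rate map over several periods shows six-fold autocorrelation peaks
  mp <- rate_map(plates, xlim = c(-1, 1), resolution = 0.02)
  ac <- autocorrelate_map(mp)
  pk <- gridpath:::autocorr_peaks(ac, min_radius = 0.3, max_radius = 0.7)
  expect_gte(nrow(pk), 6)
  radii <- sqrt(pk$dx^2 + pk$dy^2)
  expect_lt(max(abs(radii - 0.5)) / 0.5, 0.25)
  angs <- sort(atan2(pk$dy, pk$dx) %% (2 * pi))
  gaps <- diff(c(angs, angs[1] + 2 * pi))
  expect_lt(max(abs(sort(gaps) - pi / 3)), 0.35)

  # orientations not 60 degrees apart are rejected
  bad <- plates
  bad[[2]]$theta <- bad[[1]]$theta + 0.3
  expect_error(superpose_stripes(bad, mod), "60 degrees")
})

test_that("superposition is additive before rectification", {
  cal <- calibrated_reduced()
  thetas <- pi / 6 + c(0, 2, 4) * pi / 6
  plates <- lapply(thetas, function(th) {
    p <- cal$plate
    p$theta <- th
    set_plate_period(p, 0.5)
  })
  offs <- rbind(c(0.05, 0.1), c(-0.2, 0.3))
  per_plate <- sapply(plates, function(p) {
    u <- c(cos(p$theta), sin(p$theta))
    gridpath:::interp_periodic(p$s, as.vector(offs %*% u) / p$gain)
  })
  expect_equal(superpose_stripes(plates, offs), pmax(rowSums(per_plate), 0))
})

test_that("shifting all stripe phases translates the assembled pattern", {
  cal <- calibrated_reduced()
  thetas <- pi / 6 + c(0, 2, 4) * pi / 6
  plates <- lapply(thetas, function(th) {
    p <- cal$plate
    p$theta <- th
    set_plate_period(p, 0.5)
  })
  delta <- c(0.12, -0.07)
  shifted <- lapply(plates, function(p) {
    u <- c(cos(p$theta), sin(p$theta))
    shift_cells <- sum(delta * u) / p$gain
    p$s <- gridpath:::interp_periodic(p$s, (seq_len(p$n_cells) - 1) - shift_cells)
    p
  })
  offs <- as.matrix(tidyr::expand_grid(x = seq(-0.2, 0.2, 0.05),
                                       y = seq(-0.2, 0.2, 0.05)))
  a <- superpose_stripes(shifted, offs)
  b <- superpose_stripes(plates, sweep(offs, 2, delta)) # evaluate at x - delta
  # double linear interpolation leaves small resampling error
  expect_gt(cor(a, b), 0.998)
  expect_lt(max(abs(a - b)), 0.1 * max(b))
})

test_that("rate maps: constant profile in, constant map out; hex for Eq tuning", {
  cal <- calibrated_reduced()
  pl <- cal$plate
  pl$s <- rep(0.5, pl$n_cells)
  m <- rate_map(pl, xlim = c(0, 1), resolution = 0.05)
  expect_true(all(abs(m$rate - 0.5) < 1e-12))

  mod <- grid_module(0.5, cells_side = 10)
  mv <- rate_map(mod, xlim = c(-1, 1), resolution = 0.02)
  ac <- autocorrelate_map(mv)
  pk <- gridpath:::autocorr_peaks(ac, min_radius = 0.3, max_radius = 0.7)
  expect_gte(nrow(pk), 6)
  expect_lt(max(abs(sqrt(pk$dx^2 + pk$dy^2) - 0.5)) / 0.5, 0.2)
})

test_that("the assembled grid pattern flows with the agent", {
  cal <- calibrated_reduced()
  thetas <- pi / 6 + c(0, 2, 4) * pi / 6
  plates <- lapply(thetas, function(th) {
    p <- cal$plate
    p$theta <- th
    set_plate_period(p, 0.5)
  })
  v <- c(0.2, 0)
  dt_move <- 1 # one second of motion
  traj <- straight_trajectory(0.2, 0, duration = dt_move)
  moved <- lapply(plates, function(p) run_plate(p, traj)$plate)
  offs <- as.matrix(tidyr::expand_grid(x = seq(-0.24, 0.24, 0.03),
                                       y = seq(-0.24, 0.24, 0.03)))
  before <- superpose_stripes(plates, offs)
  after <- superpose_stripes(moved, offs)
  # cross-correlate over candidate displacements: the peak should sit at
  # v * dt modulo the lattice
  cands <- tidyr::expand_grid(dx = seq(-0.25, 0.25, 0.01), dy = seq(-0.1, 0.1, 0.01))
  score <- purrr::pmap_dbl(cands, function(dx, dy) {
    ref <- superpose_stripes(plates, sweep(offs, 2, c(dx, dy)))
    suppressWarnings(cor(after, ref))
  })
  best <- cands[which.max(score), ]
  target <- gridpath:::lattice_min_image(v * dt_move, grid_module(0.5)$A)
  expect_lt(abs(best$dx - target[1]), 0.03)
  expect_lt(abs(best$dy - target[2]), 0.03)
})
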