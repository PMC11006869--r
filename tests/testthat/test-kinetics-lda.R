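test_that("lifetime grids are log-even with the conventional bounds", {
  expect_equal(as.numeric(build_lifetime_grid(1e-3, 1, n = 2)), c(1e-3, 1))
  g <- default_lifetime_grid(timescale = "ultrafast")
  expect_length(g, 200)
  expect_equal(g[1], 0.03e-12)
  expect_equal(g[200], 5400e-12)
  ratios <- g[-1] / g[-length(g)]
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-12)
  ds <- transient_dataset(c(1e-6, 1e-3, 2), c(500, 600),
                          matrix(0, 3, 2))
  gns <- default_lifetime_grid(ds, "ns_s")
  expect_equal(max(gns), 3 * 2)
  expect_error(build_lifetime_grid(-1, 5), "0 < start < end")
})

test_that("design matrix is the elementwise exponential kernel", {
  t <- c(0, 0.5, 1, 2); tau <- c(0.5, 1)
  A <- build_design_matrix(t, tau)
  expect_equal(A[1, ], c(1, 1))
  expect_equal(A[3, 2], exp(-1))
  withr::local_seed(5)
  for (rep in 1:20) {
    tt <- sort(runif(6, 0, 10)); gg <- 10^runif(4, -2, 1)
    expect_equal(build_design_matrix(tt, gg),
                 outer(tt, gg, function(a, b) exp(-a / b)))
  }
  expect_true(all(diff(A[, 1]) < 0))
  expect_error(build_design_matrix(c(-1, 1), tau), "negative times")
})

test_that("Tikhonov solutions satisfy the normal equations", {
  withr::local_seed(6)
  alphas <- c(0.01, 0.1, 1, 5)
  for (rep in 1:25) {
    A <- matrix(rnorm(200), 20, 10)
    y <- rnorm(20)
    for (a in alphas) {
      x <- tikhonov_solve(A, y, a)
      expect_lt(max(abs((crossprod(A) + a^2 * diag(10)) %*% x - crossprod(A, y))),
                1e-8)
    }
  }
  # alpha = 0 on a well-conditioned square system is the exact solve
  A <- diag(4) + 0.1 * matrix(rnorm(16), 4)
  y <- rnorm(4)
  expect_equal(as.numeric(tikhonov_solve(A, y, 0)), as.numeric(solve(A, y)),
               tolerance = 1e-8)
  # large-alpha limit: x ~ A'y / alpha^2
  xl <- tikhonov_solve(A, y, 1e6)
  expect_equal(as.numeric(xl), as.numeric(crossprod(A, y)) / 1e12,
               tolerance = 1e-6)
  # rank-deficient at alpha = 0: minimum-norm solution, flagged
  Ar <- cbind(1:4, 2 * (1:4))
  xr <- tikhonov_solve(Ar, c(1, 2, 3, 4), 0)
  expect_true(attr(xr, "rank_deficient"))
})

test_that("regularization path has the stated grid and monotone norms", {
  withr::local_seed(7)
  A <- build_design_matrix(10^seq(-4, 1, 0.1), build_lifetime_grid(1e-4, 10, 40))
  y <- rnorm(nrow(A))
  p <- regularization_path(A, y)
  expect_equal(nrow(p), 200)
  expect_equal(p$alpha[1], 0.01)
  expect_equal(p$alpha[200], 5)
  expect_true(all(diff(p$residual_norm) >= -1e-10))
  expect_true(all(diff(p$solution_norm) <= 1e-10))
  # norms match an independent per-alpha recomputation
  for (i in c(1, 57, 200)) {
    x <- tikhonov_solve(A, y, p$alpha[i])
    expect_equal(p$residual_norm[i], sqrt(sum((A %*% x - y)^2)), tolerance = 1e-9)
    expect_equal(p$solution_norm[i], sqrt(sum(x^2)), tolerance = 1e-9)
  }
  expect_error(regularization_path(A, y, alpha_min = 0), "alpha_min")
})

test_that("L-curve corner finds a constructed corner and matches a fine-grid oracle", {
  # two straight log-log segments joined at one point
  lx <- c(0, 0, 0, 0, 0, 1, 2, 3, 4)
  ly <- c(8, 6, 4, 2, 0, 0, 0, 0, 0)
  path <- tibble::tibble(alpha = 10^seq(-2, 0.7, length.out = 9),
                         residual_norm = exp(lx), solution_norm = exp(ly))
  class(path) <- c("regularization_path", class(path))
  a <- l_curve_corner(path)
  expect_identical(attr(a, "index"), 5L)

  # ill-posed single-exponential inversion vs exhaustive fine-grid maximization
  sch <- photocycle_scheme("X", 1e-3, 620, 30)
  cfg <- simulation_config(seed = 7, noise_sigma = 0.01, time_start = 1e-6,
                           time_end = 1, linear_end = 1e-5,
                           points_per_decade = 12, wl_start = 620,
                           wl_end = 640, wl_step = 20)
  ds <- simulate_transient_dataset(sch, cfg)
  A <- build_design_matrix(ds$times, build_lifetime_grid(1e-5, 3, 100))
  y <- ds$delta_A[, 1]
  coarse <- regularization_path(A, y, m = 60)
  a_coarse <- l_curve_corner(coarse)
  fine <- regularization_path(A, y, m = 600)
  lxf <- log(fine$residual_norm); lyf <- log(fine$solution_norm)
  i <- 2:599
  dx <- (lxf[i + 1] - lxf[i - 1]) / 2; dy <- (lyf[i + 1] - lyf[i - 1]) / 2
  ddx <- lxf[i + 1] - 2 * lxf[i] + lxf[i - 1]
  ddy <- lyf[i + 1] - 2 * lyf[i] + lyf[i - 1]
  kap <- (dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5
  a_fine <- fine$alpha[i[which.max(kap)]]
  step <- (5 / 0.01)^(1 / 59)
  expect_lt(abs(log(as.numeric(a_coarse) / a_fine)), log(step) * 1.5)

  # degenerate flat curve falls back to the median factor with a warning
  flat <- tibble::tibble(alpha = 10^seq(-2, 0.7, length.out = 9),
                         residual_norm = rep(1, 9), solution_norm = rep(1, 9))
  class(flat) <- c("regularization_path", class(flat))
  expect_warning(am <- l_curve_corner(flat), "degenerate")
  expect_equal(as.numeric(am), flat$alpha[5])
})

test_that("noise-free single-exponential surfaces peak at the planted lifetime", {
  sch <- photocycle_scheme("X", 1e-3, 620, 30)
  cfg <- simulation_config(noise_sigma = 0, time_start = 1e-6, time_end = 1,
                           linear_end = 1e-5, points_per_decade = 12,
                           wl_start = 380, wl_end = 660, wl_step = 20)
  ds <- simulate_transient_dataset(sch, cfg)
  grid <- build_lifetime_grid(1e-5, 3, 100)
  ldm <- compute_ldm(ds, grid = grid, n_alpha = 80)
  for (w in ds$wavelengths) {
    pk <- peak_lifetimes(ldm, w)
    dom <- pk$lifetime[which.max(abs(pk$amplitude))]
    expect_true(recovered_within_step(tibble::tibble(lifetime = dom), 1e-3, grid))
  }
  # sign convention: bleach wavelength negative, photoproduct positive
  p525 <- peak_lifetimes(ldm, 525)
  p620 <- peak_lifetimes(ldm, 620)
  expect_lt(p525$amplitude[which.max(abs(p525$amplitude))], 0)
  expect_gt(p620$amplitude[which.max(abs(p620$amplitude))], 0)
})

test_that("two-exponential surfaces resolve both lifetimes at SNR 100", {
  sch <- photocycle_scheme(c("A", "B"), c(1e-3, 1e-1), c(620, 400), c(30, 25))
  cfg <- simulation_config(seed = 3, noise_sigma = 0.01, time_start = 1e-6,
                           time_end = 2, linear_end = 1e-5,
                           points_per_decade = 15, wl_start = 380,
                           wl_end = 660, wl_step = 20)
  ds <- simulate_transient_dataset(sch, cfg)
  grid <- build_lifetime_grid(1e-5, 6, 100)
  ldm <- compute_ldm(ds, grid = grid, n_alpha = 80)
  pk <- peak_lifetimes(ldm, 400, amplitude_floor = 0.1)
  expect_gte(nrow(pk), 2)
  expect_true(recovered_within_step(pk, 1e-3, grid))
  expect_true(recovered_within_step(pk, 1e-1, grid))
  # reconstruction residual stays within 1.5x the injected noise level
  for (j in seq_along(ds$wavelengths)) {
    ynorm <- sqrt(sum(ds$delta_A[ds$times > 0, j]^2))
    noise_rel <- 0.01 * sqrt(sum(ds$times > 0)) / ynorm
    expect_lte(ldm$residual[j], 1.5 * noise_rel)
  }
})

test_that("global mode selects one factor for the stacked system", {
  sch <- photocycle_scheme("X", 1e-3, 620, 30)
  cfg <- simulation_config(seed = 4, noise_sigma = 0.005, time_start = 1e-6,
                           time_end = 1, linear_end = 1e-5,
                           points_per_decade = 10, wl_start = 560,
                           wl_end = 660, wl_step = 20)
  ds <- simulate_transient_dataset(sch, cfg)
  grid <- build_lifetime_grid(1e-5, 3, 80)
  ldm <- compute_ldm(ds, grid = grid, n_alpha = 60, mode = "global")
  expect_length(ldm$alpha, 1)
  pk <- peak_lifetimes(ldm, 620)
  dom <- pk$lifetime[which.max(abs(pk$amplitude))]
  expect_true(recovered_within_step(tibble::tibble(lifetime = dom), 1e-3, grid))
})

test_that("peak detection handles zero, single and double distributions", {
  grid <- build_lifetime_grid(1e-4, 1, 50)
  zero <- structure(list(grid = grid, wavelengths = 500,
                         amplitudes = matrix(0, 50, 1), alpha = 1,
                         residual = 0, mode = "per-wavelength"), class = "ldm")
  expect_identical(nrow(peak_lifetimes(zero, 500)), 0L)
  x <- dnorm(log(as.numeric(grid)), log(1e-2), 0.3) -
    dnorm(log(as.numeric(grid)), log(0.3), 0.3)
  two <- structure(list(grid = grid, wavelengths = 500,
                        amplitudes = matrix(x, ncol = 1), alpha = 1,
                        residual = 0, mode = "per-wavelength"), class = "ldm")
  pk <- peak_lifetimes(two, 500)
  expect_identical(nrow(pk), 2L)
  expect_true(all(diff(pk$lifetime) > 0))
  expect_lt(pk$amplitude[2], 0)
})

test_that("transient reduction preserves bin means and LDA recoverability", {
  t_raw <- seq(0.001, 10, by = 0.001)
  const <- reduce_transient(t_raw, rep(2, length(t_raw)), linear_end = 0.01,
                            points_per_decade = 10)
  expect_true(all(const$value == 2))
  expect_true(all(diff(const$time) > 0))
  # a single bin of values {1,2,3} averages to 2
  r <- reduce_transient(c(0.5, 1.05, 1.10, 1.15), c(9, 1, 2, 3),
                        linear_end = 1, points_per_decade = 1)
  expect_equal(r$value, c(9, 2))
  expect_equal(r$time[2], mean(c(1.05, 1.10, 1.15)))
  # reduction then inversion still recovers the lifetime
  y <- exp(-t_raw / 0.05)
  red <- reduce_transient(t_raw, y, linear_end = 0.01, points_per_decade = 15)
  grid <- build_lifetime_grid(1e-3, 30, 80)
  ds <- transient_dataset(red$time, 600, matrix(red$value, ncol = 1))
  ldm <- compute_ldm(ds, grid = grid, n_alpha = 60)
  pk <- peak_lifetimes(ldm, 600)
  dom <- pk$lifetime[which.max(abs(pk$amplitude))]
  expect_true(recovered_within_step(tibble::tibble(lifetime = dom), 0.05, grid))
})

test_that("normalization at the reference time rescales as stated", {
  t <- 10^seq(-5, 0, 0.1)
  base <- exp(-t / 1e-3) + 0.3 * exp(-t / 0.1)
  tr <- dplyr::bind_rows(
    tibble::tibble(id = "a", time = t, value = base),
    tibble::tibble(id = "b", time = t, value = base),
    tibble::tibble(id = "c", time = t, value = 3 * base))
  out <- normalize_at_time(tr, t_ref = 1e-4)
  f <- attr(out, "factors")
  expect_equal(f$factor, c(1, 1, 1 / 3))
  expect_equal(out$value[out$id == "c"], base)
  # interpolated reference value matches the approx() oracle
  v_ref <- approx(t, 3 * base, xout = 1e-4)$y
  expect_equal(f$factor[3], approx(t, base, xout = 1e-4)$y / v_ref)
  expect_error(normalize_at_time(tibble::tibble(id = "a", time = c(1, 2),
                                                value = c(0, 0)), t_ref = 1.5),
               "zero value")
})
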