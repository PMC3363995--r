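# All closed-form expectations come from di_gaussian_exact() on exact model
# covariances (Lyapunov / forward-propagated), which is validated against
# sample-based estimates inside these tests.

test_that("DI is near zero for independent ensembles and detects direction", {
  set.seed(20)
  x <- trial_ensemble(matrix(rnorm(2048 * 5), 2048))
  y <- trial_ensemble(matrix(rnorm(2048 * 5), 2048))
  cfg <- gauss_cfg()
  expect_lt(abs(directed_information(x, y, cfg, horizon = 5)), 0.1)

  spec <- fixed_pair_spec(gamma = 0.8)
  sim <- simulate_linear_ar(spec, 4096, 12, seed = 21)
  di_yx <- directed_information(sim$y, sim$x, cfg, horizon = 10)
  di_xy <- directed_information(sim$x, sim$y, cfg, horizon = 10)
  # unidirectional model: reverse DI is estimator bias only
  expect_lt(di_yx, 0.05)
  expect_gt(di_xy, 10 * di_yx)
})

test_that("DI rate agrees with the Geweke index on a linear Gaussian system", {
  spec <- strong_pair_spec()
  # exact asymptotic rate of the delayed DI from the exact covariance
  N <- 60
  Sig <- linear_ar_cov(spec, N)
  mifc <- neurodi:::mi_from_cov
  rate_exact <- mifc(Sig, 1:(N - 1), N + 1:N) -
    mifc(Sig, 1:(N - 1), N + 1:(N - 1))
  f <- granger_f(simulate_linear_ar(spec, 1, 32768, seed = 22)$x$data[1, ],
                 simulate_linear_ar(spec, 1, 32768, seed = 22)$y$data[1, ],
                 order = 1)
  expect_lt(abs(f - rate_exact) / rate_exact, 0.1)
})

test_that("time-lagged DI with the true delay matches full DI (closed form)", {
  # hand-checkable toy: N = 3, p1 = 1, exact covariance
  spec <- strong_pair_spec()
  Sig <- linear_ar_cov(spec, 3)
  mifc <- neurodi:::mi_from_cov
  # five-entropy block of the two-sample time-lagged DI at n = 2, via MI form
  di2 <- mifc(Sig, 1, 3 + 2) +
    (mifc(Sig, 1:2, 3 + 2:3) - mifc(Sig, 1:2, 3 + 2))
  head1 <- mifc(Sig, 1, 3 + 1)
  tl_exact <- head1 + (3 - 1) / (2 * (3 - 1 - 1)) * di2

  set.seed(23)
  sim <- simulate_linear_ar(spec, 60000, 3, seed = 23, burn_in = 100)
  cfg <- di_config(p = 1, p1 = 1, estimator = estimator_config("gaussian"))
  tl_est <- time_lagged_di(sim$x, sim$y, cfg)
  expect_lt(abs(tl_est - tl_exact), 0.02)

  # equivalence with full DI for a single-order system with the true delay
  sim2 <- simulate_linear_ar(spec, 4096, 12, seed = 24)
  tl <- time_lagged_di(sim2$x, sim2$y, cfg)
  di <- directed_information(sim2$x, sim2$y, cfg, horizon = 12)
  expect_lt(abs(tl - di), 0.1 + 0.1 * abs(di))

  # independent pair: both near zero
  xi <- trial_ensemble(matrix(rnorm(4096 * 8), 4096))
  yi <- trial_ensemble(matrix(rnorm(4096 * 8), 4096))
  expect_lt(abs(time_lagged_di(xi, yi, cfg)), 0.1)
  expect_error(time_lagged_di(trial_ensemble(matrix(rnorm(8), 4)),
                              trial_ensemble(matrix(rnorm(8), 4)),
                              di_config(p = 1, p1 = 1)), "too short")
})

test_that("MDI upper-bounds DI and vanishes for degenerate copies", {
  # exact-covariance check of the upper bound (independent initial values,
  # the setting of the bound's derivation)
  spec <- fixed_pair_spec(gamma = 0.8)
  N <- 12; p <- 2
  Sig <- linear_ar_cov(spec, N, stationary = FALSE)
  mifc <- neurodi:::mi_from_cov
  mdi_exact <- 0
  for (n in (p + 1):N) {
    xw <- (n - p):(n - 1); yw <- N + (n - p):(n - 1); yn <- N + n
    mdi_exact <- mdi_exact + mifc(Sig, xw, c(yn, yw)) - mifc(Sig, xw, yw)
  }
  di_exact <- di_gaussian_exact(Sig, N)$di_xy
  expect_gte(mdi_exact, di_exact - 1e-9)

  # and on sampled data from the same start-up condition
  sim <- simulate_linear_ar(spec, 4096, N, seed = 25, burn_in = 0)
  cfg <- gauss_cfg(p = 2)
  di <- directed_information(sim$x, sim$y, cfg, horizon = N)
  md <- mdi(sim$x, sim$y, cfg, horizon = N)
  expect_gte(md, di - 0.1)

  # identical copies: Y_n is deterministic given the conditioning set, so
  # every CMI term collapses to zero by convention
  cfg_ap <- di_config(2, estimator = estimator_config("adaptive_partition"))
  sim2 <- simulate_linear_ar(spec, 4096, 14, seed = 25)
  expect_identical(mdi(sim2$x, sim2$x, cfg_ap, horizon = 12), 0)
  expect_identical(mdi(sim2$x, sim2$x, cfg, horizon = 12), 0)
})

test_that("pooled and per-step MDI agree on stationary data", {
  spec <- fixed_pair_spec(gamma = 0.8)
  sim <- simulate_linear_ar(spec, 2048, 20, seed = 26)
  cfg <- gauss_cfg(p = 2)
  a <- mdi(sim$x, sim$y, cfg, horizon = 16)
  b <- mdi(sim$x, sim$y, cfg, horizon = 16, pooled = TRUE)
  expect_lt(abs(a - b), 0.15 * max(a, b))
})

test_that("conservation: DI(X->Y) + DI(Y->X) = I(X;Y) without instantaneous coupling", {
  spec <- fixed_pair_spec(gamma = 0.7)
  N <- 12
  # independent start-up: no zero-lag dependence anywhere, identity exact
  ex <- di_gaussian_exact(linear_ar_cov(spec, N, stationary = FALSE), N)
  expect_lt(abs(ex$di_xy + ex$di_yx - ex$mi), 1e-8)

  # Massey conservation DI(X->Y) + DI(DY->X) = I(X^N;Y^N) holds for any
  # joint law, including the stationary start
  Sig <- linear_ar_cov(spec, N, stationary = TRUE)
  mifc <- neurodi:::mi_from_cov
  di_xy <- di_gaussian_exact(Sig, N)$di_xy
  di_dyx <- 0
  for (n in 2:N) di_dyx <- di_dyx +
    mifc(Sig, N + 1:(n - 1), 1:n) - mifc(Sig, N + 1:(n - 1), 1:(n - 1))
  expect_lt(abs(di_xy + di_dyx - mifc(Sig, 1:N, N + 1:N)), 1e-8)
})

test_that("delayed/instantaneous decomposition separates lagged from zero-lag coupling", {
  # strictly lagged system: instantaneous part ~ 0
  spec <- fixed_pair_spec(gamma = 0.8)
  sim <- simulate_linear_ar(spec, 4096, 10, seed = 27)
  cfg <- gauss_cfg()
  dec <- delayed_and_instantaneous(sim$x, sim$y, cfg, horizon = 8)
  di <- directed_information(sim$x, sim$y, cfg, horizon = 8)
  expect_lt(abs(dec$instantaneous), 0.1)
  expect_gt(dec$di_delayed_xy, 0.5 * di)

  # identity Eq-style check in closed form: delayed fwd + delayed rev + inst = MI
  N <- 8
  Sig <- linear_ar_cov(spec, N)
  mifc <- neurodi:::mi_from_cov
  di_dir <- function(xoff, yoff, delayed) {
    tot <- 0
    for (n in seq_len(N)) {
      up <- if (delayed) n - 1 else n
      a <- if (up >= 1) mifc(Sig, xoff + 1:up, yoff + 1:n) else 0
      b <- if (n > 1 && up >= 1) mifc(Sig, xoff + 1:up, yoff + 1:(n - 1)) else 0
      tot <- tot + (a - b)
    }
    tot
  }
  lhs <- di_dir(0, N, TRUE) + di_dir(N, 0, TRUE) +
    (di_dir(0, N, FALSE) - di_dir(0, N, TRUE))
  expect_lt(abs(lhs - mifc(Sig, 1:N, N + 1:N)), 1e-8)

  # pure common signal: instantaneous dominates
  set.seed(28)
  z <- matrix(rnorm(4096 * 8), 4096)
  xz <- trial_ensemble(z + 0.1 * matrix(rnorm(length(z)), nrow(z)))
  yz <- trial_ensemble(z + 0.1 * matrix(rnorm(length(z)), nrow(z)))
  dec2 <- delayed_and_instantaneous(xz, yz, cfg, horizon = 6)
  expect_gt(dec2$instantaneous, 5 * abs(dec2$di_delayed_xy))
})

test_that("normalized DI clips, sums to one, and flags the undefined case", {
  expect_equal(normalized_di(0.3, 0.1)[c("rho_xy", "rho_yx")],
               list(rho_xy = 0.75, rho_yx = 0.25))
  r <- normalized_di(-0.02, 0.05)
  expect_equal(c(r$rho_xy, r$rho_yx), c(0, 1))
  expect_false(r$undefined)
  u <- normalized_di(-1e-15, 0)
  expect_true(u$undefined)
  expect_equal(c(u$rho_xy, u$rho_yx), c(0.5, 0.5))
  # property: in [0,1] and summing to 1 over random inputs
  set.seed(29)
  for (i in 1:50) {
    v <- normalized_di(rnorm(1), rnorm(1))
    expect_gte(min(v$rho_xy, v$rho_yx), 0)
    expect_equal(v$rho_xy + v$rho_yx, 1)
  }
})

test_that("unidirectional exact-covariance system gives rho = (1, 0)", {
  spec <- strong_pair_spec()
  Sig <- linear_ar_cov(spec, 20, stationary = FALSE)
  ex <- di_gaussian_exact(Sig, 20)
  expect_equal(ex$rho_xy, 1, tolerance = 1e-9)
  expect_equal(ex$rho_yx, 0, tolerance = 1e-9)
  expect_lt(abs(ex$di_yx), 1e-10)
})

test_that("adaptive-partition DI refuses horizons its sample size cannot support", {
  x <- trial_ensemble(matrix(rnorm(64 * 30), 64))
  y <- trial_ensemble(matrix(rnorm(64 * 30), 64))
  cfg <- di_config(2, estimator = estimator_config("adaptive_partition"))
  expect_error(directed_information(x, y, cfg, horizon = 20), "mdi")
})
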