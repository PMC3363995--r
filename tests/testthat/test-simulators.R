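test_that("stable coefficient draws respect the AR stability region", {
  set.seed(60)
  a1 <- draw_stable_ar_coefficients(1)
  expect_true(abs(a1) < 1)
  a5 <- draw_stable_ar_coefficients(5)
  expect_lt(neurodi:::ar_spectral_radius(a5), 1)
  set.seed(61); b <- draw_stable_ar_coefficients(5)
  set.seed(61); b2 <- draw_stable_ar_coefficients(5)
  expect_identical(b, b2)
})

test_that("simulators are bit-reproducible under a fixed seed", {
  spec <- fixed_pair_spec()
  s1 <- simulate_linear_ar(spec, 16, 30, seed = 62)
  s2 <- simulate_linear_ar(spec, 16, 30, seed = 62)
  expect_identical(s1$x$data, s2$x$data)
  expect_identical(s1$y$data, s2$y$data)
  set.seed(60)
  ss <- random_single_source_spec(5, 0.4)
  expect_identical(simulate_single_source(ss, 8, 20, seed = 63)$y$data,
                   simulate_single_source(ss, 8, 20, seed = 63)$y$data)
  lz1 <- simulate_lorenz_pair(lorenz_spec(), 8, seed = 64)
  lz2 <- simulate_lorenz_pair(lorenz_spec(), 8, seed = 64)
  expect_identical(lz1$x2$data, lz2$x2$data)
})

test_that("generated ensembles match the exact model covariance (Lyapunov oracle)", {
  spec <- fixed_pair_spec(gamma = 0.6)
  N <- 6
  sim <- simulate_linear_ar(spec, 30000, N, seed = 65, burn_in = 0)
  Sig <- linear_ar_cov(spec, N, stationary = FALSE)
  emp <- cov(cbind(sim$x$data, sim$y$data))
  # every entry within 3 standard errors (~3 * maxvar / sqrt(n))
  tol <- 3 * max(diag(Sig)) / sqrt(30000)
  expect_lt(max(abs(emp - Sig)), 5 * tol)

  # stationary covariance oracle: burn-in brings the process to the
  # stationary law solved from the Lyapunov equation
  sim2 <- simulate_linear_ar(spec, 30000, N, seed = 66, burn_in = 100)
  SigS <- linear_ar_cov(spec, N, stationary = TRUE)
  emp2 <- cov(cbind(sim2$x$data, sim2$y$data))
  expect_lt(max(abs(emp2 - SigS)), 5 * tol)

  # stationarity sanity: per-time variance stable after burn-in
  vr <- apply(sim2$x$data, 2, var)
  expect_lt(max(vr) / min(vr), 1.5)
})

test_that("decoupled and sigmoid-coupled models behave at their limits", {
  spec0 <- fixed_pair_spec(gamma = 0)
  sim <- simulate_linear_ar(spec0, 2048, 30, seed = 67)
  cfg <- gauss_cfg()
  r <- mdi_test(sim$x, sim$y, cfg, n_shuffles = 60, seed = 68, horizon = 15)
  expect_false(r$significant)

  # b2 = 0 makes the sigmoid coupling constant: no information flow, so
  # rejections stay at the nominal false-positive level across seeds
  specc <- nonlinear_ar_spec(alpha = c(0.5, -0.2), beta = c(0.4, 0.1),
                             gamma = 0.8, p2 = 2, b1 = 0, b2 = 0)
  hits <- sum(sapply(1:3, function(s) {
    simc <- simulate_nonlinear_ar(specc, 1024, 30, seed = 68 + s)
    mdi_test(simc$x, simc$y, cfg, n_shuffles = 60, seed = 80 + s,
             horizon = 15)$significant
  }))
  expect_lte(hits, 1)

  # sigmoid output bounded in (0, 1): the coupling term per lag is bounded
  set.seed(71)
  spb <- random_nonlinear_ar_spec(3, gamma = 1)
  sb <- simulate_nonlinear_ar(spb, 64, 40, seed = 71)
  sig_vals <- 1 / (1 + exp(spb$b1 + spb$b2 * sb$x$data))
  # mathematically in (0, 1); saturates to the closed endpoints in floating
  # point for |b2 * x| beyond ~745
  expect_true(all(sig_vals >= 0 & sig_vals <= 1))
})

test_that("linear mixing follows the mixture identities exactly", {
  spec <- fixed_pair_spec()
  sim <- simulate_linear_ar(spec, 32, 20, seed = 72)
  m0 <- apply_mixing(sim$x, sim$y, 0)
  expect_identical(m0$x$data, sim$x$data)
  m5 <- apply_mixing(sim$x, sim$y, 0.5)
  expect_identical(m5$x$data, m5$y$data)
  cx <- trial_ensemble(matrix(2, 4, 6))
  cy <- trial_ensemble(matrix(4, 4, 6))
  m25 <- apply_mixing(cx, cy, 0.25)
  expect_true(all(m25$x$data == 2.5) && all(m25$y$data == 3.5))
  # linearity: mixing commutes with trial averaging
  mx <- apply_mixing(sim$x, sim$y, 0.3)
  expect_equal(colMeans(mx$x$data),
               0.7 * colMeans(sim$x$data) + 0.3 * colMeans(sim$y$data))
})

test_that("single-source model spans the advertised SNR range with no lagged causality", {
  set.seed(73)
  snrs <- sapply(c(0.1, 0.5, 0.9), function(eps) {
    spec <- random_single_source_spec(5, eps)
    sim <- simulate_single_source(spec, 64, 400, seed = 74)
    10 * log10(((1 - eps)^2 * var(as.vector(sim$x$data))) / eps^2)
  })
  expect_gt(snrs[1], 15)    # eps = 0.1: strong source
  expect_lt(snrs[3], -10)   # eps = 0.9: buried in noise
  expect_true(all(diff(snrs) < 0))
})

test_that("Lorenz pair integrates with the printed delay and converges as dt shrinks", {
  sp <- lorenz_spec(dt = 0.01, t_p = 0.02)
  expect_identical(sp$lag_samples, 2L)
  expect_error(lorenz_spec(dt = 0.008, t_p = 0.02), "integer multiple")

  # step-halving convergence on one trial: errors vs a dt/4 reference
  # shrink by about half when dt halves (Euler is first order)
  ref <- simulate_lorenz_pair(lorenz_spec(dt = 0.0025, t_p = 0.02,
                                          n_total = 400, n_discard = 360),
                              1, seed = 75)
  r1 <- simulate_lorenz_pair(lorenz_spec(dt = 0.01, t_p = 0.02), 1,
                             seed = 75)
  r2 <- simulate_lorenz_pair(lorenz_spec(dt = 0.005, t_p = 0.02,
                                         n_total = 200, n_discard = 180),
                             1, seed = 75)
  take <- function(sim, step) sim$x1$data[1, seq(step, ncol(sim$x1$data),
                                                 step)]
  e1 <- max(abs(take(r1, 1) - take(ref, 4)))
  e2 <- max(abs(take(r2, 2) - take(ref, 4)))
  expect_lt(e2, 0.75 * e1)

  # decoupled oscillators are independent: beta = 0
  lz0 <- simulate_lorenz_pair(lorenz_spec(beta_coupling = 0), 512, seed = 76)
  cfg <- di_config(3, estimator = estimator_config("gaussian"))
  r <- mdi_test(lz0$x1, lz0$x2, cfg, n_shuffles = 60, seed = 77)
  expect_false(r$significant)
})
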