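make_mce <- function(n_ch = 3, n_tr = 24, n_t = 40, fs = 512, seed = 1) {
  set.seed(seed)
  chans <- lapply(seq_len(n_ch), function(k)
    trial_ensemble(matrix(rnorm(n_tr * n_t), n_tr), fs, paste0("ch", k)))
  names(chans) <- paste0("ch", seq_len(n_ch))
  multichannel_ensemble(chans)
}

test_that("band-pass keeps the passband, kills the stopband, zero phase", {
  fs <- 512
  tt <- (0:511) / fs
  mk <- function(f) trial_ensemble(matrix(rep(sin(2 * pi * f * tt), 4),
                                          4, byrow = TRUE), fs)
  in_band <- bandpass(mk(6), 4, 8)
  out_band <- bandpass(mk(20), 4, 8)
  mid <- 100:400   # avoid filter edge effects
  amp <- function(e) max(abs(e$data[1, mid]))
  expect_gt(amp(in_band), 0.95)
  expect_lt(amp(out_band), 0.1)
  # zero phase: the 6 Hz component is not shifted
  ref <- sin(2 * pi * 6 * tt)
  lagcor <- cor(in_band$data[1, mid], ref[mid])
  expect_gt(lagcor, 0.99)
  expect_error(bandpass(mk(6), 4, 300), "Nyquist")

  # white noise: spectral mass concentrates in the band (periodogram oracle)
  set.seed(90)
  wn <- trial_ensemble(matrix(rnorm(4096), 1), fs)
  fl <- bandpass(wn, 4, 8)
  sp <- spec.pgram(fl$data[1, ], plot = FALSE, taper = 0)
  freq_hz <- sp$freq * fs
  inb <- sum(sp$spec[freq_hz >= 3 & freq_hz <= 9])
  expect_gt(inb / sum(sp$spec), 0.9)
})

test_that("ensemble CSV round-trips losslessly and flags malformed input", {
  mce <- make_mce(seed = 2)
  f <- tempfile(fileext = ".csv")
  write_ensemble(mce, f)
  back <- read_ensemble(f, 512)
  expect_identical(back$channel_names, mce$channel_names)
  for (nm in mce$channel_names)
    expect_identical(back$channels[[nm]]$data, mce$channels[[nm]]$data)

  # drop one cell -> parse error naming the gap
  df <- read.csv(f)
  bad <- tempfile(fileext = ".csv")
  write.csv(df[-5, ], bad, row.names = FALSE, quote = FALSE)
  expect_error(read_ensemble(bad), "missing|expected")
  # duplicate channel names collapse is caught at construction
  expect_error(multichannel_ensemble(list(a = mce$channels[[1]],
                                          a = mce$channels[[2]])),
               "unique")
})

test_that("connectivity pipeline recovers a planted edge and composes with the parts", {
  # 3 channels: true edge ch1 -> ch2 via the linear benchmark, ch3 noise
  # n_shuffles sets the attainable p-value floor (1/(n+1)); BH over the 6
  # ordered pairs needs p <= q/6, so 150 shuffles leave the floor below it
  spec <- fixed_pair_spec(gamma = 0.9)
  sim <- simulate_linear_ar(spec, 128, 40, seed = 91)
  chans <- list(A = sim$x, B = sim$y,
                C = trial_ensemble(matrix(rnorm(128 * 40), 128)))
  mce <- multichannel_ensemble(chans)
  res <- pairwise_connectivity(mce, window_start = 5, window_len = 30,
                               n_shuffles = 150, seed = 92,
                               cao = cao_config(max_dim = 4,
                                                max_points = 1000))
  expect_true(res$mask_di["A", "B"])
  expect_false(res$mask_di["B", "A"])
  expect_lt(sum(res$mask_di, na.rm = TRUE), 4)  # no wholesale selection
  expect_true(all(is.na(diag(res$di_matrix))))
  expect_identical(length(res$failures), 0L)

  # composition: the pipeline's A->B numbers equal standalone calls with the
  # same seed and settings
  wa <- trial_ensemble(sim$x$data[, 5:34], 1, "A")
  wb <- trial_ensemble(sim$y$data[, 5:34], 1, "B")
  p <- select_order(wa, wb, cao_config(max_dim = 4, max_points = 1000))
  pair_seed <- (92 + 7907L * 1 + 131L * 2) %% .Machine$integer.max
  dt <- mdi_test(wa, wb, di_config(as.integer(p),
                                   estimator = estimator_config("gaussian")),
                 n_shuffles = 150, seed = pair_seed)
  expect_identical(res$di_matrix["A", "B"], dt$di_xy)
  expect_identical(res$p_di["A", "B"], dt$p_value)

  # changing the shuffle count changes p-values only, not observed matrices
  res2 <- pairwise_connectivity(mce, window_start = 5, window_len = 30,
                                n_shuffles = 75, seed = 92,
                                cao = cao_config(max_dim = 4,
                                                 max_points = 1000))
  expect_identical(res2$di_matrix, res$di_matrix)
  expect_identical(res2$gc_matrix, res$gc_matrix)

  # result JSON round-trip
  f <- tempfile(fileext = ".json")
  write_result(res, f)
  back <- read_result(f)
  expect_equal(back$di_matrix, res$di_matrix, tolerance = 1e-12)
  expect_identical(back$mask_di, res$mask_di)
  expect_equal(back$p_gc, res$p_gc, tolerance = 1e-12)
})

test_that("all-independent ensembles select few edges under FDR", {
  mce <- make_mce(n_ch = 4, n_tr = 64, n_t = 30, seed = 93)
  res <- pairwise_connectivity(mce, n_shuffles = 60, seed = 94,
                               cao = cao_config(max_dim = 3,
                                                max_points = 800))
  frac <- mean(res$mask_di, na.rm = TRUE)
  expect_lte(frac, 0.05 + 0.03)
})
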