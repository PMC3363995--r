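#' Directed-information configuration
#'
#' @param p model order / window length used by [mdi()] (the maximum of the
#'   two marginal process orders in the benchmark models).
#' @param p1 transmission delay in samples used by [time_lagged_di()].
#'   Defaults to 1: using a one-sample lag loses no information flow relative
#'   to the true delay, at the price of a longer conditioning window.
#' @param estimator an [estimator_config()].
#' @return An object of class `di_config`.
#' @export
di_config <- function(p, p1 = 1, estimator = estimator_config()) {
  stopifnot(p >= 1, p1 >= 1)
  structure(list(p = as.integer(p), p1 = as.integer(p1),
                 estimator = estimator),
            class = "di_config")
}

#' @export
print.di_config <- function(x, ...) {
  cat(sprintf("<di_config: p = %d, p1 = %d, estimator = %s>\n",
              x$p, x$p1, x$estimator$method))
  invisible(x)
}

# across-trial MI between two sets of time indices (helper)
ens_mi <- function(x, y, ix, iy, cfg) {
  estimate_mi(x$data[, ix, drop = FALSE], y$data[, iy, drop = FALSE], cfg)
}

#' Directed information between two trial ensembles
#'
#' Computes `DI(X -> Y) = sum_n [ I(X^n; Y^n) - I(X^n; Y^{n-1}) ]` over
#' growing windows, with each joint density estimated across trials.  This is
#' the telescoped form of the sum of conditional mutual informations
#' `I(X^n; Y_n | Y^{n-1})`.  The joint dimension grows with the horizon, so
#' for nonparametric estimators the horizon is limited by the number of
#' trials; beyond that limit an error suggests [mdi()], whose window stays
#' fixed.
#'
#' @param x,y aligned `trial_ensemble`s (source `x`, target `y`).
#' @param cfg a [di_config()]; only its estimator is used here.
#' @param horizon number of time samples `N` to accumulate over (defaults to
#'   the full ensemble length).
#' @return DI in units of the configured log base (bits by default); the sum
#'   over the window, not a per-sample rate.
#' @seealso [mdi()] for the fixed-window upper bound, [di_gaussian_exact()]
#'   for the closed form on an exact covariance.
#' @export
directed_information <- function(x, y, cfg, horizon = n_time(x)) {
  di_general(x, y, cfg, horizon, delay = 0L)
}

# DI with the source delayed by `delay` samples:
# sum_n I(X^{n-delay}; Y_n | Y^{n-1}), via the telescoped MI form
di_general <- function(x, y, cfg, horizon, delay = 0L) {
  check_aligned(x, y)
  est <- cfg$estimator
  N <- horizon
  stopifnot(N >= 1, N <= n_time(x))
  if (est$method == "adaptive_partition" && N > log2(n_trials(x)))
    stop("horizon too large for the adaptive-partition estimator at this ",
         "trial count (joint dimension 2N = ", 2 * N, "); use mdi() instead")
  total <- 0
  for (n in seq_len(N)) {
    up <- n - delay
    if (up < 1) next
    a <- ens_mi(x, y, 1:up, 1:n, est)
    b <- if (n > 1) ens_mi(x, y, 1:up, 1:(n - 1), est) else 0
    total <- total + (a - b)
  }
  total
}

#' Time-lagged directed information
#'
#' Approximates DI over the whole series from blocks of two consecutive
#' samples with a fixed transmission delay `p1`: each block contributes
#' `DI_n = I(X_{n-p1}; Y_n) + I(X_{n-p1}, X_{n-p1+1}; Y_{n+1} | Y_n)` and
#' the total is
#' `sum_{n<=p1} I(X^n; Y_n | Y^{n-1}) +
#'  (N - p1) / (2 (N - p1 - 1)) * sum_{n=p1+1}^{N-1} DI_n`.
#' Equivalent to [directed_information()] when `p1` matches the true system
#' delay and the model is single-order with one-sample `Y` memory.
#'
#' @inheritParams directed_information
#' @return Time-lagged DI in configured units.
#' @export
time_lagged_di <- function(x, y, cfg) {
  check_aligned(x, y)
  est <- cfg$estimator
  p1 <- cfg$p1
  N <- n_time(x)
  if (N - p1 - 1 <= 0) stop("series too short for lag p1 = ", p1)
  head_part <- 0
  for (n in seq_len(p1)) {
    a <- ens_mi(x, y, 1:n, 1:n, est)
    b <- if (n > 1) ens_mi(x, y, 1:n, 1:(n - 1), est) else 0
    head_part <- head_part + (a - b)
  }
  block_sum <- 0
  for (n in (p1 + 1):(N - 1)) {
    a <- x$data[, n - p1, drop = FALSE]                 # X_{n-p1}
    ab <- x$data[, c(n - p1, n - p1 + 1), drop = FALSE] # X_{n-p1}, X_{n-p1+1}
    yn <- y$data[, n, drop = FALSE]
    ynn <- y$data[, c(n, n + 1), drop = FALSE]
    block_sum <- block_sum +
      estimate_mi(a, yn, est) +
      estimate_mi(ab, ynn, est) - estimate_mi(ab, yn, est)
  }
  head_part + (N - p1) / (2 * (N - p1 - 1)) * block_sum
}

#' Modified time-lagged directed information (MDI)
#'
#' The fixed-window upper bound on directed information for a stationary
#' Markov pair:
#' `MDI(X -> Y) = sum_{n=p+1}^{N} I(X_{n-p..n-1}; Y_n | Y_{n-p..n-1})`,
#' with each conditional MI estimated across trials.  The window length `p`
#' (from `cfg$p`) should cover the larger of the two process orders; it can
#' be selected model-free with [select_order()].  Because only past samples
#' of `X` enter, MDI excludes instantaneous (zero-lag) dependence by
#' construction.  `MDI >= DI` for such systems (conditioning on the shorter
#' window can only increase each term).
#'
#' @inheritParams directed_information
#' @param horizon number of samples `N` to accumulate over.
#' @param pooled see [mdi_components()].
#' @return MDI in configured units (a sum over the window).
#' @export
mdi <- function(x, y, cfg, horizon = n_time(x), pooled = FALSE) {
  mdi_components(x, y, cfg, horizon, instantaneous = FALSE,
                 reverse = FALSE, pooled = pooled)$mdi_xy
}

#' MDI in both directions with the instantaneous component
#'
#' Computes `MDI(X -> Y)`, `MDI(Y -> X)`, and the windowed instantaneous
#' information exchange
#' `inst = sum_n [ I(X_{n-p..n}; Y_n | Y_win) - I(X_{n-p..n-1}; Y_n | Y_win) ]`
#' (the gain from adding the current source sample).  Their sum plays the
#' role of the mutual information `I(X^N; Y^N)` in the normalization
#' identity: without instantaneous coupling,
#' `DI(X -> Y) + DI(Y -> X) = I(X^N; Y^N)`, and the normalized measure
#' `rho = MDI_xy / (MDI_xy + MDI_yx + inst)` (each term clipped at zero)
#' reduces to the two-term ratio.  A common source drives `inst` up and both
#' `rho` values toward zero, which is what makes the normalized statistic
#' specific against volume conduction.
#'
#' @inheritParams mdi
#' @param instantaneous,reverse logical; skip parts of the computation when
#'   `FALSE` (then the corresponding fields are `NA`).
#' @param pooled logical; if `TRUE`, the lagged windows from all time steps
#'   are stacked into one large sample before estimation (valid for
#'   stationary data), so each information quantity is estimated once from
#'   `n_trials * (N - p)` points and scaled by `N - p`.  This multiplies the
#'   effective sample size of the nonparametric estimators at the cost of
#'   assuming the terms are time-invariant.  The default (`FALSE`) estimates
#'   every time step separately across trials.
#' @return List with `mdi_xy`, `mdi_yx`, `inst`, `mi` (their clipped sum),
#'   `rho_xy`, `rho_yx`.
#' @export
mdi_components <- function(x, y, cfg, horizon = n_time(x),
                           instantaneous = TRUE, reverse = TRUE,
                           pooled = FALSE) {
  check_aligned(x, y)
  est <- cfg$estimator
  p <- cfg$p
  N <- horizon
  stopifnot(N <= n_time(x))
  if (N <= p) stop("need more than p = ", p, " time samples")
  if (n_trials(x) < (2 * p + 1) * est$ap_min_cell &&
      est$method == "adaptive_partition")
    warning("few trials for joint window dimension ", 2 * p + 1,
            "; MDI estimates will be coarse")

  steps <- (p + 1):N
  # degenerate determinism: if the target sample is an exact (linear)
  # function of the conditioning variables -- e.g. y is a copy or mixture of
  # x -- the conditional density collapses and every CMI term is 0 by
  # convention.  Checked once on the first step.
  det_given <- function(target, design) {
    ft <- stats::lm.fit(cbind(1, design), target)
    mean(ft$residuals^2) < 1e-12 * (stats::var(target) + 1e-300)
  }
  n0 <- steps[1]
  fwd_det <- det_given(y$data[, n0],
                       cbind(lag_window(x, n0, p, 0), lag_window(y, n0, p, 1)))
  rev_det <- det_given(x$data[, n0],
                       cbind(lag_window(y, n0, p, 0), lag_window(x, n0, p, 1)))
  if (fwd_det && rev_det) {
    # mutual determinism: the two series are copies (or an invertible static
    # mixture) of each other; no directional asymmetry exists
    z <- list(mdi_xy = 0, mdi_yx = if (reverse) 0 else NA_real_,
              inst = if (instantaneous) 0 else NA_real_)
    mi <- if (instantaneous && reverse) 0 else NA_real_
    return(c(z, list(mi = mi, rho_xy = if (is.na(mi)) NA_real_ else 0.5,
                     rho_yx = if (is.na(mi)) NA_real_ else 0.5)))
  }
  if (est$method == "gaussian") {
    sums <- mdi_steps_gaussian(x, y, p, steps, est$log_base, pooled,
                               instantaneous, reverse)
    mdi_xy <- sums[1]; mdi_yx <- sums[2]; inst <- sums[3]
  } else if (pooled) {
    stack <- function(ens, from, to)
      do.call(rbind, lapply(steps, function(n) lag_window(ens, n, from, to)))
    xw <- stack(x, p, 1); yw <- stack(y, p, 1); yn <- stack(y, 0, 0)
    a_xy <- estimate_mi(xw, cbind(yn, yw), est)
    b_xy <- estimate_mi(xw, yw, est)
    mdi_xy <- length(steps) * (a_xy - b_xy)
    mdi_yx <- inst <- 0
    if (reverse) {
      xn <- stack(x, 0, 0)
      mdi_yx <- length(steps) *
        (estimate_mi(yw, cbind(xn, xw), est) - estimate_mi(yw, xw, est))
    }
    if (instantaneous) {
      xw0 <- cbind(stack(x, p, 1), stack(x, 0, 0))
      inst <- length(steps) *
        (estimate_mi(xw0, cbind(yn, yw), est) -
           estimate_mi(xw0, yw, est)) - mdi_xy
    }
  } else {
    mdi_xy <- mdi_yx <- inst <- 0
    for (n in steps) {
      xw <- lag_window(x, n, p, 1)    # X_{n-p..n-1}
      yw <- lag_window(y, n, p, 1)
      yn <- lag_window(y, n, 0, 0)
      a_xy <- estimate_mi(xw, cbind(yn, yw), est)
      b_xy <- estimate_mi(xw, yw, est)
      mdi_xy <- mdi_xy + (a_xy - b_xy)
      if (reverse) {
        xn <- lag_window(x, n, 0, 0)
        mdi_yx <- mdi_yx + estimate_mi(yw, cbind(xn, xw), est) -
          estimate_mi(yw, xw, est)
      }
      if (instantaneous) {
        xw0 <- lag_window(x, n, p, 0)  # X_{n-p..n}
        inst <- inst + estimate_mi(xw0, cbind(yn, yw), est) -
          estimate_mi(xw0, yw, est) - (a_xy - b_xy)
      }
    }
  }
  if (!reverse) mdi_yx <- NA_real_
  if (!instantaneous) inst <- NA_real_
  cl <- function(v) max(v, 0)
  mi <- if (instantaneous && reverse)
    cl(mdi_xy) + cl(mdi_yx) + cl(inst) else NA_real_
  rho <- if (instantaneous && reverse) {
    if (mi < 1e-12) c(0.5, 0.5) else c(cl(mdi_xy) / mi, cl(mdi_yx) / mi)
  } else c(NA_real_, NA_real_)
  list(mdi_xy = mdi_xy, mdi_yx = mdi_yx, inst = inst, mi = mi,
       rho_xy = rho[1], rho_yx = rho[2])
}

#' Delayed and instantaneous decomposition of DI
#'
#' Splits directed information into the part carried by strictly past source
#' samples and the zero-lag (instantaneous) exchange:
#' `DI(X -> Y) = DI(DX -> Y) + inst`, where `DX` is the one-sample-delayed
#' source.  For a physical system whose coupling acts with a delay of at
#' least one sample the instantaneous part is zero, and
#' `DI(DX -> Y) + DI(DY -> X) + inst = I(X^N; Y^N)`.
#'
#' @inheritParams directed_information
#' @return List with `di_delayed_xy` and `instantaneous`.
#' @export
delayed_and_instantaneous <- function(x, y, cfg, horizon = n_time(x)) {
  di_full <- di_general(x, y, cfg, horizon, delay = 0L)
  di_del <- di_general(x, y, cfg, horizon, delay = 1L)
  list(di_delayed_xy = di_del, instantaneous = di_full - di_del)
}

#' Normalized directed information
#'
#' Maps a pair of DI values to the `[0, 1]` range:
#' `rho_xy = DI(X->Y) / (DI(X->Y) + DI(Y->X))` after clipping each DI at
#' zero.  Without instantaneous coupling the denominator equals
#' `I(X^N; Y^N)` and a unidirectional system gives `(1, 0)`.  When both
#' clipped values are (numerically) zero the ratio is undefined and
#' `(0.5, 0.5)` is returned with the `undefined` flag set.
#'
#' @param di_xy,di_yx directed information values (may be negative; clipped).
#' @return List with `rho_xy`, `rho_yx`, and logical `undefined`.
#' @examples
#' normalized_di(0.3, 0.1)   # 0.75 / 0.25
#' normalized_di(-0.02, 0.05)  # clipped to (0, 1)
#' @export
normalized_di <- function(di_xy, di_yx) {
  a <- max(di_xy, 0)
  b <- max(di_yx, 0)
  if (a + b < 1e-12)
    return(list(rho_xy = 0.5, rho_yx = 0.5, undefined = TRUE))
  list(rho_xy = a / (a + b), rho_yx = b / (a + b), undefined = FALSE)
}

# fast covariance path for the gaussian estimator: all MDI-related MI terms
# at one time step are log-determinant ratios of submatrices of a single
# (2p+2)-column covariance [X_{n-p..n-1}, X_n, Y_n, Y_{n-p..n-1}]
mdi_steps_gaussian <- function(x, y, p, steps, log_base, pooled,
                               instantaneous, reverse) {
  ixw <- 1:p; ixn <- p + 1L; iyn <- p + 2L; iyw <- (p + 3L):(2L * p + 2L)
  ld <- function(S, idx) {
    ch <- tryCatch(chol(S[idx, idx, drop = FALSE]), error = function(e)
      stop("singular sample covariance in the MDI window (totally ",
           "dependent coordinates)", call. = FALSE))
    2 * sum(log(diag(ch)))
  }
  block <- function(n)
    cbind(lag_window(x, n, p, 1), lag_window(x, n, 0, 0),
          lag_window(y, n, 0, 0), lag_window(y, n, p, 1))
  covs <- if (pooled)
    list(stats::cov(do.call(rbind, lapply(steps, block))))
  else lapply(steps, function(n) stats::cov(block(n)))

  mdi_xy <- mdi_yx <- inst <- 0
  for (S in covs) {
    l_xw <- ld(S, ixw); l_yw <- ld(S, iyw)
    l_ynw <- ld(S, c(iyn, iyw))
    l_xw_yw <- ld(S, c(ixw, iyw))
    l_xw_ynw <- ld(S, c(ixw, iyn, iyw))
    fwd <- 0.5 * (l_ynw + l_xw_yw - l_yw - l_xw_ynw)  # I(Xw;Yn|Yw), nats
    mdi_xy <- mdi_xy + fwd
    if (reverse) {
      l_xw0 <- ld(S, c(ixw, ixn))
      l_xw0_yw <- ld(S, c(ixw, ixn, iyw))
      mdi_yx <- mdi_yx + 0.5 * (l_xw0 + l_xw_yw - l_xw - l_xw0_yw)
    }
    if (instantaneous) {
      if (!reverse) {
        l_xw0 <- ld(S, c(ixw, ixn))
        l_xw0_yw <- ld(S, c(ixw, ixn, iyw))
      }
      l_full <- ld(S, c(ixw, ixn, iyn, iyw))
      inst <- inst +
        0.5 * (l_ynw + l_xw0_yw - l_yw - l_full) - fwd
    }
  }
  mult <- if (pooled) length(steps) else 1
  c(mdi_xy, if (reverse) mdi_yx else NA_real_,
    if (instantaneous) inst else NA_real_) * mult / log(log_base)
}

# --- closed-form Gaussian path ---------------------------------------------

logdet_sub <- function(Sig, idx) {
  if (!length(idx)) return(0)
  2 * sum(log(diag(chol(Sig[idx, idx, drop = FALSE]))))
}

mi_from_cov <- function(Sig, ix, iy, log_base = 2)
  (0.5 * (logdet_sub(Sig, ix) + logdet_sub(Sig, iy) -
            logdet_sub(Sig, c(ix, iy)))) / log(log_base)

#' Exact Gaussian directed information from a joint covariance
#'
#' Evaluates `DI(X -> Y)`, `DI(Y -> X)` and `I(X^N; Y^N)` in closed form
#' from the exact covariance of the stacked Gaussian vector
#' `(X_1..X_N, Y_1..Y_N)` (e.g. from [linear_ar_cov()]), using Gaussian
#' entropies of the relevant submatrices.  Deterministic; serves as the
#' oracle for the sample-based estimators.
#'
#' @param Sigma `2N x 2N` covariance, X indices first.
#' @param N number of time samples per process.
#' @param log_base logarithm base (2 = bits).
#' @return List with `di_xy`, `di_yx`, `mi`, and normalized `rho_xy`,
#'   `rho_yx`.
#' @export
di_gaussian_exact <- function(Sigma, N, log_base = 2) {
  stopifnot(nrow(Sigma) == 2 * N)
  di_dir <- function(xoff, yoff) {
    total <- 0
    for (n in seq_len(N)) {
      a <- mi_from_cov(Sigma, xoff + 1:n, yoff + 1:n, log_base)
      b <- if (n > 1) mi_from_cov(Sigma, xoff + 1:n, yoff + 1:(n - 1),
                                  log_base) else 0
      total <- total + (a - b)
    }
    total
  }
  di_xy <- di_dir(0, N)
  di_yx <- di_dir(N, 0)
  mi <- mi_from_cov(Sigma, 1:N, N + 1:N, log_base)
  rho <- normalized_di(di_xy, di_yx)
  list(di_xy = di_xy, di_yx = di_yx, mi = mi,
       rho_xy = rho$rho_xy, rho_yx = rho$rho_yx)
}
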