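#' @useDynLib neurodi, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# --- stability helpers ------------------------------------------------------

ar_companion <- function(coef) {
  p <- length(coef)
  m <- matrix(0, p, p)
  m[1, ] <- coef
  if (p > 1) m[cbind(2:p, 1:(p - 1))] <- 1
  m
}

ar_spectral_radius <- function(coef)
  max(Mod(eigen(ar_companion(coef), only.values = TRUE)$values))

#' Draw stable AR coefficients
#'
#' Repeatedly draws a coefficient vector from independent standard normals
#' until the AR companion matrix has spectral radius below 1, mirroring the
#' benchmark convention of discarding unstable systems.
#'
#' @param order AR order (length of the coefficient vector).
#' @param max_draws maximum rejection-sampling attempts before erroring.
#' @return Numeric coefficient vector of length `order` defining a stable
#'   AR process.
#' @examples
#' set.seed(1); a <- draw_stable_ar_coefficients(5)
#' @export
draw_stable_ar_coefficients <- function(order, max_draws = 1e4) {
  stopifnot(order >= 1)
  for (i in seq_len(max_draws)) {
    coef <- stats::rnorm(order)
    if (ar_spectral_radius(coef) < 1) return(coef)
  }
  stop("no stable coefficient vector found in ", max_draws, " draws")
}

# --- benchmark system specifications ---------------------------------------

#' Benchmark system specifications
#'
#' Parameter records for the five benchmark generators.  `linear_ar_spec`
#' describes the coupled pair
#' \deqn{X(n) = \sum_{i=1}^{p_4} \alpha_i X(n-i) + \sigma_x \eta_x(n)}
#' \deqn{Y(n) = \sum_{i=1}^{p_3} \beta_i Y(n-i) +
#'       \gamma \sum_{i=p_1}^{p_2} X(n-i) + \sigma_y \eta_y(n)}
#' so `gamma` controls the coupling strength and `p1` the transmission delay.
#' `nonlinear_ar_spec` replaces the coupling term by a sigmoid
#' `1 / (1 + exp(b1 + b2 X(n-i)))`.  `single_source_spec` describes a common
#' AR source observed on two sensors, one of which is corrupted by noise with
#' weight `epsilon`.  `lorenz_spec` parameterizes two Lorenz oscillators with
#' a delayed drive `beta * X1(t - t_p)` entering the second system's X
#' equation.
#'
#' @param alpha,beta own-lag AR coefficient vectors for X and Y.
#' @param gamma coupling strength (>= 0).
#' @param sigma_x,sigma_y innovation scales.
#' @param p1 transmission delay in samples (default 1).
#' @param p2 largest X lag entering Y (default `length(alpha)`).
#' @param b1,b2 sigmoid threshold and slope (nonlinear model).
#' @param epsilon mixing/noise weight (see the individual generators).
#' @param A,R,B,beta_coupling,t_p,dt,n_total,n_discard Lorenz constants,
#'   coupling strength, drive delay in seconds, Euler step, total and
#'   discarded sample counts.
#' @return A spec object of the corresponding class.
#' @name system_specs
NULL

#' @rdname system_specs
#' @export
linear_ar_spec <- function(alpha, beta, gamma, sigma_x = 1, sigma_y = 1,
                           p1 = 1, p2 = length(alpha)) {
  stopifnot(p1 >= 1, p2 >= p1, gamma >= 0)
  if (ar_spectral_radius(alpha) >= 1 || ar_spectral_radius(beta) >= 1)
    stop("unstable marginal AR part (spectral radius >= 1)")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 p1 = as.integer(p1), p2 = as.integer(p2),
                 p3 = length(beta), p4 = length(alpha)),
            class = "linear_ar_spec")
}

#' @rdname system_specs
#' @export
nonlinear_ar_spec <- function(alpha, beta, gamma, sigma_x = 1, sigma_y = 1,
                              p1 = 1, p2 = length(alpha), b1 = 0, b2 = 50) {
  out <- linear_ar_spec(alpha, beta, gamma, sigma_x, sigma_y, p1, p2)
  out$b1 <- b1
  out$b2 <- b2
  class(out) <- c("nonlinear_ar_spec", "linear_ar_spec")
  out
}

#' @rdname system_specs
#' @export
single_source_spec <- function(alpha, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (ar_spectral_radius(alpha) >= 1) stop("unstable source AR part")
  structure(list(alpha = alpha, epsilon = epsilon, p4 = length(alpha)),
            class = "single_source_spec")
}

#' @rdname system_specs
#' @export
lorenz_spec <- function(A = 10, R = 28, B = 8 / 3, beta_coupling = 0.5,
                        t_p = 0.02, dt = 0.01, n_total = 100, n_discard = 90) {
  lag <- t_p / dt
  if (abs(lag - round(lag)) > 1e-9 || lag < 1)
    stop("t_p must be a positive integer multiple of dt")
  stopifnot(n_discard < n_total, beta_coupling >= 0)
  structure(list(A = A, R = R, B = B, beta_coupling = beta_coupling,
                 t_p = t_p, dt = dt, n_total = as.integer(n_total),
                 n_discard = as.integer(n_discard),
                 lag_samples = as.integer(round(lag))),
            class = "lorenz_spec")
}

#' Random stable benchmark specs
#'
#' Draws all AR coefficients (and innovation scales) from standard normals,
#' discarding unstable systems, as the benchmarks prescribe.
#'
#' @param order shared order `p2 = p3 = p4`.
#' @param gamma coupling strength.
#' @param p1 transmission delay.
#' @param b1,b2 sigmoid parameters (nonlinear variant).
#' @param epsilon noise weight (single-source variant).
#' @return A spec object with randomly drawn stable coefficients.
#' @export
random_linear_ar_spec <- function(order = 5, gamma = 0.8, p1 = 1) {
  linear_ar_spec(alpha = draw_stable_ar_coefficients(order),
                 beta = draw_stable_ar_coefficients(order),
                 gamma = gamma,
                 sigma_x = stats::rnorm(1), sigma_y = stats::rnorm(1),
                 p1 = p1, p2 = order)
}

#' @rdname random_linear_ar_spec
#' @export
random_nonlinear_ar_spec <- function(order = 5, gamma = 0.8, p1 = 1,
                                     b1 = 0, b2 = 50) {
  s <- random_linear_ar_spec(order, gamma, p1)
  nonlinear_ar_spec(s$alpha, s$beta, s$gamma, s$sigma_x, s$sigma_y,
                    s$p1, s$p2, b1, b2)
}

#' @rdname random_linear_ar_spec
#' @export
random_single_source_spec <- function(order = 5, epsilon = 0.5)
  single_source_spec(draw_stable_ar_coefficients(order), epsilon)

# --- generators -------------------------------------------------------------

#' Simulate coupled autoregressive trial ensembles
#'
#' Generates `n_trials` independent realizations of the coupled AR pair
#' described by `spec` (linear or sigmoid-coupled nonlinear).  Initial values
#' and innovations are standard normal; a burn-in of `burn_in` samples is
#' discarded so the retained window is effectively stationary.
#'
#' @param spec a [linear_ar_spec()] or [nonlinear_ar_spec()].
#' @param n_trials number of realizations.
#' @param n_time retained samples per trial.
#' @param seed optional RNG seed for reproducibility.
#' @param burn_in discarded initial samples (default 100).
#' @return List with `trial_ensemble`s `x` and `y`.
#' @examples
#' spec <- linear_ar_spec(alpha = c(0.5), beta = c(0.4), gamma = 0.8, p2 = 1)
#' sim <- simulate_linear_ar(spec, n_trials = 64, n_time = 30, seed = 1)
#' @export
simulate_linear_ar <- function(spec, n_trials, n_time, seed = NULL,
                               burn_in = 100) {
  if (!is.null(seed)) set.seed(seed)
  p_init <- max(spec$p2, spec$p3, spec$p4)
  stopifnot(n_time > p_init)
  total <- burn_in + n_time
  x <- matrix(0, n_trials, total)
  y <- matrix(0, n_trials, total)
  x[, seq_len(p_init)] <- stats::rnorm(n_trials * p_init)
  y[, seq_len(p_init)] <- stats::rnorm(n_trials * p_init)
  nonlin <- inherits(spec, "nonlinear_ar_spec")
  couple_lags <- spec$p1:spec$p2
  for (n in (p_init + 1):total) {
    xl <- x[, n - seq_len(spec$p4), drop = FALSE]
    x[, n] <- xl %*% spec$alpha + spec$sigma_x * stats::rnorm(n_trials)
    xc <- x[, n - couple_lags, drop = FALSE]
    drive <- if (nonlin)
      rowSums(1 / (1 + exp(spec$b1 + spec$b2 * xc)))
    else rowSums(xc)
    yl <- y[, n - seq_len(spec$p3), drop = FALSE]
    y[, n] <- yl %*% spec$beta + spec$gamma * drive +
      spec$sigma_y * stats::rnorm(n_trials)
  }
  keep <- (burn_in + 1):total
  list(x = trial_ensemble(x[, keep, drop = FALSE], label = "X"),
       y = trial_ensemble(y[, keep, drop = FALSE], label = "Y"))
}

#' @rdname simulate_linear_ar
#' @export
simulate_nonlinear_ar <- function(spec, n_trials, n_time, seed = NULL,
                                  burn_in = 100) {
  if (!inherits(spec, "nonlinear_ar_spec"))
    stop("spec must be a nonlinear_ar_spec")
  simulate_linear_ar(spec, n_trials, n_time, seed, burn_in)
}

#' Linear instantaneous mixing of two ensembles
#'
#' Returns the sensor-space mixtures
#' `X_eps = (1 - eps) X + eps Y` and `Y_eps = eps X + (1 - eps) Y`,
#' emulating volume conduction between two coupled sources.  At
#' `epsilon = 0.5` the two mixtures are identical.
#'
#' @param x,y aligned `trial_ensemble`s.
#' @param epsilon mixing coefficient in `[0, 0.5]`.
#' @return List with mixed ensembles `x` and `y`.
#' @export
apply_mixing <- function(x, y, epsilon) {
  check_aligned(x, y)
  stopifnot(epsilon >= 0, epsilon <= 0.5)
  xe <- (1 - epsilon) * x$data + epsilon * y$data
  ye <- epsilon * x$data + (1 - epsilon) * y$data
  list(x = trial_ensemble(xe, x$sampling_rate_hz, paste0(x$label, "_eps")),
       y = trial_ensemble(ye, y$sampling_rate_hz, paste0(y$label, "_eps")))
}

#' Simulate the common-source (volume conduction) model
#'
#' A single AR source `S` is observed directly on sensor X and, corrupted by
#' independent Gaussian noise with weight `epsilon`, on sensor Y:
#' `X(n) = S(n)`, `Y(n) = (1 - eps) S(n) + eps eta(n)`.  There is no lagged
#' causality between the sensors by construction; any detected directed flow
#' is a false positive.
#'
#' @param spec a [single_source_spec()].
#' @inheritParams simulate_linear_ar
#' @return List with `trial_ensemble`s `x` and `y`.
#' @export
simulate_single_source <- function(spec, n_trials, n_time, seed = NULL,
                                   burn_in = 100) {
  if (!is.null(seed)) set.seed(seed)
  p <- spec$p4
  stopifnot(n_time > p)
  total <- burn_in + n_time
  s <- matrix(0, n_trials, total)
  s[, seq_len(p)] <- stats::rnorm(n_trials * p)
  for (n in (p + 1):total)
    s[, n] <- s[, n - seq_len(p), drop = FALSE] %*% spec$alpha +
      stats::rnorm(n_trials)
  keep <- (burn_in + 1):total
  s <- s[, keep, drop = FALSE]
  ye <- (1 - spec$epsilon) * s +
    spec$epsilon * matrix(stats::rnorm(length(s)), nrow(s), ncol(s))
  list(x = trial_ensemble(s, label = "X_eps"),
       y = trial_ensemble(ye, label = "Y_eps"))
}

#' Simulate delay-coupled Lorenz oscillators
#'
#' Forward-Euler integration of two Lorenz systems in which
#' `beta_coupling * X1(t - t_p)` drives the second oscillator's X equation,
#' giving unidirectional ground truth X1 -> X2 for positive coupling.
#' Initial conditions are standard normal per trial; the drive's pre-history
#' buffer is held at the initial X1 value.  Trials whose state magnitude
#' exceeds `1e6` (Euler blow-up) are regenerated with fresh initial
#' conditions and counted in the `regenerated` attribute.
#'
#' @param spec a [lorenz_spec()].
#' @param n_trials number of trials.
#' @param seed optional RNG seed.
#' @return Named list of six `trial_ensemble`s (`x1`, `y1`, `z1`, `x2`,
#'   `y2`, `z2`), each `n_trials x (n_total - n_discard)`.
#' @export
simulate_lorenz_pair <- function(spec, n_trials, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lag <- spec$lag_samples
  total <- spec$n_total
  keep <- (spec$n_discard + 1):total
  fs <- 1 / spec$dt

  integrate_trials <- function(m) {
    st <- matrix(stats::rnorm(m * 6), m, 6)  # X1 Y1 Z1 X2 Y2 Z2
    hist_x1 <- matrix(st[, 1], m, lag)       # ring buffer of past X1
    out <- array(0, c(m, total, 6))
    for (n in seq_len(total)) {
      x1 <- st[, 1]; y1 <- st[, 2]; z1 <- st[, 3]
      x2 <- st[, 4]; y2 <- st[, 5]; z2 <- st[, 6]
      x1d <- hist_x1[, 1]
      d <- cbind(-spec$A * (x1 - y1),
                 spec$R * x1 - y1 - x1 * z1,
                 x1 * y1 - spec$B * z1,
                 -spec$A * (x2 - y2) + spec$beta_coupling * x1d,
                 spec$R * x2 - y2 - x2 * z2,
                 x2 * y2 - spec$B * z2)
      if (lag > 1) hist_x1[, seq_len(lag - 1)] <- hist_x1[, 2:lag]
      hist_x1[, lag] <- x1
      st <- st + spec$dt * d
      out[, n, ] <- st
    }
    out
  }

  out <- integrate_trials(n_trials)
  regenerated <- 0L
  repeat {
    bad <- which(apply(abs(out), 1, max) > 1e6)
    if (!length(bad)) break
    regenerated <- regenerated + length(bad)
    if (regenerated > 100L * n_trials) stop("Euler integration keeps diverging")
    out[bad, , ] <- integrate_trials(length(bad))
  }

  comp <- c("x1", "y1", "z1", "x2", "y2", "z2")
  res <- lapply(seq_along(comp), function(k)
    trial_ensemble(out[, keep, k, drop = FALSE][, , 1], fs, comp[k]))
  names(res) <- comp
  attr(res, "regenerated") <- regenerated
  res
}

# --- exact second-order structure of the linear benchmark -------------------

#' Exact joint covariance of the linear AR benchmark
#'
#' Solves the discrete Lyapunov equation for the stationary covariance of the
#' joint VAR form of a [linear_ar_spec()] and assembles the exact covariance
#' matrix of the stacked vector `(X_1, ..., X_N, Y_1, ..., Y_N)`.  This is
#' the closed-form oracle against which the sample-based estimators are
#' checked, and the input for exact Gaussian directed-information values.
#'
#' @param spec a [linear_ar_spec()] (the linear model only).
#' @param N number of time samples.
#' @param stationary if `TRUE` (default) the process is started from its
#'   stationary distribution; if `FALSE` the covariance is propagated exactly
#'   from the simulator's initial condition (independent standard-normal
#'   values for the first `max(p2, p3, p4)` samples, no burn-in), matching
#'   `simulate_linear_ar(..., burn_in = 0)` sample for sample.
#' @return `2N x 2N` covariance matrix; X indices first, then Y.
#' @export
linear_ar_cov <- function(spec, N, stationary = TRUE) {
  p <- max(spec$p2, spec$p3, spec$p4)
  if (!stationary) return(linear_ar_cov_init(spec, N, p))
  # lag-i 2x2 coefficient blocks of the joint VAR
  A <- lapply(seq_len(p), function(i) {
    m <- matrix(0, 2, 2)
    if (i <= spec$p4) m[1, 1] <- spec$alpha[i]
    if (i <= spec$p3) m[2, 2] <- spec$beta[i]
    if (i >= spec$p1 && i <= spec$p2) m[2, 1] <- spec$gamma
    m
  })
  d <- 2 * p
  C <- matrix(0, d, d)
  for (i in seq_len(p)) C[1:2, (2 * i - 1):(2 * i)] <- A[[i]]
  if (p > 1) C[3:d, 1:(d - 2)] <- diag(d - 2)
  Q <- matrix(0, d, d)
  Q[1, 1] <- spec$sigma_x^2
  Q[2, 2] <- spec$sigma_y^2
  S <- matrix(solve(diag(d^2) - kronecker(C, C), as.vector(Q)), d, d)
  S <- (S + t(S)) / 2

  # Gamma(k) = Cov(z_{n+k}, z_n), z = (X, Y)
  Gam <- vector("list", N)
  for (k in 0:(p - 1)) {
    if (k + 1 > N) break
    Gam[[k + 1]] <- S[1:2, (2 * k + 1):(2 * k + 2)]
  }
  if (N > p) for (k in p:(N - 1)) {
    g <- matrix(0, 2, 2)
    for (i in seq_len(p)) g <- g + A[[i]] %*% Gam[[k - i + 1]]
    Gam[[k + 1]] <- g
  }
  gam <- function(k) if (k >= 0) Gam[[k + 1]] else t(Gam[[-k + 1]])

  Sig <- matrix(0, 2 * N, 2 * N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    g <- gam(i - j)
    Sig[i, j] <- g[1, 1]                 # Cov(X_i, X_j)
    Sig[N + i, N + j] <- g[2, 2]         # Cov(Y_i, Y_j)
    Sig[i, N + j] <- g[1, 2]             # Cov(X_i, Y_j)
    Sig[N + i, j] <- g[2, 1]             # Cov(Y_i, X_j)
  }
  (Sig + t(Sig)) / 2
}

# exact covariance with independent-normal initial samples: every sample is a
# linear map of 2N iid unit-variance innovations; Sigma = L L'
linear_ar_cov_init <- function(spec, N, p) {
  L <- matrix(0, 2 * N, 2 * N)   # rows: X_1..X_N, Y_1..Y_N; cols: innovations
  xi <- function(n) n            # innovation column driving X_n
  yi <- function(n) N + n
  for (n in seq_len(N)) {
    if (n <= p) {
      L[n, xi(n)] <- 1
      L[N + n, yi(n)] <- 1
      next
    }
    for (i in seq_len(spec$p4)) L[n, ] <- L[n, ] + spec$alpha[i] * L[n - i, ]
    L[n, xi(n)] <- L[n, xi(n)] + spec$sigma_x
    for (i in seq_len(spec$p3))
      L[N + n, ] <- L[N + n, ] + spec$beta[i] * L[N + n - i, ]
    for (i in spec$p1:spec$p2)
      L[N + n, ] <- L[N + n, ] + spec$gamma * L[n - i, ]
    L[N + n, yi(n)] <- L[N + n, yi(n)] + spec$sigma_y
  }
  tcrossprod(L)
}
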