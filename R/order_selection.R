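#' Cao-criterion configuration
#'
#' @param max_dim search ceiling for the embedding dimension.
#' @param tau embedding delay in samples; 1 is the usual choice for
#'   discrete-time signals.
#' @param e1_tol saturation tolerance on successive differences of the
#'   `E1(d)` curve.
#' @param plateau_tol how close all later `E1` values must stay to the
#'   candidate plateau value.
#' @param min_points minimum number of pooled delay vectors required.
#' @param max_points cap on pooled delay vectors; beyond it an evenly spaced
#'   (deterministic) subsample is used for the nearest-neighbour search.
#' @return An object of class `cao_config`.
#' @export
cao_config <- function(max_dim = 10, tau = 1, e1_tol = 0.05,
                       plateau_tol = 0.1, min_points = 100,
                       max_points = 2000) {
  stopifnot(max_dim >= 2, tau >= 1, e1_tol > 0, min_points >= 10,
            max_points >= min_points)
  structure(list(max_dim = as.integer(max_dim), tau = as.integer(tau),
                 e1_tol = e1_tol, plateau_tol = plateau_tol,
                 min_points = as.integer(min_points),
                 max_points = as.integer(max_points)),
            class = "cao_config")
}

# delay vectors of dimension d (most recent first), pooled across trials
delay_vectors <- function(ens, d, tau) {
  nt <- n_time(ens)
  span <- (d - 1) * tau
  if (nt <= span) stop("series too short for delay vectors of dimension ", d)
  starts <- (span + 1):nt
  out <- matrix(0, n_trials(ens) * length(starts), d)
  for (k in seq_len(d))
    out[, k] <- as.vector(ens$data[, starts - (k - 1) * tau])
  out
}

#' Embedding dimension by the Cao false-nearest-neighbour criterion
#'
#' Builds delay vectors `(X_n, X_{n-tau}, ..., X_{n-(d-1)tau})` per trial,
#' pools them, and computes Cao's `E1(d) = E(d+1)/E(d)` from the expansion
#' of nearest-neighbour distances when one more coordinate is appended
#' (maximum norm, self-matches and zero distances excluded).  The returned
#' dimension is the smallest `d` at which the `E1` curve has saturated:
#' `|E1(d+1) - E1(d)| < e1_tol` and every later `E1` value stays within
#' `plateau_tol` of `E1(d)`.  If no saturation occurs up to `max_dim`, that
#' ceiling is returned with attribute `no_saturation = TRUE`.  Cao's noise
#' diagnostic `E2(d) = E*(d+1)/E*(d)` is attached as attribute `e2` (values
#' near 1 for every `d` indicate a purely stochastic series) but does not
#' alter the estimate.
#'
#' The estimated dimension serves as the model order `p` for [mdi()].
#'
#' @param series a `trial_ensemble`.
#' @param cfg a [cao_config()].
#' @return Integer embedding dimension with attributes `e1` (numeric curve),
#'   `e2`, and `no_saturation`.
#' @export
cao_dimension <- function(series, cfg = cao_config()) {
  stopifnot(inherits(series, "trial_ensemble"))
  vecs <- delay_vectors(series, cfg$max_dim + 1L, cfg$tau)
  if (nrow(vecs) < cfg$min_points)
    stop("only ", nrow(vecs), " delay vectors; need at least ",
         cfg$min_points)
  if (nrow(vecs) > cfg$max_points) {
    idx <- unique(round(seq(1, nrow(vecs), length.out = cfg$max_points)))
    vecs <- vecs[idx, , drop = FALSE]
  }
  ee <- cpp_cao_e(vecs)                  # rows: E(d), E*(d), d = 1..max_dim
  e1 <- ee[1, 2:cfg$max_dim] / ee[1, 1:(cfg$max_dim - 1)]
  e2 <- ee[2, 2:cfg$max_dim] / ee[2, 1:(cfg$max_dim - 1)]
  names(e1) <- names(e2) <- seq_len(cfg$max_dim - 1)

  d_hat <- NA_integer_
  for (d in seq_len(length(e1) - 1)) {
    later <- e1[(d + 1):length(e1)]
    if (abs(e1[d + 1] - e1[d]) < cfg$e1_tol &&
        all(abs(later - e1[d]) <= cfg$plateau_tol)) {
      d_hat <- d
      break
    }
  }
  no_sat <- is.na(d_hat)
  if (no_sat) d_hat <- cfg$max_dim
  structure(as.integer(d_hat), e1 = e1, e2 = e2, no_saturation = no_sat)
}

#' Shared model order for a channel pair
#'
#' Applies [cao_dimension()] to both channels and returns the larger
#' estimate, mirroring `p = max(p2, p3)` for a coupled pair.
#'
#' @param x,y `trial_ensemble`s.
#' @param cfg a [cao_config()].
#' @return Integer order `p` (attribute `no_saturation` is `TRUE` if either
#'   channel failed to saturate).
#' @export
select_order <- function(x, y, cfg = cao_config()) {
  dx <- cao_dimension(x, cfg)
  dy <- cao_dimension(y, cfg)
  structure(max(as.integer(dx), as.integer(dy)),
            no_saturation = attr(dx, "no_saturation") ||
              attr(dy, "no_saturation"))
}
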