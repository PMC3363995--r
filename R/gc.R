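#' Fit full and reduced autoregressive models for Granger causality
#'
#' Ordinary least-squares fits of `y[n]` on its own `p` lags (reduced model)
#' and on its own plus the source's `p` lags (full model).  Residual
#' variances are mean squared residuals; adding regressors can only decrease
#' the least-squares residual variance.
#'
#' @param x,y numeric vectors (single realizations) of equal length.
#' @param order model order `p`.
#' @return Object of class `mvar_fit`: `order`, `coeff_full`,
#'   `coeff_reduced`, `resid_var_full`, `resid_var_reduced`, `n_used`.
#' @export
fit_mvar <- function(x, y, order) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(y)
  stopifnot(length(x) == n, order >= 1)
  if (n <= 10 * order)
    stop("series too short for order ", order, " (need > ", 10 * order, ")")
  idx <- (order + 1):n
  ylag <- sapply(seq_len(order), function(k) y[idx - k])
  xlag <- sapply(seq_len(order), function(k) x[idx - k])
  yr <- y[idx]

  ols <- function(design, which_block) {
    qrd <- qr(cbind(1, design))
    if (qrd$rank < ncol(design) + 1)
      stop("rank-deficient ", which_block,
           " design (constant or collinear lag block)")
    cf <- qr.coef(qrd, yr)
    res <- yr - cbind(1, design) %*% cf
    list(coef = cf[-1], rv = mean(res^2))
  }
  red <- ols(ylag, "own-lag")
  full <- ols(cbind(ylag, xlag), "cross-lag")
  structure(list(order = as.integer(order),
                 coeff_reduced = red$coef, coeff_full = full$coef,
                 resid_var_reduced = red$rv, resid_var_full = full$rv,
                 n_used = length(idx)),
            class = "mvar_fit")
}

#' Granger causality as the Geweke index
#'
#' `F(X -> Y) = (1/2) log( var_reduced / var_full )`, the log ratio of the
#' prediction-residual variances of the reduced and full models, floored at
#' zero.  For jointly Gaussian processes this equals the directed-information
#' rate of the one-sample-delayed source, which is the basis of the
#' cross-check against [directed_information()].
#'
#' @inheritParams fit_mvar
#' @param log_base logarithm base; 2 (bits) keeps the index on the same
#'   scale as the information measures.
#' @return Nonnegative Geweke index in units of `log_base`.
#' @export
granger_f <- function(x, y, order, log_base = 2) {
  fit <- fit_mvar(x, y, order)
  max(0, 0.5 * log(fit$resid_var_reduced / fit$resid_var_full) /
        log(log_base))
}

#' Normalize a Geweke index to [0, 1)
#'
#' Proportional-variance-reduction map `1 - exp(-2 F)` (with `F` in nats),
#' i.e. the fraction of residual variance removed by the source's lags.
#' Monotone in `F`, zero at `F = 0`, and approaches 1 as `F` grows.
#'
#' @param F nonnegative Geweke index.
#' @param log_base base in which `F` was computed.
#' @return Value in `[0, 1)`.
#' @examples
#' normalize_gc(0.5 * log2(2))  # variance halved -> 0.5
#' @export
normalize_gc <- function(F, log_base = 2) {
  stopifnot(all(F >= 0))
  1 - exp(-2 * F * log(log_base))
}
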