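#' Significance test of directed information flow between two ensembles
#'
#' Computes MDI in both directions plus the instantaneous exchange, forms the
#' normalized statistic `rho = MDI_xy / (MDI_xy + MDI_yx + inst)` (terms
#' clipped at zero; the mutual-information-normalized form of the
#' `[0, 1]`-ranged directed-information ratio), and compares it against a
#' trial-shuffle null at level `alpha`.  Normalization is what gives the test
#' its specificity against common-source (volume-conduction) dependence: a
#' shared zero-lag source inflates the instantaneous denominator term, so
#' both directions' `rho` collapse toward zero even when the raw lagged MDI
#' is positive because of shared dynamics.  Set `statistic = "raw"` to test
#' the unnormalized MDI instead.
#'
#' @param x,y aligned `trial_ensemble`s (direction tested: `x` to `y`).
#' @param cfg a [di_config()]; `cfg$p` is the MDI window (use
#'   [select_order()] for a model-free choice).
#' @param n_shuffles trial permutations for the null (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed optional RNG seed (recorded in the result).
#' @param statistic `"normalized"` (default) or `"raw"`.
#' @param horizon number of time samples to accumulate over.
#' @param pooled passed to [mdi_components()]; pool time windows for
#'   stationary data.
#' @return Object of class `di_result`: raw `di_xy`, `di_yx`, `inst`, `mi`,
#'   normalized `rho_xy`, `rho_yx`, the tested `observed` statistic,
#'   `threshold`, `p_value`, logical `significant`, the `null`, and `config`.
#' @export
mdi_test <- function(x, y, cfg, n_shuffles = 100, alpha = 0.05, seed = NULL,
                     statistic = c("normalized", "raw"),
                     horizon = n_time(x), pooled = FALSE) {
  statistic <- match.arg(statistic)
  normalized <- statistic == "normalized"
  stat_fun <- if (normalized) {
    function(a, b) mdi_components(a, b, cfg, horizon, pooled = pooled)$rho_xy
  } else {
    function(a, b) mdi_components(a, b, cfg, horizon, instantaneous = FALSE,
                                  reverse = FALSE, pooled = pooled)$mdi_xy
  }
  comp <- mdi_components(x, y, cfg, horizon, pooled = pooled)
  observed <- if (normalized) comp$rho_xy else comp$mdi_xy
  null <- trial_shuffle_null(x, y, stat_fun, n_shuffles, alpha, seed)
  structure(list(di_xy = comp$mdi_xy, di_yx = comp$mdi_yx,
                 inst = comp$inst, mi = comp$mi,
                 rho_xy = comp$rho_xy, rho_yx = comp$rho_yx,
                 statistic = statistic, observed = observed,
                 threshold = null$threshold,
                 p_value = empirical_pvalue(observed, null),
                 significant = observed > null$threshold,
                 null = null, config = cfg),
            class = "di_result")
}

#' @export
print.di_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<di_result: MDI_xy = %.4g, MDI_yx = %.4g bits; rho_xy = %.3f; ",
    "%s stat %.4g vs threshold %.4g (p = %.4g)%s>\n"),
    x$di_xy, x$di_yx, x$rho_xy, x$statistic, x$observed, x$threshold,
    x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Significance test of Granger causality on single realizations
#'
#' Computes the Geweke index `F(X -> Y)` at the given order and compares it
#' against a time-shuffle null (the source's samples are permuted, which
#' destroys its temporal structure) at level `alpha`.
#'
#' @param x,y numeric vectors (single realizations).
#' @param order MVAR model order.
#' @param n_shuffles,alpha,seed as in [mdi_test()].
#' @return Object of class `gc_result` with `f`, `f_normalized`,
#'   `threshold`, `p_value`, `significant`, `null`, `order`.
#' @export
gc_test <- function(x, y, order, n_shuffles = 100, alpha = 0.05,
                    seed = NULL) {
  xe <- trial_ensemble(matrix(as.numeric(x), 1))
  ye <- trial_ensemble(matrix(as.numeric(y), 1))
  stat_fun <- function(a, b) granger_f(a$data[1, ], b$data[1, ], order)
  observed <- granger_f(as.numeric(x), as.numeric(y), order)
  null <- time_shuffle_null(xe, ye, stat_fun, n_shuffles, alpha, seed)
  structure(list(f = observed, f_normalized = normalize_gc(observed),
                 threshold = null$threshold,
                 p_value = empirical_pvalue(observed, null),
                 significant = observed > null$threshold,
                 null = null, order = as.integer(order)),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf(
    "<gc_result: F = %.4g bits (normalized %.3f) vs threshold %.4g (p = %.4g)%s>\n",
    x$f, x$f_normalized, x$threshold, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}
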