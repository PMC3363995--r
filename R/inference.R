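#' Trial-shuffle null distribution
#'
#' Destroys the trial pairing between two ensembles by permuting the trial
#' axis of `x` (the temporal structure of every trial is left intact),
#' recomputes the statistic for each shuffled pair, and records the empirical
#' `(1 - alpha)`-quantile as the significance threshold.  An observed
#' statistic above the threshold indicates information flow that cannot be
#' explained by per-trial temporal structure alone.
#'
#' @param x,y aligned `trial_ensemble`s.
#' @param statistic function taking `(x, y)` ensembles and returning a
#'   scalar.
#' @param n_shuffles number of trial permutations (default 100).
#' @param alpha significance level for the threshold (default 0.05).
#' @param seed optional RNG seed; identical seeds give identical nulls.
#' @return Object of class `null_distribution` with fields `values`,
#'   `threshold`, `alpha`, `n_shuffles`, `seed`.
#' @export
trial_shuffle_null <- function(x, y, statistic, n_shuffles = 100,
                               alpha = 0.05, seed = NULL) {
  check_aligned(x, y)
  if (n_trials(x) < 2) stop("trial shuffling needs at least 2 trials")
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(n_shuffles), function(i) {
    xs <- x
    xs$data <- x$data[sample.int(n_trials(x)), , drop = FALSE]
    statistic(xs, y)
  }, numeric(1))
  new_null(vals, alpha, n_shuffles, seed)
}

#' Time-shuffle null distribution
#'
#' Permutes the time samples of `x` within each trial (for single-realization
#' statistics such as Granger causality, where there is no trial axis to
#' shuffle) and otherwise proceeds as [trial_shuffle_null()].
#'
#' @inheritParams trial_shuffle_null
#' @export
time_shuffle_null <- function(x, y, statistic, n_shuffles = 100,
                              alpha = 0.05, seed = NULL) {
  check_aligned(x, y)
  if (n_time(x) < 2) stop("time shuffling needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(n_shuffles), function(i) {
    xs <- x
    perm <- sample.int(n_time(x))
    xs$data <- x$data[, perm, drop = FALSE]
    statistic(xs, y)
  }, numeric(1))
  new_null(vals, alpha, n_shuffles, seed)
}

new_null <- function(vals, alpha, n_shuffles, seed) {
  # smallest null value with at least (1 - alpha) * n_shuffles values below it
  sorted <- sort(vals)
  k <- min(n_shuffles, floor((1 - alpha) * n_shuffles) + 1L)
  structure(list(values = vals,
                 threshold = sorted[k],
                 alpha = alpha, n_shuffles = n_shuffles,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: %d shuffles, alpha = %g, threshold = %.4g>\n",
    x$n_shuffles, x$alpha, x$threshold))
  invisible(x)
}

#' Empirical p-value against a shuffle null
#'
#' Permutation-inclusive (add-one) rule:
#' `p = (1 + #{null >= observed}) / (1 + n_shuffles)`, so `p > 0` always.
#'
#' @param observed observed statistic.
#' @param null a `null_distribution`.
#' @return p-value in `(0, 1]`.
#' @examples
#' nd <- structure(list(values = 1:100, n_shuffles = 100),
#'                 class = "null_distribution")
#' empirical_pvalue(101, nd)  # 1/101
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"), length(null$values) >= 1)
  (1 + sum(null$values >= observed)) / (1 + null$n_shuffles)
}

#' Benjamini-Hochberg selection at a fixed FDR bound
#'
#' Step-up rule: sort the `m` p-values ascending, find the largest `i` with
#' `p_(i) <= i q / m`, and select every p-value at or below that data-driven
#' cutoff `p_r` (nothing is selected when no such `i` exists).  This is the
#' standard procedure for thresholding large families of connectivity
#' p-values at FDR bound `q`.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @param q FDR bound (default 0.05).
#' @return Object of class `fdr_selection`: `p_values`, `q`, `p_r`, logical
#'   `mask`.
#' @examples
#' fdr_select(c(0.001, 0.02, 0.04, 0.2), q = 0.05)$p_r  # 0.02
#' @export
fdr_select <- function(p_values, q = 0.05) {
  stopifnot(q > 0, q < 1)
  m <- length(p_values)
  if (m == 0)
    return(structure(list(p_values = numeric(0), q = q, p_r = 0,
                          mask = logical(0)), class = "fdr_selection"))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  p_r <- if (length(ok)) ps[max(ok)] else 0
  structure(list(p_values = p_values, q = q, p_r = p_r,
                 mask = p_values <= p_r & p_r > 0),
            class = "fdr_selection")
}

#' @export
print.fdr_selection <- function(x, ...) {
  cat(sprintf("<fdr_selection: %d of %d selected at q = %g (p_r = %.4g)>\n",
              sum(x$mask), length(x$p_values), x$q, x$p_r))
  invisible(x)
}
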