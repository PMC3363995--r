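#' Estimator configuration
#'
#' Bundles the choice of mutual-information estimator and its parameters.
#' Three families are available:
#' \describe{
#'   \item{`adaptive_partition`}{Nonparametric estimator that recursively
#'     partitions the rank-transformed joint sample into cells, refining a
#'     cell only while a chi-square test rejects independence of the two
#'     coordinate blocks within it.  Model-free; the default.}
#'   \item{`histogram`}{Plug-in estimator on a fixed equal-width grid.}
#'   \item{`gaussian`}{Closed form from sample covariance determinants;
#'     exact for jointly Gaussian data and deterministic given the sample.}
#' }
#'
#' @param method one of `"adaptive_partition"`, `"histogram"`, `"gaussian"`.
#' @param log_base base of the logarithm; 2 gives bits (default).
#' @param ap_significance upper-tail quantile level in (0,1) of the
#'   chi-square uniformity statistics (one- and two-level) that a partition
#'   cell must exceed to be refined further.  The default 0.5 prunes a cell
#'   once its statistics drop to the typical noise level (the null median),
#'   which balances the too-coarse-partition bias (underestimation) against
#'   noise-chasing (overestimation); smaller values give a more conservative,
#'   downward-biased estimator.
#' @param ap_min_cell minimum number of points every child cell must keep for
#'   a split to be allowed.
#' @param hist_bins number of equal-width bins per coordinate for the
#'   histogram method.
#' @return An object of class `estimator_config`.
#' @examples
#' estimator_config("gaussian")
#' @export
estimator_config <- function(method = c("adaptive_partition", "histogram",
                                        "gaussian"),
                             log_base = 2, ap_significance = 0.5,
                             ap_min_cell = 5, hist_bins = 16) {
  method <- match.arg(method)
  stopifnot(log_base > 1, ap_significance > 0, ap_significance < 1,
            ap_min_cell >= 1, hist_bins >= 2)
  structure(list(method = method, log_base = log_base,
                 ap_significance = ap_significance,
                 ap_min_cell = as.integer(ap_min_cell),
                 hist_bins = as.integer(hist_bins)),
            class = "estimator_config")
}

#' @export
print.estimator_config <- function(x, ...) {
  cat(sprintf("<estimator_config: %s, log base %g>\n", x$method, x$log_base))
  invisible(x)
}

as_sample_matrix <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  x <- as.matrix(x)
  if (length(x) && !all(is.finite(x))) stop("samples must be finite")
  x
}

#' Differential entropy of a multivariate Gaussian
#'
#' Closed form `(d/2) log(2 pi e) + (1/2) log det(cov)` for a Gaussian with
#' the given covariance, in the base configured by `log_base`.
#'
#' @param cov symmetric positive-definite covariance matrix.
#' @param log_base logarithm base (2 = bits).
#' @return Entropy (a scalar, in units of `log_base`).
#' @examples
#' entropy_gaussian(diag(2))  # 2 * 0.5 * log2(2*pi*e) = 4.0942 bits
#' @export
entropy_gaussian <- function(cov, log_base = 2) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || any(abs(cov - t(cov)) > 1e-8 * (1 + max(abs(cov)))))
    stop("cov must be a symmetric matrix")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop(sprintf("cov is not positive definite (smallest eigenvalue %g)",
                 min(ev)))
  d <- nrow(cov)
  (d / 2 * log(2 * pi * exp(1)) + 0.5 * sum(log(ev))) / log(log_base)
}

# log-determinant of a sample covariance; error on singularity with a hint
sample_logdet <- function(m) {
  s <- stats::cov(m)
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < 1e-7 * (1 + max(diag(ch))))
    stop("singular sample covariance (a column is constant or an exact ",
         "linear combination of others); the gaussian estimator cannot be ",
         "used on totally dependent coordinates")
  2 * sum(log(diag(ch)))
}

mi_gaussian <- function(x, y, log_base) {
  (0.5 * (sample_logdet(x) + sample_logdet(y) - sample_logdet(cbind(x, y)))) /
    log(log_base)
}

mi_histogram <- function(x, y, bins, log_base) {
  code_block <- function(m) {
    idx <- rep(0, nrow(m))
    for (k in seq_len(ncol(m))) {
      v <- m[, k]
      r <- range(v)
      b <- if (r[1] == r[2]) rep(1L, length(v)) else
        pmin(bins, 1L + floor((v - r[1]) / (r[2] - r[1]) * bins))
      idx <- idx * bins + (b - 1L)
    }
    idx
  }
  cx <- code_block(x); cy <- code_block(y)
  n <- length(cx)
  joint <- table(paste(cx, cy, sep = ":")) / n
  px <- table(cx) / n
  py <- table(cy) / n
  keys <- strsplit(names(joint), ":", fixed = TRUE)
  mi <- 0
  for (i in seq_along(joint)) {
    p <- as.numeric(joint[i])
    mi <- mi + p * log(p / (px[[keys[[i]][1]]] * py[[keys[[i]][2]]]))
  }
  mi / log(log_base)
}

# deterministic total order on sample blocks (dims, then values)
block_leq <- function(a, b) {
  if (ncol(a) != ncol(b)) return(ncol(a) < ncol(b))
  d <- a - b
  nz <- which(d != 0)
  if (!length(nz)) return(TRUE)
  d[nz[1]] < 0
}

mi_adaptive <- function(x, y, cfg) {
  sig <- cfg$ap_significance
  cpp_ap_mi(x, y, stats::qchisq(1 - sig, df = 3),
            stats::qchisq(1 - sig, df = 15), cfg$ap_min_cell) /
    log(cfg$log_base)
}

#' Mutual information between two sample blocks
#'
#' Estimates `I(X; Y)` from paired samples: row `i` of `x` and row `i` of `y`
#' form one joint realization.  Both arguments may be multi-column, in which
#' case the MI between the two random vectors is estimated.  Symmetric in its
#' arguments by construction.  Nonparametric estimates may come out slightly
#' negative; they are returned as-is.
#'
#' @param x,y numeric matrices (or vectors) with equal row counts.
#' @param cfg an [estimator_config()].
#' @return MI estimate in units of `cfg$log_base` (bits by default).
#' @examples
#' cfg <- estimator_config("gaussian")
#' x <- rnorm(2000); y <- 0.6 * x + 0.8 * rnorm(2000)
#' estimate_mi(x, y, cfg)  # about -0.5*log2(1 - 0.36) = 0.32 bits
#' @export
estimate_mi <- function(x, y, cfg = estimator_config()) {
  x <- as_sample_matrix(x); y <- as_sample_matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of samples")
  if (ncol(x) == 0L || ncol(y) == 0L) return(0)
  if (cfg$method == "adaptive_partition" && nrow(x) < cfg$ap_min_cell)
    stop("too few samples for the adaptive-partition estimator")
  # canonical argument order, so estimate_mi(x, y) is bit-identical to
  # estimate_mi(y, x) for every method
  if (!block_leq(x, y)) { tmp <- x; x <- y; y <- tmp }
  switch(cfg$method,
         gaussian = mi_gaussian(x, y, cfg$log_base),
         histogram = mi_histogram(x, y, cfg$hist_bins, cfg$log_base),
         adaptive_partition = mi_adaptive(x, y, cfg))
}

#' Conditional mutual information
#'
#' Estimates `I(X; Y | Z)` through the decomposition
#' `I(X; (Y, Z)) - I(X; Z)`, so that only mutual informations between two
#' blocks are ever estimated and part of the estimator bias cancels.  With a
#' zero-width `z` this reduces exactly to [estimate_mi()].
#'
#' @param x,y,z numeric matrices (or vectors) with equal row counts; `z` may
#'   be `NULL` or zero-column.
#' @inheritParams estimate_mi
#' @return CMI estimate in units of `cfg$log_base`.
#' @export
estimate_cmi <- function(x, y, z = NULL, cfg = estimator_config()) {
  x <- as_sample_matrix(x); y <- as_sample_matrix(y); z <- as_sample_matrix(z)
  if (ncol(z) == 0L) return(estimate_mi(x, y, cfg))
  if (nrow(x) != nrow(y) || nrow(x) != nrow(z))
    stop("x, y and z must have the same number of samples")
  estimate_mi(x, cbind(y, z), cfg) - estimate_mi(x, z, cfg)
}
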