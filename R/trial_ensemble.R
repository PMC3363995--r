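#' Trial ensemble of one channel
#'
#' Container for one channel's recordings: a trials-by-time matrix together
#' with its sampling rate.  Trials are treated as i.i.d. realizations of the
#' underlying process, which is what every information estimator in this
#' package consumes: the joint density at each time index is estimated across
#' trials.
#'
#' @param data numeric matrix, `n_trials x n_time` (each row one trial).
#'   A vector is treated as a single trial.
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @param label character label for the channel.
#' @return An object of class `trial_ensemble`.
#' @examples
#' te <- trial_ensemble(matrix(rnorm(200), 20, 10), 512, "Cz")
#' n_trials(te); n_time(te)
#' @export
trial_ensemble <- function(data, sampling_rate_hz = 1, label = "") {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("ensemble data must be finite numeric values")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("ensemble needs at least one trial and one time sample")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive scalar")
  structure(
    list(data = unname(data), sampling_rate_hz = as.numeric(sampling_rate_hz),
         label = as.character(label)),
    class = "trial_ensemble")
}

#' @rdname trial_ensemble
#' @param x a `trial_ensemble`.
#' @export
n_trials <- function(x) nrow(x$data)

#' @rdname trial_ensemble
#' @export
n_time <- function(x) ncol(x$data)

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble '%s': %d trials x %d samples @ %g Hz>\n",
              x$label, n_trials(x), n_time(x), x$sampling_rate_hz))
  invisible(x)
}

# internal: check two ensembles are aligned
check_aligned <- function(x, y) {
  stopifnot(inherits(x, "trial_ensemble"), inherits(y, "trial_ensemble"))
  if (n_trials(x) != n_trials(y) || n_time(x) != n_time(y))
    stop("ensembles must share trial count and length")
  invisible(TRUE)
}

#' Samples of lagged windows across trials
#'
#' Extracts, for a single time index `n`, the across-trial sample of the
#' window `(X[n - from], ..., X[n - to])`.  Used internally to turn a trial
#' ensemble into the sample matrices the estimators consume.
#'
#' @param x a `trial_ensemble`.
#' @param n time index (1-based).
#' @param from,to lag range; `from >= to >= 0`.  `from = p, to = 1` gives the
#'   `p` past samples; `from = to = 0` gives the current sample.
#' @return numeric matrix, `n_trials x (from - to + 1)`.
#' @keywords internal
lag_window <- function(x, n, from, to) {
  stopifnot(from >= to, to >= 0, n - from >= 1, n <= n_time(x))
  x$data[, n - from:to, drop = FALSE]
}
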