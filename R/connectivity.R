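#' Multichannel trial ensemble
#'
#' A list of aligned [trial_ensemble()]s (same trial count, length, and
#' sampling rate) with unique channel names.
#'
#' @param channels named list of `trial_ensemble`s, or a 3-d array
#'   `channel x trial x time`.
#' @param channel_names channel names (defaults to list names).
#' @param sampling_rate_hz sampling rate, used when `channels` is an array.
#' @return Object of class `multichannel_ensemble`.
#' @export
multichannel_ensemble <- function(channels, channel_names = NULL,
                                  sampling_rate_hz = 1) {
  if (is.array(channels) && length(dim(channels)) == 3) {
    nm <- channel_names
    if (is.null(nm)) nm <- dimnames(channels)[[1]]
    if (is.null(nm)) nm <- paste0("ch", seq_len(dim(channels)[1]))
    channels <- lapply(seq_len(dim(channels)[1]), function(k)
      trial_ensemble(channels[k, , , drop = TRUE], sampling_rate_hz, nm[k]))
    names(channels) <- nm
    channel_names <- nm
  }
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(channel_names))
    channel_names <- names(channels)
  if (is.null(channel_names) ||
      anyDuplicated(channel_names) || any(channel_names == ""))
    stop("channels need unique non-empty names")
  ref <- channels[[1]]
  for (ch in channels) {
    check_aligned(ref, ch)
    if (ch$sampling_rate_hz != ref$sampling_rate_hz)
      stop("channels must share a sampling rate")
  }
  names(channels) <- channel_names
  structure(list(channels = channels, channel_names = channel_names),
            class = "multichannel_ensemble")
}

#' @export
print.multichannel_ensemble <- function(x, ...) {
  ref <- x$channels[[1]]
  cat(sprintf("<multichannel_ensemble: %d channels x %d trials x %d samples @ %g Hz>\n",
              length(x$channels), n_trials(ref), n_time(ref),
              ref$sampling_rate_hz))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' trial of every channel.  Zero-phase filtering matters here: a causal
#' filter's group delay would shift channels in time and could masquerade as
#' lagged information flow.
#'
#' @param ensemble a `multichannel_ensemble` (or single `trial_ensemble`).
#' @param low_hz,high_hz band edges; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param filter_order Butterworth order (default 4).
#' @return Filtered object of the same class and dimensions.
#' @export
bandpass <- function(ensemble, low_hz, high_hz, filter_order = 4) {
  if (inherits(ensemble, "trial_ensemble")) {
    fs <- ensemble$sampling_rate_hz
    if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
      stop("band must satisfy 0 < low < high < Nyquist (", fs / 2, " Hz)")
    bf <- signal::butter(filter_order, c(low_hz, high_hz) / (fs / 2),
                         type = "pass")
    out <- t(apply(ensemble$data, 1, function(tr)
      signal::filtfilt(bf, tr)))
    return(trial_ensemble(out, fs, ensemble$label))
  }
  stopifnot(inherits(ensemble, "multichannel_ensemble"))
  multichannel_ensemble(lapply(ensemble$channels, bandpass,
                               low_hz = low_hz, high_hz = high_hz,
                               filter_order = filter_order))
}

# concatenate trials into one realization, removing each trial's mean
concat_trials <- function(ens) {
  d <- ens$data - rowMeans(ens$data)
  as.vector(t(d))
}

#' Pairwise effective-connectivity pipeline
#'
#' For every ordered channel pair `(i, j)` of a multichannel ensemble:
#' restricts to the analysis window, selects a shared model order with
#' [select_order()], tests MDI with a trial-shuffle null ([mdi_test()]), and
#' tests Granger causality on the trial-concatenated (per-trial demeaned)
#' series with a time-shuffle null ([gc_test()]).  The DI and GC p-value
#' families are each passed to [fdr_select()] at bound `q_fdr` to produce
#' significance masks.  Per-pair failures are recorded and skipped, not
#' fatal.
#'
#' @param ensemble a `multichannel_ensemble`.
#' @param window_start first sample (1-based) of the analysis window.
#' @param window_len window length in samples.
#' @param q_fdr FDR bound for both measure families (default 0.05).
#' @param n_shuffles shuffles per pair (default 100).
#' @param seed RNG seed; each pair's nulls are seeded deterministically from
#'   it.
#' @param cao a [cao_config()] for the order search.
#' @param estimator an [estimator_config()] for the MDI terms.
#' @param statistic statistic passed to [mdi_test()].
#' @param gc_mode `"concatenate"` (one long demeaned series, default) or
#'   `"average_f"` (mean per-trial Geweke index).
#' @return Object of class `connectivity_result`: square matrices `di_matrix`
#'   (raw MDI), `gc_matrix`, `p_di`, `p_gc`, masks `mask_di`, `mask_gc`
#'   (diagonals `NA`), `order_used` matrix, `window`, `seed`, and a character
#'   vector `failures`.
#' @export
pairwise_connectivity <- function(ensemble, window_start = 1,
                                  window_len = NULL, q_fdr = 0.05,
                                  n_shuffles = 100, seed = 1,
                                  cao = cao_config(),
                                  estimator = estimator_config("gaussian"),
                                  statistic = "normalized",
                                  gc_mode = c("concatenate", "average_f")) {
  stopifnot(inherits(ensemble, "multichannel_ensemble"))
  gc_mode <- match.arg(gc_mode)
  chans <- ensemble$channels
  nc <- length(chans)
  nt <- n_time(chans[[1]])
  if (is.null(window_len)) window_len <- nt - window_start + 1
  if (window_start < 1 || window_start + window_len - 1 > nt)
    stop("analysis window outside the recording")
  win <- window_start:(window_start + window_len - 1)
  chans <- lapply(chans, function(ch)
    trial_ensemble(ch$data[, win, drop = FALSE], ch$sampling_rate_hz,
                   ch$label))

  mk <- function(fill) {
    m <- matrix(fill, nc, nc,
                dimnames = list(ensemble$channel_names,
                                ensemble$channel_names))
    diag(m) <- NA
    m
  }
  di_m <- mk(NA_real_); gc_m <- mk(NA_real_)
  p_di <- mk(NA_real_); p_gc <- mk(NA_real_)
  ord_m <- mk(NA_integer_)
  failures <- character(0)

  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    pair_seed <- (seed + 7907L * i + 131L * j) %% .Machine$integer.max
    res <- tryCatch({
      p <- select_order(chans[[i]], chans[[j]], cao)
      cfg <- di_config(p = as.integer(p), estimator = estimator)
      dt <- mdi_test(chans[[i]], chans[[j]], cfg, n_shuffles = n_shuffles,
                     seed = pair_seed, statistic = statistic)
      xi <- concat_trials(chans[[i]])
      yj <- concat_trials(chans[[j]])
      gt <- if (gc_mode == "concatenate") {
        gc_test(xi, yj, order = as.integer(p), n_shuffles = n_shuffles,
                seed = pair_seed + 1L)
      } else {
        fs <- mean(vapply(seq_len(n_trials(chans[[i]])), function(m)
          granger_f(chans[[i]]$data[m, ], chans[[j]]$data[m, ],
                    as.integer(p)), numeric(1)))
        gt0 <- gc_test(xi, yj, order = as.integer(p),
                       n_shuffles = n_shuffles, seed = pair_seed + 1L)
        gt0$f <- fs
        gt0
      }
      list(p = p, dt = dt, gt = gt)
    }, error = function(e) e)
    nm_i <- ensemble$channel_names[i]; nm_j <- ensemble$channel_names[j]
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("%s->%s: %s", nm_i, nm_j, conditionMessage(res)))
      next
    }
    ord_m[i, j] <- as.integer(res$p)
    di_m[i, j] <- res$dt$di_xy
    p_di[i, j] <- res$dt$p_value
    gc_m[i, j] <- res$gt$f
    p_gc[i, j] <- res$gt$p_value
  }

  off <- !is.na(p_di)
  mask_di <- mk(FALSE)
  mask_di[off] <- fdr_select(p_di[off], q_fdr)$mask
  off_g <- !is.na(p_gc)
  mask_gc <- mk(FALSE)
  mask_gc[off_g] <- fdr_select(p_gc[off_g], q_fdr)$mask

  structure(list(di_matrix = di_m, gc_matrix = gc_m,
                 p_di = p_di, p_gc = p_gc,
                 mask_di = mask_di, mask_gc = mask_gc,
                 order_used = ord_m, q_fdr = q_fdr,
                 n_shuffles = n_shuffles, seed = seed,
                 window = c(start = window_start, length = window_len),
                 failures = failures),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<connectivity_result: %d channels; %d DI and %d GC edges significant ",
    "at FDR q = %g; %d pair failures>\n"),
    nrow(x$di_matrix), sum(x$mask_di, na.rm = TRUE),
    sum(x$mask_gc, na.rm = TRUE), x$q_fdr, length(x$failures)))
  invisible(x)
}

# --- file I/O ---------------------------------------------------------------

#' Read and write multichannel ensembles as long-form CSV
#'
#' The on-disk convention is long-form delimited text with header
#' `channel,trial,time,value`, time in 0-based sample indices, one row per
#' sample.  The round trip `write_ensemble()` then `read_ensemble()` is
#' lossless up to the numeric formatting (17 significant digits, i.e.
#' bit-exact for doubles).
#'
#' @param path file path.
#' @param sampling_rate_hz sampling rate to attach on read.
#' @param ensemble a `multichannel_ensemble` to write.
#' @return `read_ensemble()` returns a `multichannel_ensemble`;
#'   `write_ensemble()` returns `path` invisibly.
#' @export
read_ensemble <- function(path, sampling_rate_hz = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "trial", "time", "value")
  if (!all(need %in% names(df)))
    stop("ensemble CSV needs header columns: ", paste(need, collapse = ","))
  if (any(!is.finite(df$value)))
    stop("non-finite value at data row ", which(!is.finite(df$value))[1])
  chs <- unique(df$channel)
  trials <- sort(unique(df$trial))
  times <- sort(unique(df$time))
  channels <- lapply(chs, function(ch) {
    sub <- df[df$channel == ch, ]
    if (nrow(sub) != length(trials) * length(times))
      stop("channel '", ch, "' has ", nrow(sub), " rows; expected ",
           length(trials) * length(times),
           " (missing or duplicate (trial, time) cells)")
    m <- matrix(NA_real_, length(trials), length(times))
    m[cbind(match(sub$trial, trials), match(sub$time, times))] <- sub$value
    if (anyNA(m)) {
      gap <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("channel '", ch, "' missing cell (trial ", trials[gap[1]],
           ", time ", times[gap[2]], ")")
    }
    trial_ensemble(m, sampling_rate_hz, ch)
  })
  names(channels) <- chs
  multichannel_ensemble(channels)
}

#' @rdname read_ensemble
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "multichannel_ensemble"))
  rows <- lapply(ensemble$channel_names, function(nm) {
    m <- ensemble$channels[[nm]]$data
    data.frame(channel = nm,
               trial = rep(seq_len(nrow(m)), times = ncol(m)),
               time = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
               value = sprintf("%.17g", as.vector(m)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize and reload connectivity results
#'
#' `write_result()` stores a [pairwise_connectivity()] result as JSON
#' (matrices, p-values, masks, configuration, seed, and package version);
#' `read_result()` restores it with matrices intact.
#'
#' @param result a `connectivity_result`.
#' @param path file path (`.json`).
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "connectivity_result"))
  payload <- list(
    version = as.character(utils::packageVersion("neurodi")),
    channel_names = rownames(result$di_matrix),
    di_matrix = result$di_matrix, gc_matrix = result$gc_matrix,
    p_di = result$p_di, p_gc = result$p_gc,
    mask_di = result$mask_di, mask_gc = result$mask_gc,
    order_used = result$order_used,
    q_fdr = result$q_fdr, n_shuffles = result$n_shuffles,
    seed = result$seed, window = as.list(result$window),
    failures = result$failures)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- p$channel_names
  fix <- function(m, mode = "numeric") {
    m <- as.matrix(m)
    dimnames(m) <- list(nm, nm)
    storage.mode(m) <- mode
    m
  }
  structure(list(di_matrix = fix(p$di_matrix), gc_matrix = fix(p$gc_matrix),
                 p_di = fix(p$p_di), p_gc = fix(p$p_gc),
                 mask_di = fix(p$mask_di, "logical"),
                 mask_gc = fix(p$mask_gc, "logical"),
                 order_used = fix(p$order_used, "integer"),
                 q_fdr = p$q_fdr, n_shuffles = p$n_shuffles, seed = p$seed,
                 window = unlist(p$window), failures = p$failures),
            class = "connectivity_result")
}
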