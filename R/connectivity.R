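# Detection of putative monosynaptic connections from fine-timescale spike
# cross-correlograms, and weight-distribution statistics.

#' Spike-train cross-correlogram
#'
#' Histogram of time differences `t_post - t_pre` over all spike pairs
#' within the window, in fine bins (0.2 ms by default, bin centers from
#' -window to +window inclusive: 501 bins for the default).
#'
#' @param pre,post sorted spike-time vectors (s)
#' @param window_ms half-window (default 50 ms)
#' @param bin_ms bin width (default 0.2 ms)
#' @param drop_zero drop exactly-zero lags (for auto-correlograms, to
#'   exclude self-pairs)
#' @return list of class `ccg`: `lag_ms` (bin centers), `counts`,
#'   `n_pre`, `n_post`, `window_ms`, `bin_ms`
#' @export
crosscorrelogram <- function(pre, post, window_ms = 50, bin_ms = 0.2,
                             drop_zero = FALSE) {
  if (length(pre) == 0 || length(post) == 0)
    stop("both spike trains must be non-empty")
  w <- window_ms / 1000
  i1 <- findInterval(pre - w, post) + 1L
  i2 <- findInterval(pre + w, post)
  ns <- pmax(i2 - i1 + 1L, 0L)
  keep <- ns > 0L
  diffs <- (post[sequence(ns[keep], from = i1[keep])] -
              rep(pre[keep], ns[keep])) * 1000
  if (drop_zero) diffs <- diffs[diffs != 0]
  centers <- seq(-window_ms, window_ms, by = bin_ms)
  breaks <- c(centers - bin_ms / 2, window_ms + bin_ms / 2)
  counts <- tabulate(findInterval(diffs, breaks), nbins = length(centers))
  structure(list(lag_ms = centers, counts = counts,
                 n_pre = length(pre), n_post = length(post),
                 window_ms = window_ms, bin_ms = bin_ms),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("ccg: +/-%g ms in %g ms bins, %d pre / %d post spikes, peak %d\n",
              x$window_ms, x$bin_ms, x$n_pre, x$n_post, max(x$counts)))
  invisible(x)
}

#' Detect a putative monosynaptic connection in a cross-correlogram
#'
#' The baseline predictor is the correlogram convolved with a Gaussian
#' kernel of 4 ms s.d. (full kernel, edge-renormalized). Each bin is tested
#' against the 99th percentile of the Poisson distribution at the predicted
#' rate; a connection is significant when at least two consecutive bins
#' within the short-latency search window (0.5-5 ms after the presynaptic
#' spike by default) exceed their thresholds. The weight is the amplitude
#' of the short-latency peak: the excess count over the predictor summed
#' across the contiguous positive-excess bins containing the peak,
#' normalized by the number of presynaptic spikes (an efficacy-like
#' spikes-per-presynaptic-spike quantity that is insensitive to how
#' synaptic latency jitter spreads the peak over fine bins).
#'
#' @param ccg a [crosscorrelogram()] result
#' @param search_ms latency search window, ms after the presynaptic spike
#' @param predictor_sd_ms s.d. of the Gaussian baseline kernel (default 4)
#' @param p threshold percentile of the Poisson distribution (default 0.99)
#' @return list of class `synapse_call`: `significant`, `sig_mask` (per-bin,
#'   full correlogram), `weight`, `latency_ms`, `predictor`
#' @export
detect_synapse <- function(ccg, search_ms = c(0.5, 5), predictor_sd_ms = 4,
                           p = 0.99) {
  counts <- ccg$counts
  if (sum(counts) == 0)
    return(structure(list(significant = FALSE, sig_mask = rep(FALSE, length(counts)),
                          weight = NA_real_, latency_ms = NA_real_,
                          predictor = counts),
                     class = "synapse_call"))
  predictor <- smooth_linear(counts, predictor_sd_ms / ccg$bin_ms)
  thr <- stats::qpois(p, pmax(predictor, 0))
  supra <- counts > thr
  win <- ccg$lag_ms >= search_ms[1] & ccg$lag_ms <= search_ms[2]
  runs <- rle(supra & win)
  significant <- any(runs$lengths[runs$values] >= 2)
  excess <- counts - predictor
  wi <- which(win)
  pk_loc <- which.max(excess[win])
  pk <- wi[pk_loc]
  # peak region: contiguous positive-excess bins around the argmax
  lo <- pk_loc
  while (lo > 1 && excess[wi[lo - 1]] > 0) lo <- lo - 1
  hi <- pk_loc
  while (hi < length(wi) && excess[wi[hi + 1]] > 0) hi <- hi + 1
  structure(list(significant = significant, sig_mask = supra,
                 weight = sum(excess[wi[lo:hi]]) / ccg$n_pre,
                 latency_ms = ccg$lag_ms[pk], predictor = predictor),
            class = "synapse_call")
}

#' @export
print.synapse_call <- function(x, ...) {
  cat(sprintf("synapse_call: %s, weight %.4g at %.1f ms\n",
              if (x$significant) "significant" else "not significant",
              x$weight, x$latency_ms))
  invisible(x)
}

#' Summary statistics of a set of synaptic weights
#'
#' Natural-scale moments of the weight distribution; the coefficient of
#' variation (s.d./mean) is the dispersion statistic compared against the
#' feed-forward model's symmetry-emergence regime.
#'
#' @param weights numeric weights (e.g. from significant [detect_synapse()]
#'   calls)
#' @return list: `n`, `mean`, `sd`, `cv`, `skewness`
#' @export
weight_stats <- function(weights) {
  weights <- weights[is.finite(weights)]
  if (length(weights) < 2) stop("need at least 2 weights")
  m <- mean(weights); s <- stats::sd(weights)
  sk <- mean((weights - m)^3) / (mean((weights - m)^2)^1.5)
  list(n = length(weights), mean = m, sd = s,
       cv = if (m != 0) s / m else NaN, skewness = sk)
}
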