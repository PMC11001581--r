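# Inhomogeneous-Poisson spike emission from ground-truth tuning curves, and
# injection of monosynaptic structure into spike trains.

#' Generate an inhomogeneous Poisson spike train from a tuning curve
#'
#' The driving angle series (real trajectory during wake, or a latent
#' drifting angle during REM) is sampled at its own time step; per-step
#' counts are Poisson with rate `lambda(hd(t)) * dt` and spike times are
#' jittered uniformly within the step. During `gain` ON intervals the rate
#' becomes `m * lambda + a * max(lambda)`; negative resulting rates are
#' clipped at zero and counted.
#'
#' @param tuning numeric vector of ground-truth rates (Hz) over angular bins
#'   anchored at 0 degrees
#' @param hd_series data.frame with columns `t` (s, uniform step) and `hd`
#'   (degrees); a `trajectory` works directly
#' @param gain list with elements `multiplicative` (m, default 1),
#'   `additive` (a, fraction of the tuning maximum, default 0) and
#'   `schedule` (matrix with columns start/end in seconds, or NULL)
#' @param bin_deg angular bin width of `tuning` (default inferred as
#'   360 / length(tuning))
#' @param seed integer seed
#' @return numeric vector of sorted spike times (s), with attribute
#'   `n_clipped` (number of samples whose rate was clipped at 0)
#' @export
generate_spikes <- function(tuning, hd_series, gain = NULL, bin_deg = NULL,
                            seed = NULL) {
  if (is.null(bin_deg)) bin_deg <- 360 / length(tuning)
  if (!is.null(seed)) set.seed(seed)
  t <- hd_series$t
  dt <- stats::median(diff(t))
  idx <- (floor(wrap_deg(hd_series$hd) / bin_deg) %% length(tuning)) + 1L
  lam <- tuning[idx]
  n_clipped <- 0L
  if (!is.null(gain)) {
    m <- if (is.null(gain$multiplicative)) 1 else gain$multiplicative
    a <- if (is.null(gain$additive)) 0 else gain$additive
    sched <- gain$schedule
    on <- if (is.null(sched)) rep(TRUE, length(t)) else in_intervals(t, sched)
    lam_on <- m * lam + a * max(tuning)
    neg <- on & lam_on < 0
    n_clipped <- sum(neg)
    lam_on[lam_on < 0] <- 0
    lam[on] <- lam_on[on]
  }
  counts <- stats::rpois(length(lam), lam * dt)
  tot <- sum(counts)
  if (tot == 0) {
    spk <- numeric(0)
  } else {
    spk <- sort(rep(t[counts > 0], counts[counts > 0]) +
                  stats::runif(tot, 0, dt))
  }
  attr(spk, "n_clipped") <- n_clipped
  spk
}

# TRUE for times falling inside any [start, end) row of a 2-column matrix.
in_intervals <- function(t, intervals) {
  intervals <- as_epoch_matrix(intervals)
  out <- rep(FALSE, length(t))
  for (r in seq_len(nrow(intervals)))
    out <- out | (t >= intervals[r, 1] & t < intervals[r, 2])
  out
}

as_epoch_matrix <- function(epoch) {
  if (is.null(epoch)) return(NULL)
  if (is.data.frame(epoch)) {
    cols <- intersect(c("start_s", "end_s"), names(epoch))
    if (length(cols) == 2) return(as.matrix(epoch[, cols]))
    epoch <- as.matrix(epoch)
  }
  if (is.matrix(epoch)) return(epoch)
  matrix(epoch, ncol = 2, byrow = TRUE)
}

#' Inject a monosynaptic connection into a postsynaptic spike train
#'
#' For every presynaptic spike, with probability `efficacy` a postsynaptic
#' spike is inserted at `latency_ms` plus Gaussian jitter. Creates the
#' short-latency cross-correlogram structure that synapse detection must
#' recover; the number of inserted spikes is recorded.
#'
#' @param pre,post sorted spike time vectors (s)
#' @param efficacy per-spike transmission probability in \[0, 1]
#' @param latency_ms synaptic latency (ms)
#' @param jitter_ms Gaussian s.d. of latency jitter (ms)
#' @param seed integer seed
#' @return merged sorted postsynaptic train with attribute `n_injected`
#' @export
inject_synapse <- function(pre, post, efficacy, latency_ms = 2,
                           jitter_ms = 0.2, seed = NULL) {
  if (efficacy < 0 || efficacy > 1) stop("`efficacy` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  fire <- stats::runif(length(pre)) < efficacy
  add <- pre[fire] + (latency_ms + stats::rnorm(sum(fire), 0, jitter_ms)) / 1000
  out <- sort(c(post, add))
  attr(out, "n_injected") <- sum(fire)
  out
}
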