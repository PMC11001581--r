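# Occupancy-normalized circular tuning curves and tuning metrics.

#' Construct a tuning curve object
#' @param rates firing rates per angular bin (Hz)
#' @param occupancy_s occupancy per bin (s)
#' @param bin_deg angular bin width (deg); bin i covers
#'   `[(i-1)*bin_deg, i*bin_deg)`
#' @param smooth_sd_deg Gaussian smoothing s.d. applied (deg; 0 = none)
#' @param epoch epoch identifier (free-form)
#' @return object of class `tuning_curve`
#' @export
tuning_curve <- function(rates, occupancy_s = NULL, bin_deg = 360 / length(rates),
                         smooth_sd_deg = 0, epoch = NA) {
  if (is.null(occupancy_s)) occupancy_s <- rep(1, length(rates))
  stopifnot(length(rates) == length(occupancy_s),
            abs(length(rates) * bin_deg - 360) < 1e-9)
  structure(list(rates = as.numeric(rates),
                 occupancy_s = as.numeric(occupancy_s),
                 bin_deg = bin_deg, smooth_sd_deg = smooth_sd_deg,
                 epoch = epoch),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf(paste0("tuning_curve: %d bins of %g deg, peak %.2f Hz at %g deg,",
                     " mean %.2f Hz, occupancy %.1f s\n"),
              length(x$rates), x$bin_deg, max(x$rates),
              (which.max(x$rates) - 1) * x$bin_deg,
              sum(x$rates * occ_p(x)), sum(x$occupancy_s)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(bin_angles(x), x$rates, type = "l",
                 xlab = "head direction (deg)", ylab = "rate (Hz)", ...)
  invisible(x)
}

# left-edge angle of each bin (bins anchored at 0 degrees)
bin_angles <- function(tc) (seq_along(tc$rates) - 1) * tc$bin_deg

occ_p <- function(tc) {
  s <- sum(tc$occupancy_s)
  if (s <= 0) rep(NA_real_, length(tc$occupancy_s)) else tc$occupancy_s / s
}

rates_of <- function(x) if (inherits(x, "tuning_curve")) x$rates else as.numeric(x)

#' Compute an occupancy-normalized head-direction tuning curve
#'
#' Spike-count and occupancy histograms over angular bins are smoothed
#' separately with a circular Gaussian kernel (truncated at 4 s.d.) and then
#' divided, which stabilizes bins with little occupancy while conserving
#' total spike mass and total time. Samples with speed below
#' `speed_min_cms` are excluded from both histograms (set the threshold to 0
#' for short cue/opto epochs where speed filtering is not applied).
#'
#' @param spikes sorted spike times (s)
#' @param trajectory data.frame with `t`, `hd` and optionally `speed`
#' @param epoch NULL (whole trajectory), a `c(start, end)` pair, or a matrix
#'   / data.frame of disjoint `[start, end)` intervals
#' @param bin_deg angular bin width (default 1 deg)
#' @param smooth_sd_deg Gaussian kernel s.d. (default 3 deg; 0 disables)
#' @param speed_min_cms minimum speed (default 2 cm/s)
#' @return a [tuning_curve()] whose `occupancy_s` sums to the speed-filtered
#'   epoch duration
#' @export
compute_tuning_curve <- function(spikes, trajectory, epoch = NULL, bin_deg = 1,
                                 smooth_sd_deg = 3, speed_min_cms = 2) {
  n_bins <- as.integer(round(360 / bin_deg))
  stopifnot(abs(n_bins * bin_deg - 360) < 1e-9)
  t <- trajectory$t
  dt <- stats::median(diff(t))
  keep <- rep(TRUE, length(t))
  if (!is.null(epoch)) keep <- in_intervals(t, epoch)
  if (speed_min_cms > 0 && !is.null(trajectory$speed))
    keep <- keep & trajectory$speed >= speed_min_cms
  if (!any(keep)) stop("no occupancy in the requested epoch after filtering")
  bin_of <- (floor(wrap_deg(trajectory$hd) / bin_deg) %% n_bins) + 1L
  occ <- tabulate(bin_of[keep], nbins = n_bins) * dt
  si <- findInterval(spikes, t)
  # sample-and-hold window (small tolerance: spikes landing on a float
  # boundary must not fall through)
  valid <- si >= 1L & (spikes - t[pmax(si, 1L)]) < dt * (1 + 1e-9)
  si <- si[valid]
  si <- si[keep[si]]
  cnt <- tabulate(bin_of[si], nbins = n_bins)
  if (smooth_sd_deg > 0) {
    sd_bins <- smooth_sd_deg / bin_deg
    cnt <- smooth_circular(cnt, sd_bins)
    occ <- smooth_circular(occ, sd_bins)
  }
  rates <- ifelse(occ > 0, cnt / occ, 0)
  tuning_curve(rates, occ, bin_deg, smooth_sd_deg)
}

#' Head-direction information of a tuning curve
#'
#' `I = sum_i lambda(theta_i) * log2(lambda(theta_i) / lambda) * p(theta_i)`
#' in bits/s, where `lambda = sum_i lambda(theta_i) p(theta_i)` is the mean
#' rate and `p` the normalized occupancy; bins with zero rate contribute 0.
#' The rate-normalized value (bits/spike) is rate-scale and rotation
#' invariant.
#'
#' @param curve a [tuning_curve()] (or a rate vector, with uniform occupancy
#'   assumed)
#' @return list of class `hd_info`: `info_bits_per_s`, `info_bits_per_spike`
#'   (`NaN` when the mean rate is 0), `mean_rate_hz`
#' @export
hd_information <- function(curve) {
  if (!inherits(curve, "tuning_curve")) curve <- tuning_curve(curve)
  p <- occ_p(curve)
  lam <- curve$rates
  lbar <- sum(lam * p)
  pos <- lam > 0 & p > 0
  bits_s <- if (lbar > 0)
    sum(lam[pos] * log2(lam[pos] / lbar) * p[pos]) else 0
  structure(list(info_bits_per_s = bits_s,
                 info_bits_per_spike = if (lbar > 0) bits_s / lbar else NaN,
                 mean_rate_hz = lbar),
            class = "hd_info")
}

#' @export
print.hd_info <- function(x, ...) {
  cat(sprintf("hd_info: %.3f bits/spike (%.3f bits/s at %.2f Hz)\n",
              x$info_bits_per_spike, x$info_bits_per_s, x$mean_rate_hz))
  invisible(x)
}

#' Time-reversed control tuning and information
#'
#' Reverses the order of head-direction samples against their timestamps
#' within the epoch, decoupling spikes from direction while preserving both
#' the spike train and the occupancy histogram, then recomputes the tuning
#' curve and HD information.
#'
#' @inheritParams compute_tuning_curve
#' @return list with `curve` (control [tuning_curve()]) and `info`
#'   (control `hd_info`)
#' @export
time_reversed_control <- function(spikes, trajectory, epoch = NULL, bin_deg = 1,
                                  smooth_sd_deg = 3, speed_min_cms = 2) {
  t <- trajectory$t
  sel <- if (is.null(epoch)) rep(TRUE, length(t)) else in_intervals(t, epoch)
  trj <- trajectory
  trj$hd[sel] <- rev(trj$hd[sel])
  if (!is.null(trj$speed)) trj$speed[sel] <- rev(trj$speed[sel])
  curve <- compute_tuning_curve(spikes, trj, epoch, bin_deg, smooth_sd_deg,
                                speed_min_cms)
  list(curve = curve, info = hd_information(curve))
}

#' Classify HD cells from information scores
#'
#' A cell is an HD cell when its information exceeds the 99th percentile
#' (linear interpolation) of the time-reversed control distribution, or a
#' fixed cut in bits/spike (the population-level criterion resolves to
#' 0.2 bits/spike in large cortical datasets).
#'
#' @param info bits/spike per cell
#' @param control control bits/spike distribution (pooled across cells);
#'   ignored when `fixed_cut` is given
#' @param fixed_cut optional fixed threshold in bits/spike
#' @return logical vector of HD flags
#' @export
classify_hd <- function(info, control = NULL, fixed_cut = NULL) {
  thr <- if (!is.null(fixed_cut)) fixed_cut
  else {
    if (is.null(control) || length(control) < 2)
      stop("need a control distribution (>= 2 cells) or a fixed cut")
    stats::quantile(control, 0.99, names = FALSE, type = 7)
  }
  info > thr
}

#' Classify units into fast-spiking and excitatory classes
#'
#' Fast-spiking: trough-to-peak < 0.4 ms and mean rate > 10 Hz.
#' Excitatory: trough-to-peak > 0.4 ms and mean rate < 10 Hz.
#' Everything else is unclassified.
#'
#' @param mean_rate_hz mean firing rates
#' @param trough_to_peak_ms waveform trough-to-peak durations
#' @return character vector: `"FS"`, `"excitatory"` or `"unclassified"`
#' @export
classify_units <- function(mean_rate_hz, trough_to_peak_ms) {
  ifelse(trough_to_peak_ms < 0.4 & mean_rate_hz > 10, "FS",
         ifelse(trough_to_peak_ms > 0.4 & mean_rate_hz < 10, "excitatory",
                "unclassified"))
}

#' Circular cross-correlogram of two tuning curves
#'
#' Pearson correlation between curve `a` and curve `b` circularly shifted by
#' every offset `0 .. 359` degrees (in units of the bin width). The offset
#' with maximum correlation gives the rotation of `b` relative to `a`.
#'
#' @param a,b tuning curves (or rate vectors) with the same bin width
#' @return numeric vector of correlations, named by offset in degrees; all
#'   `NaN` (with a warning) when either curve has zero variance
#' @export
circular_xcorr <- function(a, b) {
  av <- rates_of(a); bv <- rates_of(b)
  stopifnot(length(av) == length(bv))
  n <- length(av)
  bd <- if (inherits(a, "tuning_curve")) a$bin_deg else 360 / n
  a0 <- av - mean(av); b0 <- bv - mean(bv)
  sa <- sqrt(mean(a0^2)); sb <- sqrt(mean(b0^2))
  offs <- (seq_len(n) - 1) * bd
  if (sa == 0 || sb == 0) {
    warning("zero-variance curve: correlogram undefined")
    return(stats::setNames(rep(NaN, n), offs))
  }
  # circular cross-covariance via FFT: cc[k] = mean_i a0[i] * b0[i + k],
  # so the argmax offset is the forward rotation of b relative to a
  cc <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(b0), inverse = TRUE)) / n^2
  stats::setNames(cc / (sa * sb), offs)
}

#' Offset of maximum correlation, as a signed rotation
#' @param xc output of [circular_xcorr()]
#' @return signed rotation in `(-180, 180]` degrees
#' @export
xcorr_peak_offset <- function(xc) {
  off <- as.numeric(names(xc))
  circ_diff_deg(off[which.max(xc)], 0)
}

#' Cross-validated tuning-curve auto- or cross-correlogram
#'
#' The two curves are computed from interleaved halves of the epoch (first
#' half vs second half of the filtered time) so that noise is independent
#' between them; for a single unit this gives the cross-validated
#' auto-correlogram.
#'
#' @param spikes_a,spikes_b spike trains; `spikes_b` defaults to `spikes_a`
#'   (auto mode)
#' @inheritParams compute_tuning_curve
#' @return correlogram as in [circular_xcorr()]
#' @export
cv_tuning_xcorr <- function(spikes_a, trajectory, spikes_b = NULL, epoch = NULL,
                            bin_deg = 1, smooth_sd_deg = 3, speed_min_cms = 2) {
  if (is.null(spikes_b)) spikes_b <- spikes_a
  ep <- as_epoch_matrix(epoch)
  if (is.null(ep)) ep <- matrix(range(trajectory$t) + c(0, 1e-9), ncol = 2)
  # split each epoch interval at its midpoint
  half1 <- cbind(ep[, 1], (ep[, 1] + ep[, 2]) / 2)
  half2 <- cbind((ep[, 1] + ep[, 2]) / 2, ep[, 2])
  ca <- compute_tuning_curve(spikes_a, trajectory, half1, bin_deg,
                             smooth_sd_deg, speed_min_cms)
  cb <- compute_tuning_curve(spikes_b, trajectory, half2, bin_deg,
                             smooth_sd_deg, speed_min_cms)
  circular_xcorr(ca, cb)
}

#' Full width at half maximum of a circular tuning curve
#'
#' The half-maximum level is halfway between the curve's minimum and
#' maximum; the width is measured circularly around the peak with linear
#' interpolation between bins. Undefined (NaN) for a flat curve.
#'
#' @param curve a [tuning_curve()] or rate vector
#' @return width in degrees
#' @export
width_fwhm <- function(curve) {
  x <- rates_of(curve)
  n <- length(x)
  bd <- if (inherits(curve, "tuning_curve")) curve$bin_deg else 360 / n
  if (max(x) <= min(x)) return(NaN)
  th <- (max(x) + min(x)) / 2
  pk <- which.max(x)
  walk <- function(dir) {
    d <- 0
    prev <- x[pk]
    for (s in seq_len(n - 1)) {
      i <- ((pk - 1 + dir * s) %% n) + 1
      if (x[i] < th) {
        # linear interpolation between previous (>= th) and current bin
        frac <- (prev - th) / (prev - x[i])
        return((s - 1 + frac) * bd)
      }
      prev <- x[i]
    }
    360
  }
  min(walk(1) + walk(-1), 360)
}

#' Multi-peak score of a tuning curve
#'
#' Mean value of the max-normalized curve at angles outside the primary
#' peak (peak angle +/- the curve width); high values flag secondary
#' receptive fields.
#'
#' @param curve a [tuning_curve()] or rate vector
#' @return score in \[0, 1] (`NaN` for flat curves)
#' @export
multipeak_score <- function(curve) {
  x <- rates_of(curve)
  n <- length(x)
  bd <- if (inherits(curve, "tuning_curve")) curve$bin_deg else 360 / n
  w <- width_fwhm(curve)
  if (!is.finite(w)) return(NaN)
  pk_deg <- (which.max(x) - 1) * bd
  ang <- (seq_len(n) - 1) * bd
  outside <- abs(circ_diff_deg(ang, pk_deg)) > w
  if (!any(outside)) return(0)
  mean(x[outside] / max(x))
}

#' Cluster contamination score from a spike-train auto-correlogram
#'
#' The auto-correlogram is computed over +/-100 ms in 1 ms bins (self-pairs
#' excluded); the score is the ratio between the value of the first positive
#' bin (0-1 ms, i.e. at 0.1 ms resolution of refractoriness) and the highest
#' bin. Scores above 0.2 indicate a noisy cluster.
#'
#' @param spikes sorted spike times (s)
#' @return list: `score`, `noisy` (score > 0.2), `acg` (lag counts)
#' @export
contamination_score <- function(spikes) {
  cc <- crosscorrelogram(spikes, spikes, window_ms = 100, bin_ms = 1,
                         drop_zero = TRUE)
  pos <- cc$lag_ms > 0
  counts <- cc$counts[pos]
  score <- if (max(counts) > 0) counts[1] / max(counts) else NaN
  list(score = score, noisy = is.finite(score) && score > 0.2,
       acg = stats::setNames(cc$counts, cc$lag_ms))
}

#' Common rotation between two environments and corrected curves
#'
#' Computes each cell's tuning rotation between environments via circular
#' cross-correlation, takes the session-wide circular mean over HD cells,
#' and shifts all second-environment curves back by that amount.
#'
#' @param curves_env1,curves_env2 lists of [tuning_curve()]s (or rate
#'   vectors), matched by position
#' @return list: `rotation_deg` (session mean), `per_cell_deg`,
#'   `corrected_env2` (list of back-rotated rate vectors)
#' @export
align_population_rotation <- function(curves_env1, curves_env2) {
  per <- mapply(function(a, b) xcorr_peak_offset(circular_xcorr(a, b)),
                curves_env1, curves_env2)
  rot <- circ_mean_deg(per, na.rm = TRUE)
  n <- length(rates_of(curves_env1[[1]]))
  bd <- 360 / n
  shift_bins <- round(rot / bd)
  corrected <- lapply(curves_env2, function(b) circshift(rates_of(b), -shift_bins))
  list(rotation_deg = rot, per_cell_deg = per, corrected_env2 = corrected)
}
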