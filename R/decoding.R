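# Poisson Bayesian head-direction decoding and the cue-rotation
# realignment analysis.

#' Bayesian HD decoding from population spike counts
#'
#' Under the hypothesis that cells fire as independent Poisson processes
#' with rates given by their baseline tuning curves, the log posterior over
#' direction in each time bin (uniform prior) is
#' `sum_i [ n_i * log(lambda_i(theta)) - tau * lambda_i(theta) ]`. Counts
#' are Gaussian-smoothed in time before decoding, and the resulting
#' non-integer counts enter the same expression. The decoded direction is
#' the posterior argmax.
#'
#' @param spikes_list named list of spike trains (tuned units, >= 2)
#' @param tuning_list list of baseline [tuning_curve()]s (or rate vectors)
#'   matched to `spikes_list`
#' @param epoch `c(start, end)` decoding window (or interval matrix)
#' @param bin_s decoding bin (default 0.05 s)
#' @param smooth_sd_s count smoothing s.d. (default 0.1 s)
#' @param rate_floor_hz floor for zero tuning rates (default 1e-3 Hz)
#' @param trajectory optional trajectory; when given, the signed circular
#'   decoder error against the real HD is attached
#' @return data.frame of class `decoded_series`: `t`, `decoded_deg` and,
#'   with a trajectory, `real_deg` and `error_deg` in `(-180, 180]`
#' @export
bayes_decode <- function(spikes_list, tuning_list, epoch, bin_s = 0.05,
                         smooth_sd_s = 0.1, rate_floor_hz = 1e-3,
                         trajectory = NULL) {
  if (length(spikes_list) < 2) stop("need at least 2 tuned units")
  ep <- as_epoch_matrix(epoch)
  L <- t(vapply(tuning_list, rates_of, numeric(length(rates_of(tuning_list[[1]])))))
  L[L < rate_floor_hz] <- rate_floor_hz
  logL <- log(L)
  pen <- bin_s * colSums(L)
  nb <- ncol(L)
  bd <- 360 / nb
  out <- list()
  for (r in seq_len(nrow(ep))) {
    breaks <- seq(ep[r, 1], ep[r, 2], by = bin_s)
    if (length(breaks) < 2) next
    ctr <- breaks[-length(breaks)] + bin_s / 2
    C <- matrix(vapply(spikes_list, function(s) {
      s <- s[s >= breaks[1] & s < breaks[length(breaks)]]
      cnt <- tabulate(findInterval(s, breaks), nbins = length(breaks) - 1L)
      smooth_linear(cnt, smooth_sd_s / bin_s)
    }, numeric(length(ctr))), nrow = length(ctr))
    lp <- C %*% logL - matrix(pen, nrow(C), nb, byrow = TRUE)
    dec <- (max.col(lp, ties.method = "first") - 1) * bd
    out[[r]] <- data.frame(t = ctr, decoded_deg = dec)
  }
  res <- do.call(rbind, out)
  if (!is.null(trajectory)) {
    idx <- pmax(findInterval(res$t, trajectory$t), 1L)
    res$real_deg <- trajectory$hd[idx]
    res$error_deg <- circ_diff_deg(res$decoded_deg, res$real_deg)
  }
  class(res) <- c("decoded_series", "data.frame")
  res
}

# 4-parameter logistic in time: y = A + (B - A) / (1 + exp(-(t - t0) / s))
sigmoid4 <- function(t, A, B, t0, s) A + (B - A) / (1 + exp(-(t - t0) / s))

fit_sigmoid <- function(t, y, t_range) {
  A0 <- mean(y[t <= stats::quantile(t, 0.1)])
  B0 <- mean(y[t >= stats::quantile(t, 0.9)])
  best <- NULL; best_dev <- Inf
  # multi-start on the midpoint to escape local minima of the LM fit
  for (t0 in stats::quantile(t, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ sigmoid4(t, A, B, t0, s),
                        data = data.frame(t = t, y = y),
                        start = list(A = A0, B = B0, t0 = t0, s = 10),
                        lower = c(-360, -360, t_range[1], 0.05),
                        upper = c(360, 360, t_range[2], diff(t_range)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && stats::deviance(fit) < best_dev) {
      best <- fit; best_dev <- stats::deviance(fit)
    }
  }
  if (is.null(best)) return(NULL)
  as.list(stats::coef(best))
}

#' Cue-rotation realignment analysis
#'
#' For each cue rotation event: the following epoch is excluded when the
#' mean absolute decoder error stays below 45 degrees (no realignment) or
#' when the animal was near-stationary in the preceding epoch (mean speed
#' below 2 cm/s). For included epochs a 4-parameter sigmoid is fitted to the
#' signed decoder error time course; the realignment window is where the
#' normalized sigmoid crosses 0.01 and 0.99. Per-cell tuning is then
#' computed from the end of realignment to the next rotation, each cell's
#' rotation is the peak offset of the cross-correlation between
#' consecutive-epoch curves, and each FS cell's rotation is compared to the
#' mean rotation of HD cells in the same epoch.
#'
#' @param decoded a `decoded_series` with `error_deg` spanning the cue
#'   epochs
#' @param trajectory the session trajectory (for the speed exclusion and the
#'   per-epoch tuning curves)
#' @param spikes_list named list of spike trains (HD and FS cells)
#' @param unit_type character vector (`"hd"` / `"fs"`) matched to
#'   `spikes_list`
#' @param event_t rotation event times (s)
#' @param epoch_s epoch length after each rotation (default 200 s)
#' @param min_error_deg exclusion threshold on mean absolute decoder error
#' @param min_speed_cms exclusion threshold on preceding-epoch mean speed
#' @param bin_deg,smooth_sd_deg tuning parameters for per-epoch curves
#' @return list of class `realignment_result`: `epochs` (data.frame with
#'   exclusion flags, sigmoid parameters, realignment start/end),
#'   `rotations` (per cell x epoch matrix, deg), `pooled_rotation` (one
#'   rotation per cell from tuning pooled across all stable windows at each
#'   of the two alternating cue positions), `hd_pooled_rotation` (circular
#'   mean over HD cells), `fs_hd_diff` (signed FS minus mean-HD rotation per
#'   FS cell and epoch), `fs_minus_hd` (per FS cell: absolute difference
#'   between its pooled rotation and the HD pooled rotation)
#' @export
realignment_analysis <- function(decoded, trajectory, spikes_list, unit_type,
                                 event_t, epoch_s = 200, min_error_deg = 45,
                                 min_speed_cms = 2, bin_deg = 1,
                                 smooth_sd_deg = 3) {
  n_ev <- length(event_t)
  ep_info <- data.frame(event_t = event_t, included = FALSE,
                        mean_abs_error = NA_real_, prev_speed = NA_real_,
                        t0 = NA_real_, s = NA_real_,
                        realign_start = NA_real_, realign_end = NA_real_)
  n_cells <- length(spikes_list)
  rotations <- matrix(NA_real_, n_cells, n_ev,
                      dimnames = list(names(spikes_list), NULL))
  prev_curve_window <- c(max(min(trajectory$t), event_t[1] - epoch_s), event_t[1])
  prev_curves <- lapply(spikes_list, compute_tuning_curve, trajectory,
                        epoch = prev_curve_window, bin_deg = bin_deg,
                        smooth_sd_deg = smooth_sd_deg, speed_min_cms = 0)
  for (k in seq_len(n_ev)) {
    t1 <- event_t[k]
    t2 <- if (k < n_ev) event_t[k + 1] else t1 + epoch_s
    sel <- decoded$t >= t1 & decoded$t < t2
    err <- decoded$error_deg[sel]
    tt <- decoded$t[sel]
    ep_info$mean_abs_error[k] <- mean(abs(err))
    pre <- trajectory$t >= t1 - epoch_s & trajectory$t < t1
    ep_info$prev_speed[k] <- if (is.null(trajectory$speed)) Inf else
      mean(trajectory$speed[pre])
    sf <- fit_sigmoid(tt, err, c(t1, t2))
    excluded <- ep_info$mean_abs_error[k] < min_error_deg ||
      ep_info$prev_speed[k] < min_speed_cms
    if (!is.null(sf)) {
      ep_info$t0[k] <- sf$t0
      ep_info$s[k] <- sf$s
      ep_info$realign_start[k] <- max(t1, sf$t0 - sf$s * log(99))
      ep_info$realign_end[k] <- min(t2, sf$t0 + sf$s * log(99))
      ep_info$included[k] <- !excluded  # non-convergent fits stay excluded
    }
    # stable-part tuning for this epoch, compared to the previous epoch;
    # curves are tracked across every epoch so consecutive comparisons
    # remain valid when intermediate epochs are excluded
    stable_from <- if (!is.na(ep_info$realign_end[k]))
      ep_info$realign_end[k] else t1 + 0.2 * (t2 - t1)
    # keep at least the last 40% of the epoch for the tuning estimate, even
    # when a shallow sigmoid fit stretches the nominal realignment window
    win <- c(min(stable_from, t1 + 0.6 * (t2 - t1)), t2)
    cur <- lapply(spikes_list, compute_tuning_curve, trajectory,
                  epoch = win, bin_deg = bin_deg,
                  smooth_sd_deg = smooth_sd_deg, speed_min_cms = 0)
    rotations[, k] <- vapply(seq_len(n_cells), function(i)
      xcorr_peak_offset(circular_xcorr(prev_curves[[i]], cur[[i]])),
      numeric(1))
    prev_curves <- cur
  }
  is_fs <- unit_type == "fs"
  fs_diff <- matrix(NA_real_, sum(is_fs), n_ev,
                    dimnames = list(names(spikes_list)[is_fs], NULL))
  inc <- which(ep_info$included & colSums(!is.na(rotations)) > 0)
  if (length(inc) > 0 && any(is_fs)) {
    hd_mean <- vapply(inc, function(k)
      circ_mean_deg(rotations[!is_fs, k], na.rm = TRUE), numeric(1))
    fs_diff[, inc] <- t(t(rotations[is_fs, inc, drop = FALSE]) - hd_mean)
    fs_diff[] <- circ_diff_deg(fs_diff, 0)
  }

  # pooled comparison: tuning computed across all stable windows at each of
  # the two alternating cue positions, then a single rotation per cell --
  # much less alias-prone for multipeaked (FS) curves than per-epoch curves
  stable_wins <- cbind(ifelse(is.na(ep_info$realign_end),
                              event_t + 0.6 * epoch_s, ep_info$realign_end),
                       c(event_t[-1], event_t[n_ev] + epoch_s))
  pos_b <- seq(1, n_ev, by = 2)  # cue switches back and forth: odd = rotated
  pos_a <- seq(2, n_ev, by = 2)
  win_a <- rbind(prev_curve_window, stable_wins[pos_a, , drop = FALSE])
  win_b <- stable_wins[pos_b, , drop = FALSE]
  pooled_rot <- vapply(spikes_list, function(s) {
    ca <- compute_tuning_curve(s, trajectory, win_a, bin_deg, smooth_sd_deg,
                               speed_min_cms = 0)
    cb <- compute_tuning_curve(s, trajectory, win_b, bin_deg, smooth_sd_deg,
                               speed_min_cms = 0)
    xcorr_peak_offset(circular_xcorr(ca, cb))
  }, numeric(1))
  hd_pooled <- circ_mean_deg(pooled_rot[!is_fs], na.rm = TRUE)
  fs_minus_hd <- abs(circ_diff_deg(pooled_rot[is_fs], hd_pooled))
  names(fs_minus_hd) <- names(spikes_list)[is_fs]

  structure(list(epochs = ep_info, rotations = rotations,
                 pooled_rotation = pooled_rot, hd_pooled_rotation = hd_pooled,
                 fs_hd_diff = fs_diff, fs_minus_hd = fs_minus_hd),
            class = "realignment_result")
}
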