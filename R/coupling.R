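# Population-rate-conditioned pairwise spike-rate coupling (Poisson GLM)
# and its WAKE/REM conservation analysis.

#' Bin and smooth a spike train into a rate series
#'
#' Counts in `bin_s` bins smoothed with a Gaussian window; the smoothed
#' (non-integer) counts are what the coupling GLM fits.
#'
#' @param spikes spike times (s)
#' @param epoch `c(start, end)` (must span at least `min_s` seconds)
#' @param bin_s bin width (default 0.1 s)
#' @param smooth_sd_s Gaussian s.d. (default 0.1 s)
#' @param min_s minimum epoch length (default 60 s)
#' @return numeric series with attributes `t` (bin centers) and `bin_s`
#' @export
bin_smooth <- function(spikes, epoch, bin_s = 0.1, smooth_sd_s = 0.1,
                       min_s = 60) {
  ep <- as_epoch_matrix(epoch)
  stopifnot(nrow(ep) == 1)
  if (diff(ep[1, ]) < min_s) stop("epoch too short for rate-coupling analysis")
  breaks <- seq(ep[1, 1], ep[1, 2], by = bin_s)
  s <- spikes[spikes >= breaks[1] & spikes < breaks[length(breaks)]]
  cnt <- tabulate(findInterval(s, breaks), nbins = length(breaks) - 1L)
  out <- smooth_linear(cnt, smooth_sd_s / bin_s)
  attr(out, "t") <- breaks[-length(breaks)] + bin_s / 2
  attr(out, "bin_s") <- bin_s
  out
}

#' Population rate series
#'
#' All spike times from all units aggregated and processed exactly like a
#' single train; by linearity it equals the sum of the per-unit series.
#'
#' @param spikes_list named list of spike trains
#' @inheritParams bin_smooth
#' @return series as in [bin_smooth()]
#' @export
population_rate <- function(spikes_list, epoch, bin_s = 0.1,
                            smooth_sd_s = 0.1, min_s = 60) {
  bin_smooth(sort(unlist(spikes_list, use.names = FALSE)), epoch, bin_s,
             smooth_sd_s, min_s)
}

# One Poisson GLM: y ~ 1 + x + pop with log link; smoothed counts may be
# non-integer, which the Poisson deviance accepts (warnings suppressed on
# purpose). Returns c(beta_x, beta_pop, converged).
poisson_beta <- function(y, x, pop) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, x, pop), y,
                                    family = stats::poisson(),
                                    control = list(maxit = 100,
                                                   epsilon = 1e-8))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$boundary ||
      anyNA(fit$coefficients))
    return(c(NA_real_, NA_real_, 0))
  c(fit$coefficients[2], fit$coefficients[3], 1)
}

#' Pairwise spike-rate coupling curve (Poisson GLM)
#'
#' For every time offset, the series of cell A is modeled as Poisson with
#' log rate linear in the offset series of cell B and in the population
#' rate; the coefficient on B is the coupling `beta(offset)` and the
#' coefficient on the population rate is `beta_POP`. Because the procedure
#' is asymmetric it is repeated with A and B swapped and averaged at
#' equivalent offsets. Edge bins with incomplete overlap are dropped;
#' ill-fitted offsets are flagged.
#'
#' @param series_a,series_b rate series from [bin_smooth()] (same epoch)
#' @param pop population rate series (same epoch)
#' @param offsets_s offset grid in seconds (default -10..10 s in 0.1 s
#'   steps, 201 offsets); must be multiples of the bin width and include 0
#' @return object of class `coupling_curve`: `offsets_s`, `beta`
#'   (symmetrized), `beta_a_on_b`, `beta_b_on_a`, `beta_pop` (at zero
#'   offset, averaged over directions), `ok` (all offsets converged)
#' @export
pair_coupling <- function(series_a, series_b, pop,
                          offsets_s = seq(-10, 10, by = 0.1)) {
  bin_s <- attr(series_a, "bin_s")
  stopifnot(length(series_a) == length(series_b),
            length(series_a) == length(pop))
  ks <- round(offsets_s / bin_s)
  n <- length(series_a)
  one_direction <- function(a, b) {
    vapply(ks, function(k) {
      # regress a(t) on b(t - k): positive offset = A lags B
      if (k >= 0) {
        idx_a <- (1 + k):n; idx_b <- 1:(n - k)
      } else {
        idx_a <- 1:(n + k); idx_b <- (1 - k):n
      }
      poisson_beta(a[idx_a], b[idx_b], pop[idx_a])
    }, numeric(3))
  }
  ab <- one_direction(series_a, series_b)
  ba <- one_direction(series_b, series_a)
  # beta_sym(tau) = mean of beta_AB(tau) and beta_BA(-tau)
  rev_idx <- match(-ks, ks)
  beta <- (ab[1, ] + ba[1, rev_idx]) / 2
  ok <- all(ab[3, ] == 1) && all(ba[3, ] == 1)
  z <- which(ks == 0)
  structure(list(offsets_s = offsets_s, beta = beta,
                 beta_a_on_b = ab[1, ], beta_b_on_a = ba[1, ],
                 beta_pop = if (length(z)) (ab[2, z] + ba[2, z]) / 2 else NA,
                 ok = ok),
            class = "coupling_curve")
}

#' @export
print.coupling_curve <- function(x, ...) {
  z <- which(x$offsets_s == 0)
  cat(sprintf("coupling_curve: %d offsets, beta(0) = %.4f, beta_pop = %.4f%s\n",
              length(x$offsets_s),
              if (length(z)) x$beta[z] else NA, x$beta_pop,
              if (x$ok) "" else " [ill-fitted offsets]"))
  invisible(x)
}

#' WAKE/REM conservation of coupling
#'
#' Pearson correlation between WAKE and REM coupling values across pairs,
#' per pair class, either at zero offset or across full curves
#' (concatenated).
#'
#' @param curves_wake,curves_rem lists of `coupling_curve`s for the same
#'   pairs in the two epochs
#' @param pair_class character vector of pair classes (e.g. `"HD:HD"`,
#'   `"FS:FS"`, `"HD:FS"`)
#' @param mode `"zero"` (beta at 0 offset) or `"curve"` (full curves)
#' @return data.frame with `class`, `r`, `n` (NA r for classes with < 3
#'   pairs)
#' @export
wake_rem_conservation <- function(curves_wake, curves_rem, pair_class,
                                  mode = c("zero", "curve")) {
  mode <- match.arg(mode)
  stopifnot(length(curves_wake) == length(curves_rem),
            length(pair_class) == length(curves_wake))
  val <- function(cc) {
    if (mode == "zero") cc$beta[which(cc$offsets_s == 0)] else cc$beta
  }
  out <- lapply(unique(pair_class), function(cl) {
    i <- which(pair_class == cl)
    w <- unlist(lapply(curves_wake[i], val))
    r <- unlist(lapply(curves_rem[i], val))
    fin <- is.finite(w) & is.finite(r)
    data.frame(class = cl,
               r = if (length(i) < 3 || sum(fin) < 3) NA_real_ else
                 stats::cor(w[fin], r[fin]),
               n = length(i))
  })
  do.call(rbind, out)
}
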