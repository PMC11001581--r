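# Ground-truth tuning curve populations: von Mises bumps plus a constant
# baseline, parameterized by full width at half maximum (FWHM).

#' Convert von Mises concentration to tuning-curve FWHM
#'
#' The half-maximum is taken halfway between the minimum and the maximum of
#' the von Mises bump `exp(kappa * (cos(theta) - 1))`, giving
#' `FWHM = 2 * acos(1 + log((1 + exp(-2 kappa)) / 2) / kappa)`.
#'
#' @param kappa concentration parameter (> 0)
#' @return FWHM in degrees
#' @export
vm_fwhm <- function(kappa) {
  stopifnot(all(kappa > 0))
  2 * acos(pmin(1, pmax(-1, 1 + log((1 + exp(-2 * kappa)) / 2) / kappa))) * 180 / pi
}

#' Convert tuning-curve FWHM to von Mises concentration
#' @param fwhm_deg full width at half maximum in degrees; attainable widths
#'   are in (0, 180) because the half-maximum of a von Mises bump sits at
#'   90 degrees in the flat (kappa -> 0) limit
#' @return concentration kappa
#' @export
vm_kappa <- function(fwhm_deg) {
  vapply(fwhm_deg, function(w) {
    if (!is.finite(w) || w <= 0 || w >= 180)
      stop("FWHM is unattainable for a von Mises curve with kappa > 0 ",
           "(attainable range is (0, 180) degrees)")
    stats::uniroot(function(k) vm_fwhm(k) - w,
                   lower = 1e-6, upper = 1e4, tol = 1e-10)$root
  }, numeric(1))
}

#' Evaluate a von Mises tuning curve
#'
#' `rate(theta) = baseline + peak * exp(kappa * (cos(theta - pd) - 1))`,
#' so `peak` is the modulation amplitude above baseline at the preferred
#' direction `pd`.
#'
#' @param theta_deg angles (degrees) at which to evaluate
#' @param pd_deg preferred direction (degrees)
#' @param kappa concentration
#' @param peak peak modulation above baseline (Hz)
#' @param baseline baseline rate (Hz)
#' @return firing rates (Hz)
#' @export
von_mises_curve <- function(theta_deg, pd_deg, kappa, peak, baseline = 0) {
  baseline + peak * exp(kappa * (cos((theta_deg - pd_deg) * pi / 180) - 1))
}

#' Generate a ground-truth population of HD-like tuning curves
#'
#' Von Mises curves with preferred directions uniform on the circle, FWHM
#' drawn uniformly from `width_range_fwhm_deg` and peak/baseline rates drawn
#' uniformly from their ranges. Broader widths emulate thalamic (ADN-like)
#' populations, narrower widths cortical (PoSub-like) populations.
#'
#' @param n number of cells
#' @param width_range_fwhm_deg length-2 FWHM range in degrees, within (0,360)
#' @param peak_rate_range length-2 range of peak modulation (Hz)
#' @param baseline_rate_range length-2 range of baseline rate (Hz)
#' @param bin_deg angular bin width of the returned curves (default 1)
#' @param region region tag stored with the population (metadata only)
#' @param seed integer seed
#' @return object of class `hd_population`: list with `curves` (n x nbins
#'   rate matrix, bins anchored at 0 degrees), `pd_deg`, `kappa`, `fwhm_deg`,
#'   `peak_hz`, `baseline_hz`, `bin_deg`, `region`
#' @export
make_hd_population <- function(n, width_range_fwhm_deg = c(60, 120),
                               peak_rate_range = c(5, 40),
                               baseline_rate_range = c(0.1, 1),
                               bin_deg = 1, region = "PoSub", seed = NULL) {
  if (any(width_range_fwhm_deg <= 0) || any(width_range_fwhm_deg >= 360))
    stop("widths must be in (0, 360) degrees")
  if (!is.null(seed)) set.seed(seed)
  pd <- stats::runif(n, 0, 360)
  fwhm <- stats::runif(n, width_range_fwhm_deg[1], width_range_fwhm_deg[2])
  kappa <- vm_kappa(fwhm)
  peak <- stats::runif(n, peak_rate_range[1], peak_rate_range[2])
  base <- stats::runif(n, baseline_rate_range[1], baseline_rate_range[2])
  theta <- seq(0, 360 - bin_deg, by = bin_deg)
  curves <- t(vapply(seq_len(n), function(i)
    von_mises_curve(theta, pd[i], kappa[i], peak[i], base[i]),
    numeric(length(theta))))
  structure(list(curves = curves, pd_deg = pd, kappa = kappa, fwhm_deg = fwhm,
                 peak_hz = peak, baseline_hz = base, bin_deg = bin_deg,
                 region = region),
            class = "hd_population")
}

#' @export
print.hd_population <- function(x, ...) {
  cat(sprintf("hd_population: %d cells (%s), FWHM %.0f-%.0f deg, %g deg bins\n",
              nrow(x$curves), x$region, min(x$fwhm_deg), max(x$fwhm_deg),
              x$bin_deg))
  invisible(x)
}
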