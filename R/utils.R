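# Circular helpers and smoothing kernels shared across the package.
# Angles are degrees throughout; yaw in a fixed world frame.

#' Wrap angles to \[0, 360)
#' @param x angles in degrees
#' @return wrapped angles
#' @export
wrap_deg <- function(x) x %% 360

#' Signed smallest circular difference in degrees
#'
#' Returns `a - b` mapped to `(-180, 180]`.
#' @param a,b angles in degrees
#' @return signed differences
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular mean of angles in degrees
#' @param x angles in degrees
#' @param na.rm drop missing values
#' @return circular mean in `(-180, 180]` (or `NaN` if undefined)
#' @export
circ_mean_deg <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' Circular variance of angles in degrees
#'
#' `1 - R` where `R` is the mean resultant length; 0 for concentrated,
#' 1 for uniform samples.
#' @param x angles in degrees
#' @param na.rm drop missing values
#' @return circular variance in \[0, 1]
#' @export
circ_var_deg <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  r <- x * pi / 180
  1 - sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

# Circular correlation between two angle series (Fisher & Lee form,
# rho = sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) normalized), computed in
# O(n) via product-sum identities. Invariant to rotations of either series
# and well-defined for uniform marginals (where mean-direction-based
# variants are not); reflections flip the sign.
#' Circular correlation coefficient between two angle series
#' @param a,b angle series in degrees, equal length
#' @return correlation in \[-1, 1]
#' @export
circ_cor_deg <- function(a, b) {
  a <- a * pi / 180; b <- b * pi / 180
  n <- length(a)
  sa <- sin(a); ca <- cos(a); sb <- sin(b); cb <- cos(b)
  num <- sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb)
  den_a <- (n^2 - Mod(sum(exp(2i * a)))^2) / 2
  den_b <- (n^2 - Mod(sum(exp(2i * b)))^2) / 2
  2 * num / sqrt(den_a * den_b)
}

# Discrete Gaussian kernel truncated at +/- 4 s.d., normalized to sum 1.
gauss_kernel <- function(sd_bins) {
  if (sd_bins <= 0) return(1)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k / sum(k)
}

# Wrap-around (circular) convolution with a Gaussian kernel.
# Conserves sum(x) exactly because the kernel sums to 1.
smooth_circular <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  k <- gauss_kernel(sd_bins)
  if (length(k) >= length(x)) {
    # very wide kernel relative to the circle: fold it onto the circle
    n <- length(x)
    half <- (length(k) - 1L) / 2L
    idx <- ((seq_along(k) - half - 1L) %% n) + 1L
    kk <- as.numeric(tapply(k, idx, sum))
    ord <- sort(unique(idx))
    kfold <- numeric(n); kfold[ord] <- kk
    return(Re(stats::fft(stats::fft(x) * stats::fft(kfold), inverse = TRUE)) / n)
  }
  as.numeric(stats::filter(x, k, method = "convolution", sides = 2, circular = TRUE))
}

# Open (non-circular) Gaussian smoothing for time series; edge bins are
# renormalized by the in-range kernel mass so total mass is conserved.
smooth_linear <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  k <- gauss_kernel(sd_bins)
  n <- length(x)
  half <- (length(k) - 1L) / 2L
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  out <- (num / den)[(half + 1L):(half + n)]
  # FFT-based convolution leaves ~1e-17 negatives on non-negative input
  if (min(x) >= 0) out <- pmax(out, 0)
  out
}

# Deterministic substream seeds: each named stage of a generator consumes
# its own seed derived from the master seed (kept below 2^31).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) + 1000003L * (h %% 2017L)) %% .Machine$integer.max
}

# Rotate a circular vector forward by k bins: y[i] = x[i - k].
circshift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
}
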