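# Shared small fixtures, built once per test run.

# a 5-minute wake session with strongly tuned HD cells and a few FS cells
fixture_session <- local({
  ses <- NULL
  function() {
    if (is.null(ses))
      ses <<- simulate_session(session_config(
        duration_s = 300,
        hd = list(n = 12, peak_rate_range = c(10, 40)),
        fs = list(n = 3, n_inputs = 6),
        seed = 424242))
    ses
  }
})

# dense von Mises curve on 1-degree bins
vm_vec <- function(pd, kappa, peak = 10, baseline = 0, n = 360) {
  von_mises_curve((0:(n - 1)) * 360 / n, pd, kappa, peak, baseline)
}

# Rayleigh test p-value for uniformity of angles (deg)
rayleigh_p <- function(deg) {
  r <- deg * pi / 180
  n <- length(r)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# mean silhouette width for a labeled embedding (Euclidean)
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  s <- vapply(seq_len(nrow(coords)), function(i) {
    a <- mean(d[i, labels == labels[i] & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
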