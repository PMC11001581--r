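#' Generate a random-walk head-direction trajectory
#'
#' Emulates open-field exploration: head direction follows wrapped Brownian
#' motion and running speed follows a log-normal marginal with
#' Ornstein-Uhlenbeck temporal correlation, so that a speed threshold
#' (typically 2 cm/s) removes a controllable fraction of samples.
#'
#' @param duration_s session duration in seconds (> 0)
#' @param angular_diffusion diffusion constant of head direction in deg^2/s:
#'   the variance of angular increments grows as `angular_diffusion * tau`
#' @param dt_s sampling step in seconds (default 0.01)
#' @param speed_log_mean,speed_log_sd mean and s.d. of log speed (log cm/s);
#'   defaults give a median speed of ~8 cm/s with roughly 10-15% of samples
#'   below 2 cm/s
#' @param speed_tau_s OU correlation time of the latent log-speed process
#' @param hd0 initial head direction in degrees (default random)
#' @param seed integer seed; the generator is fully deterministic given
#'   `seed` and the configuration
#' @return a `data.frame` of class `trajectory` with columns `t` (s),
#'   `hd` (degrees in \[0,360)) and `speed` (cm/s)
#' @examples
#' tr <- generate_trajectory(60, angular_diffusion = 200, seed = 1)
#' range(tr$hd)
#' @export
generate_trajectory <- function(duration_s, angular_diffusion = 200, dt_s = 0.01,
                                speed_log_mean = log(8), speed_log_sd = 0.7,
                                speed_tau_s = 1, hd0 = NULL, seed = NULL) {
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(dt_s, "dt_s")
  if (angular_diffusion < 0) stop("`angular_diffusion` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_s / dt_s)
  t <- (seq_len(n) - 1L) * dt_s
  if (is.null(hd0)) hd0 <- stats::runif(1, 0, 360)
  inc <- if (angular_diffusion > 0)
    stats::rnorm(n - 1L, 0, sqrt(angular_diffusion * dt_s)) else numeric(n - 1L)
  hd <- wrap_deg(hd0 + c(0, cumsum(inc)))
  # OU process in log-speed space, stationary initialization
  rho <- exp(-dt_s / speed_tau_s)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) {
    eps <- stats::rnorm(n - 1L, 0, sqrt(1 - rho^2))
    for (i in 2:n) z[i] <- rho * z[i - 1L] + eps[i - 1L]
  }
  speed <- exp(speed_log_mean + speed_log_sd * z)
  structure(data.frame(t = t, hd = hd, speed = speed),
            class = c("trajectory", "data.frame"))
}

#' Generate a drifting latent head-direction series
#'
#' Wrapped Brownian motion with its own diffusion constant, used as the
#' internally generated virtual head direction that drives spiking during
#' REM sleep epochs.
#'
#' @param duration_s duration in seconds
#' @param diffusion diffusion constant in deg^2/s
#' @param dt_s sampling step (s)
#' @param hd0 initial angle (default random)
#' @param seed integer seed
#' @return `data.frame` with columns `t`, `hd`
#' @export
generate_latent_hd <- function(duration_s, diffusion = 400, dt_s = 0.01,
                               hd0 = NULL, seed = NULL) {
  tr <- generate_trajectory(duration_s, angular_diffusion = diffusion, dt_s = dt_s,
                            hd0 = hd0, seed = seed)
  data.frame(t = tr$t, hd = tr$hd)
}
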