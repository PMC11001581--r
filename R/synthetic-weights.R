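# Synaptic weight draws parameterized by their natural-scale mean and
# coefficient of variation (CV = sd/mean), for several families. The CV is
# the dispersion parameter that governs the emergence of radial symmetries
# in randomly connected outputs.

#' Draw non-negative synaptic weights with given mean and CV
#'
#' Families are parameterized so that the natural-scale mean and CV of the
#' distribution match the request exactly (log-normal, gamma, uniform) or by
#' numeric moment matching (truncated Gaussian). `cv = 0` returns constant
#' weights equal to `mean`.
#'
#' @param n number of draws
#' @param family one of `"lognormal"`, `"gamma"`, `"uniform"`,
#'   `"gaussian-truncated"`
#' @param mean target mean (> 0)
#' @param cv target coefficient of variation (>= 0); the uniform family can
#'   only reach `cv <= 1/sqrt(3)` with non-negative support
#' @param seed optional integer seed
#' @return numeric vector of non-negative weights
#' @export
draw_weights <- function(n, family = c("lognormal", "gamma", "uniform",
                                       "gaussian-truncated"),
                         mean = 1, cv = 1, seed = NULL) {
  family <- match.arg(family)
  if (mean <= 0) stop("`mean` must be > 0")
  if (cv < 0) stop("`cv` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (cv == 0) return(rep(mean, n))
  switch(family,
    lognormal = {
      sigma2 <- log(1 + cv^2)
      mu <- log(mean) - sigma2 / 2
      stats::rlnorm(n, mu, sqrt(sigma2))
    },
    gamma = {
      shape <- 1 / cv^2
      stats::rgamma(n, shape = shape, scale = mean * cv^2)
    },
    uniform = {
      s <- mean * cv
      a <- mean - sqrt(3) * s
      if (a < 0) stop("uniform family cannot reach cv > 1/sqrt(3) with non-negative weights")
      stats::runif(n, a, mean + sqrt(3) * s)
    },
    `gaussian-truncated` = {
      # a zero-truncated Gaussian cannot exceed CV ~1 (the exponential-tail
      # limit); keep requests in the comfortably attainable range
      if (cv > 0.9)
        stop("gaussian-truncated family cannot reach cv > 0.9")
      par <- trunc_gauss_params(mean, cv)
      q <- stats::runif(n, stats::pnorm(0, par[1], par[2]), 1)
      stats::qnorm(q, par[1], par[2])
    })
}

# Solve for the (mu, sigma) of a Gaussian truncated at zero whose truncated
# mean and CV match the request; numeric because the truncated moments have
# no closed-form inverse.
trunc_gauss_params <- function(mean, cv) {
  target_sd <- mean * cv
  obj <- function(p) {
    mu <- p[1]; sigma <- exp(p[2])
    alpha <- -mu / sigma
    lam <- stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + alpha * lam - lam^2)
    (m - mean)^2 + (sqrt(max(v, 0)) - target_sd)^2
  }
  fit <- stats::optim(c(mean, log(target_sd + 1e-9)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  c(fit$par[1], exp(fit$par[2]))
}

#' Build ground-truth fast-spiking tuning curves as random linear mixtures
#'
#' Each FS output curve is a weighted sum of input HD tuning curves with
#' weights drawn independently from the requested family; each output
#' selects `n_inputs` of the available inputs at random (all of them by
#' default). The returned curves equal `W %*% inputs` exactly.
#'
#' @param hd_pop an `hd_population` (or a numeric matrix of input curves,
#'   cells in rows)
#' @param n_fs number of FS outputs
#' @param weight_family,weight_mean,weight_cv passed to [draw_weights()]
#' @param n_inputs number of inputs per output (default all)
#' @param seed integer seed
#' @return list with `curves` (n_fs x nbins), `weights` (n_fs x n_in, zero
#'   where unconnected), `family`, `mean`, `cv`, `n_inputs`
#' @export
make_fs_ground_truth <- function(hd_pop, n_fs, weight_family = "lognormal",
                                 weight_mean = 1, weight_cv = 2,
                                 n_inputs = NULL, seed = NULL) {
  inputs <- if (inherits(hd_pop, "hd_population")) hd_pop$curves else hd_pop
  n_in <- nrow(inputs)
  if (is.null(n_inputs)) n_inputs <- n_in
  if (n_inputs < 1 || n_inputs > n_in) stop("`n_inputs` out of range")
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n_fs, n_in)
  for (i in seq_len(n_fs)) {
    sel <- if (n_inputs == n_in) seq_len(n_in) else
      sample.int(n_in, n_inputs)
    W[i, sel] <- draw_weights(n_inputs, weight_family, weight_mean, weight_cv)
  }
  list(curves = W %*% inputs, weights = W, family = weight_family,
       mean = weight_mean, cv = weight_cv, n_inputs = n_inputs)
}
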