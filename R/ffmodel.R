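# Random feed-forward linear-integration model: output units integrate
# HD-tuned inputs through random non-negative weights (no rectification is
# needed in the linear regime since weights and rates are non-negative).
# The dispersion (CV) of the weights governs which radial symmetries
# dominate the outputs; the number of inputs governs how much HD
# information survives the mixing.

#' Simulate output tuning curves from random feed-forward connectivity
#'
#' Outputs are pure linear combinations `W %*% inputs` of the input tuning
#' curves, with each row of `W` drawn independently from the requested
#' weight family (optionally over a random subset of `n_inputs` inputs).
#'
#' @param input_curves matrix of input tuning curves (cells x bins) or an
#'   `hd_population`
#' @param n_outputs number of output units
#' @param family,mean,cv weight distribution (see [draw_weights()])
#' @param n_inputs inputs per output (default: all)
#' @param seed integer seed
#' @param n_keep harmonics kept in the signatures
#' @return list: `curves` (outputs x bins), `weights`, `signatures` (list of
#'   [fourier_signature()]s)
#' @export
simulate_outputs <- function(input_curves, n_outputs, family = "lognormal",
                             mean = 1, cv = 1, n_inputs = NULL, seed = NULL,
                             n_keep = 10) {
  gt <- make_fs_ground_truth(input_curves, n_outputs, family, mean, cv,
                             n_inputs, seed = seed)
  sigs <- lapply(seq_len(n_outputs), function(i)
    fourier_signature(gt$curves[i, ], n_keep = n_keep))
  list(curves = gt$curves, weights = gt$weights, signatures = sigs)
}

#' Symmetry-class proportions as a function of weight dispersion
#'
#' For each CV on the grid, repeats the random mixing `n_runs` times and
#' reports the mean and s.d. (over runs) of the proportion of outputs whose
#' dominant Fourier component is k = 1, 2 or 3. Proportions plateau once
#' the weight s.d. exceeds the mean (CV > 1), independently of the weight
#' family and of the weight mean.
#'
#' @param input_curves input tuning matrix or `hd_population`
#' @param cv_grid CVs to sweep (should straddle 1)
#' @param family weight family
#' @param n_outputs outputs per run
#' @param n_inputs inputs per output (default all)
#' @param n_runs independent repeats per CV (default 30)
#' @param mean weight mean (proportions are scale-invariant)
#' @param classes dominant components reported (default 1:3)
#' @param seed integer seed
#' @return data.frame: `cv`, `class`, `prop_mean`, `prop_sd`
#' @export
symmetry_proportions <- function(input_curves, cv_grid = c(0.25, 0.5, 1, 2, 4),
                                 family = "lognormal", n_outputs = 200,
                                 n_inputs = NULL, n_runs = 30, mean = 1,
                                 classes = 1:3, seed = 1) {
  inputs <- if (inherits(input_curves, "hd_population")) input_curves$curves
  else input_curves
  res <- list()
  for (cv in cv_grid) {
    props <- matrix(0, n_runs, length(classes))
    for (r in seq_len(n_runs)) {
      sim <- simulate_outputs(inputs, n_outputs, family, mean, cv, n_inputs,
                              seed = substream_seed(seed,
                                                    sprintf("%s_%g_%d",
                                                            family, cv, r)))
      dom <- vapply(sim$signatures, dominant_component, integer(1))
      props[r, ] <- vapply(classes, function(k) mean(dom == k, na.rm = TRUE),
                           numeric(1))
    }
    res[[length(res) + 1L]] <- data.frame(
      cv = cv, class = classes,
      prop_mean = colMeans(props),
      prop_sd = apply(props, 2, stats::sd))
  }
  do.call(rbind, res)
}

#' HD information of outputs as a function of input count
#'
#' Sweeps the number of inputs per output at fixed weight CV and reports the
#' distribution of output HD information (bits/spike, computed on the
#' noiseless output curves with uniform occupancy). Information decreases
#' with the number of inputs: averaging many tuned inputs converges to the
#' population-mean curve.
#'
#' @param input_curves input tuning matrix or `hd_population`
#' @param n_inputs_grid input counts to sweep (>= 3 values recommended)
#' @param cv weight CV (fixed)
#' @param family weight family
#' @param n_outputs outputs per condition
#' @param seed integer seed
#' @return data.frame: `n_inputs`, `info_median`, `info_q25`, `info_q75`
#' @export
info_vs_inputs <- function(input_curves, n_inputs_grid = c(1, 5, 20, 80),
                           cv = 1, family = "lognormal", n_outputs = 200,
                           seed = 1) {
  inputs <- if (inherits(input_curves, "hd_population")) input_curves$curves
  else input_curves
  res <- lapply(n_inputs_grid, function(ni) {
    sim <- simulate_outputs(inputs, n_outputs, family, 1, cv, n_inputs = ni,
                            seed = substream_seed(seed, paste0("ni", ni)))
    info <- apply(sim$curves, 1, function(x)
      hd_information(tuning_curve(x))$info_bits_per_spike)
    q <- stats::quantile(info, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(n_inputs = ni, info_median = q[2], info_q25 = q[1],
               info_q75 = q[3])
  })
  do.call(rbind, res)
}

# --- two-pathway fit ---------------------------------------------------

#' Target statistics of an output (FS-like) population
#'
#' The three constraint groups of the two-pathway fit: mean firing rate
#' across cells, variance of firing rates across cells, and the variances
#' (across cells) of the first `n_keep` Fourier powers.
#'
#' @param curves output tuning matrix (cells x bins)
#' @param n_keep harmonics (default 10)
#' @return list: `rate_mean`, `rate_var`, `fourier_var` (length `n_keep`)
#' @export
fs_target_stats <- function(curves, n_keep = 10) {
  rates <- rowMeans(curves)
  P <- t(apply(curves, 1, function(x)
    fourier_signature(x, n_keep)$power[seq_len(n_keep)]))
  list(rate_mean = mean(rates), rate_var = stats::var(rates),
       fourier_var = apply(P, 2, stats::var))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))

# Shared machinery of the two-pathway model: batched common-random-number
# draws of log-normal weights and the summary statistics of the simulated
# outputs. Averaging the statistics over `n_batch` weight batches tames
# their heavy-tailed sampling noise at fixed n_outputs.
pathway_stats_fn <- function(adn_curves, posub_curves, n_outputs, seed,
                             n_keep = 10, n_batch = 4L) {
  n_a <- nrow(adn_curves); n_p <- nrow(posub_curves)
  set.seed(seed)
  Za <- lapply(seq_len(n_batch), function(b)
    matrix(stats::rnorm(n_outputs * n_a), n_outputs, n_a))
  Zp <- lapply(seq_len(n_batch), function(b)
    matrix(stats::rnorm(n_outputs * n_p), n_outputs, n_p))
  nb <- ncol(adn_curves)
  inputs <- rbind(adn_curves, posub_curves)
  # the DFT is linear in the weights: precompute per-input Fourier
  # coefficients once and mix those, instead of transforming every
  # simulated output curve
  Fin <- stats::mvfft(t(inputs))[1 + seq_len(n_keep), , drop = FALSE] / nb
  FinRe <- t(Re(Fin)); FinIm <- t(Im(Fin))  # n_in x n_keep
  m_in <- rowMeans(inputs)
  lognorm_w <- function(Z, m, s) {
    sigma2 <- log(1 + (s / m)^2)
    exp(log(m) - sigma2 / 2 + sqrt(sigma2) * Z)
  }
  col_var <- function(M) (colSums(M^2) - colSums(M)^2 / nrow(M)) /
    (nrow(M) - 1)
  function(par) {
    rm_ <- rv <- 0; fv <- numeric(n_keep)
    for (b in seq_len(n_batch)) {
      W <- cbind(lognorm_w(Za[[b]], par[1], par[2]),
                 lognorm_w(Zp[[b]], par[3], par[4]))
      r <- as.numeric(W %*% m_in)
      P <- sqrt(2) * sqrt((W %*% FinRe)^2 + (W %*% FinIm)^2)
      rm_ <- rm_ + mean(r); rv <- rv + stats::var(r)
      fv <- fv + col_var(P)
    }
    list(rate_mean = rm_ / n_batch, rate_var = rv / n_batch,
         fourier_var = fv / n_batch)
  }
}

#' Simulated two-pathway output statistics at given weight parameters
#'
#' Generates random two-pathway outputs (log-normal weights with the given
#' per-pathway mean and s.d.) and returns the same statistic set that
#' [fit_two_pathway()] matches. Useful for building targets for parameter
#' recovery.
#'
#' @param adn_curves,posub_curves input tuning matrices
#' @param par numeric `(mean_adn, sd_adn, mean_posub, sd_posub)`
#' @param n_outputs simulated output count per batch (default 500)
#' @param seed integer seed
#' @return list as in [fs_target_stats()]
#' @export
simulate_pathway_stats <- function(adn_curves, posub_curves, par,
                                   n_outputs = 500, seed = 1) {
  pathway_stats_fn(adn_curves, posub_curves, n_outputs, seed)(par)
}

#' Fit a two-pathway random-connectivity model by gradient descent
#'
#' Output units receive two input pathways (thalamic / ADN-like, broadly
#' tuned; cortical / PoSub-like, sharply tuned) through log-normal weights.
#' The four parameters (weight mean and s.d. per pathway, kept positive via
#' a softplus reparameterization) are optimized by finite-difference
#' gradient descent with backtracking so that the simulated outputs match
#' the target statistics under three constraint groups: (1) mean firing
#' rate, (2) variance of firing rates, (3) variances of the Fourier
#' coefficients. Groups are weighted equally after scaling each term by its
#' target magnitude. Weights are re-drawn per evaluation from common random
#' numbers (fixed standard-normal draws scaled by the current parameters)
#' to stabilize the gradients.
#'
#' @param targets target statistics from [fs_target_stats()]
#' @param adn_curves,posub_curves input tuning matrices for the two pathways
#'   (cells x bins)
#' @param n_outputs simulated output units per evaluation (default 500)
#' @param init starting values `(mean_adn, sd_adn, mean_posub, sd_posub)`,
#'   or a list of several such vectors: the descent is run from each start
#'   and the best final loss wins (the loss surface has long curved valleys)
#' @param max_iter gradient-descent iterations (default 200)
#' @param step initial step size on the unconstrained scale
#' @param seed integer seed for the common random numbers
#' @return object of class `two_pathway_fit`: `par` (natural-scale
#'   parameters), `cv` (per-pathway CV), `loss_trace` (non-increasing over
#'   accepted steps), `converged`, plus `decompose(fit)`-ready inputs
#' @export
fit_two_pathway <- function(targets, adn_curves, posub_curves,
                            n_outputs = 500, init = NULL,
                            max_iter = 200, step = 0.1, seed = 1) {
  if (is.null(init))
    init <- list(c(mean_adn = 0.02, sd_adn = 0.02,
                   mean_posub = 0.02, sd_posub = 0.02),
                 c(mean_adn = 0.03, sd_adn = 0.01,
                   mean_posub = 0.015, sd_posub = 0.04),
                 c(mean_adn = 0.01, sd_adn = 0.025,
                   mean_posub = 0.04, sd_posub = 0.015))
  if (!is.list(init)) init <- list(init)
  n_keep <- length(targets$fourier_var)
  sim_stats <- pathway_stats_fn(adn_curves, posub_curves, n_outputs, seed,
                                n_keep = n_keep)
  loss_of <- function(raw) {
    par <- softplus(raw)
    s <- sim_stats(par)
    l1 <- ((s$rate_mean - targets$rate_mean) / targets$rate_mean)^2
    l2 <- ((s$rate_var - targets$rate_var) / targets$rate_var)^2
    l3 <- mean(((s$fourier_var - targets$fourier_var) /
                  pmax(targets$fourier_var, 1e-12))^2)
    l1 + l2 + l3
  }
  descend <- function(init_par, step) {
  raw <- inv_softplus(pmax(init_par, 1e-6))
  cur <- loss_of(raw)
  trace <- cur
  h <- 1e-3
  step0 <- step
  fails <- 0
  for (it in seq_len(max_iter)) {
    g <- vapply(1:4, function(j) {
      e <- numeric(4); e[j] <- h
      (loss_of(raw + e) - loss_of(raw - e)) / (2 * h)
    }, numeric(1))
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-12) break
    accepted <- FALSE
    st <- step / max(gn, 1e-8)  # scale so the first trial moves ~`step`
    for (bt in 1:20) {  # backtracking: halve the step until loss decreases
      cand <- raw - st * g
      l <- loss_of(cand)
      if (is.finite(l) && l < cur) {
        raw <- cand; cur <- l; accepted <- TRUE
        step <- min(st * max(gn, 1e-8) * 2, 16 * step0)  # re-expand
        break
      }
      st <- st / 2
    }
    trace <- c(trace, cur)
    if (!accepted) {
      fails <- fails + 1
      step <- step / 2
      if (fails >= 4) {
        if (h > 2e-5) {  # finite-difference error dominates: refine h
          h <- h / 10
          step <- step0
          fails <- 0
        } else break  # step and difference width exhausted: stop
      }
    } else fails <- 0
    if (cur < 1e-12) break
  }
  list(raw = raw, loss = cur, trace = trace, fails = fails)
  }
  best <- NULL
  for (ip in init) {
    run <- descend(ip, step)
    if (is.null(best) || run$loss < best$loss) best <- run
    if (best$loss < 1e-12) break
  }
  raw <- best$raw; cur <- best$loss; trace <- best$trace
  # derivative-free simplex refinement: the loss surface has long, curved
  # valleys where fixed-step gradient descent stalls well short of the
  # minimum; a Nelder-Mead polish from the descent's end point (and from
  # the first start, in case the descent left the right basin) closes the
  # remaining gap
  for (start_raw in list(raw, inv_softplus(pmax(init[[1]], 1e-6)))) {
    nm <- stats::optim(start_raw, loss_of, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    if (is.finite(nm$value) && nm$value < cur) {
      raw <- nm$par; cur <- nm$value
      trace <- c(trace, cur)
    }
  }
  par <- softplus(raw)
  names(par) <- c("mean_adn", "sd_adn", "mean_posub", "sd_posub")
  structure(list(par = par,
                 cv = c(adn = par[["sd_adn"]] / par[["mean_adn"]],
                        posub = par[["sd_posub"]] / par[["mean_posub"]]),
                 loss_trace = trace, loss = cur,
                 converged = is.finite(cur) && cur < trace[1],
                 adn_curves = adn_curves, posub_curves = posub_curves,
                 n_outputs = n_outputs, seed = seed),
            class = "two_pathway_fit")
}

#' @export
print.two_pathway_fit <- function(x, ...) {
  cat(sprintf(paste0("two_pathway_fit: loss %.4g after %d steps\n",
                     "  ADN   mean %.4g sd %.4g (CV %.2f)\n",
                     "  PoSub mean %.4g sd %.4g (CV %.2f)\n"),
              x$loss, length(x$loss_trace) - 1,
              x$par["mean_adn"], x$par["sd_adn"], x$cv["adn"],
              x$par["mean_posub"], x$par["sd_posub"], x$cv["posub"]))
  invisible(x)
}

#' @export
coef.two_pathway_fit <- function(object, ...) object$par

#' Decompose fitted outputs into per-pathway contributions
#'
#' Re-simulates outputs at the fitted parameters and splits each output
#' curve into its ADN part and PoSub part. The modulation depth
#' `(max - min) / (max + min)` of each contribution quantifies its tuning;
#' a flat (high-rate, untuned) ADN contribution next to an HD-modulated
#' PoSub contribution is the fitted regime for FS-like targets built from
#' broad ADN and narrow PoSub inputs.
#'
#' @param fit a `two_pathway_fit`
#' @param n_outputs outputs to simulate (default: as fitted)
#' @param seed seed (default: as fitted)
#' @return list: `adn_part`, `posub_part` (outputs x bins), `depth_adn`,
#'   `depth_posub` (per-output modulation depths)
#' @export
decompose_contributions <- function(fit, n_outputs = fit$n_outputs,
                                    seed = fit$seed) {
  set.seed(seed)
  n_a <- nrow(fit$adn_curves); n_p <- nrow(fit$posub_curves)
  Za <- matrix(stats::rnorm(n_outputs * n_a), n_outputs, n_a)
  Zp <- matrix(stats::rnorm(n_outputs * n_p), n_outputs, n_p)
  lw <- function(Z, m, s) {
    sigma2 <- log(1 + (s / m)^2)
    exp(log(m) - sigma2 / 2 + sqrt(sigma2) * Z)
  }
  adn_part <- lw(Za, fit$par["mean_adn"], fit$par["sd_adn"]) %*% fit$adn_curves
  posub_part <- lw(Zp, fit$par["mean_posub"], fit$par["sd_posub"]) %*%
    fit$posub_curves
  depth <- function(m) apply(m, 1, function(x)
    (max(x) - min(x)) / (max(x) + min(x)))
  list(adn_part = adn_part, posub_part = posub_part,
       depth_adn = depth(adn_part), depth_posub = depth(posub_part))
}
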