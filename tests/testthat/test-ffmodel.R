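test_that("degenerate mixing limits behave exactly", {
  pop <- make_hd_population(30, seed = 41)
  sim0 <- simulate_outputs(pop$curves, 10, cv = 0, seed = 42)
  expect_lt(max(abs(sweep(sim0$curves, 2, sim0$curves[1, ]))), 1e-12)
  P <- t(vapply(sim0$signatures, function(s) s$normalized_power, numeric(10)))
  expect_lt(max(apply(P, 2, var)), 1e-20)  # between-output variance 0
  # single-input outputs inherit their input's signature exactly
  sim1 <- simulate_outputs(pop$curves, 10, cv = 1, n_inputs = 1, seed = 43)
  for (i in 1:10) {
    j <- which(sim1$weights[i, ] > 0)
    expect_equal(sim1$signatures[[i]]$normalized_power,
                 fourier_signature(pop$curves[j, ])$normalized_power,
                 tolerance = 1e-9)
  }
})

test_that("outputs lie in the input subspace and scale-invariance holds", {
  pop <- make_hd_population(40, seed = 44)
  sim <- simulate_outputs(pop$curves, 25, cv = 2, seed = 45)
  V <- svd(pop$curves)$v
  resid <- sim$curves - sim$curves %*% V %*% t(V)
  expect_lt(max(abs(resid)) / max(sim$curves), 1e-9)
  # scaling all weights leaves normalized signatures unchanged
  sigs_scaled <- lapply(seq_len(25), function(i)
    fourier_signature(10 * sim$curves[i, ]))
  expect_equal(sigs_scaled[[5]]$normalized_power,
               sim$signatures[[5]]$normalized_power, tolerance = 1e-12)
})

test_that("random mixing preserves the population power spectrum", {
  th <- 0:359
  pds <- (0:149) * 2.4
  curves <- t(vapply(pds, function(p) von_mises_curve(th, p, vm_kappa(90), 20),
                     numeric(360)))
  in_sigs <- lapply(seq_len(150), function(i) fourier_signature(curves[i, ]))
  sim <- simulate_outputs(curves, 500, cv = 2, seed = 46)
  expect_lt(sum(abs(population_power_spectrum(in_sigs) -
                    population_power_spectrum(sim$signatures))), 0.05)
})

test_that("symmetry proportions plateau beyond CV 1 and across families", {
  pop <- make_hd_population(80, seed = 47)
  sp <- symmetry_proportions(pop$curves, cv_grid = c(0.25, 2, 4),
                             n_runs = 8, n_outputs = 150, seed = 48)
  low <- sp[sp$cv == 0.25, ]
  expect_gt(max(low$prop_mean), 0.9)  # low dispersion: one class dominates
  p2 <- sp[sp$cv == 2, "prop_mean"]; p4 <- sp[sp$cv == 4, "prop_mean"]
  expect_lt(max(abs(p2 - p4)), 0.05)
  spg <- symmetry_proportions(pop$curves, cv_grid = 2, family = "gamma",
                              n_runs = 8, n_outputs = 150, seed = 48)
  expect_lt(max(abs(spg$prop_mean - p2)), 0.05)
  # proportions at large cv do not depend on the weight mean
  spm <- symmetry_proportions(pop$curves, cv_grid = 2, n_runs = 8,
                              n_outputs = 150, mean = 17, seed = 48)
  expect_equal(spm$prop_mean, p2, tolerance = 1e-12)
})

test_that("HD information of outputs decreases with the number of inputs", {
  pop <- make_hd_population(80, seed = 49)
  iv <- info_vs_inputs(pop$curves, c(1, 5, 20, 80), cv = 1,
                       n_outputs = 120, seed = 50)
  expect_true(all(diff(iv$info_median) < 0))
  # single input reproduces the input information distribution
  in_info <- apply(pop$curves, 1, function(x)
    hd_information(tuning_curve(x))$info_bits_per_spike)
  expect_gt(iv$info_median[1], quantile(in_info, 0.2))
  expect_lt(iv$info_median[1], quantile(in_info, 0.8))
  # large-input limit approaches the population-mean curve's information
  lim <- hd_information(tuning_curve(colMeans(pop$curves)))$info_bits_per_spike
  expect_lt(abs(iv$info_median[4] - lim), 5 * lim)
})

test_that("two-pathway loss is zero at self-consistent targets", {
  set.seed(51)
  th <- 0:359
  adn <- t(vapply(1:20, function(i)
    von_mises_curve(th, runif(1, 0, 360), vm_kappa(140), 30, 2), numeric(360)))
  pos <- t(vapply(1:40, function(i)
    von_mises_curve(th, runif(1, 0, 360), vm_kappa(80), 15, 0.5), numeric(360)))
  par0 <- c(0.02, 0.02, 0.02, 0.02)
  targets <- simulate_pathway_stats(adn, pos, par0, n_outputs = 100, seed = 7)
  fit <- fit_two_pathway(targets, adn, pos, n_outputs = 100, max_iter = 0,
                         init = par0, seed = 7)
  expect_lt(fit$loss, 1e-18)
})

test_that("two-pathway fit recovers generating parameters", {
  set.seed(52)
  th <- 0:359
  adn <- t(vapply(1:30, function(i)
    von_mises_curve(th, runif(1, 0, 360), vm_kappa(runif(1, 120, 160)),
                    runif(1, 20, 60), 2), numeric(360)))
  pos <- t(vapply(1:60, function(i)
    von_mises_curve(th, runif(1, 0, 360), vm_kappa(runif(1, 60, 100)),
                    runif(1, 5, 40), 0.5), numeric(360)))
  true_par <- c(0.02, 0.01, 0.03, 0.06)  # ADN CV 0.5, PoSub CV 2
  targets <- simulate_pathway_stats(adn, pos, true_par, n_outputs = 300,
                                    seed = 8)
  fit <- fit_two_pathway(targets, adn, pos, n_outputs = 300, max_iter = 400,
                         seed = 8)
  expect_lt(abs(fit$cv["adn"] - 0.5) / 0.5, 0.2)
  expect_lt(abs(fit$cv["posub"] - 2) / 2, 0.2)
  expect_true(all(diff(fit$loss_trace) <= 1e-12))  # non-increasing loss
  # broad-ADN / narrow-PoSub fits give a flat ADN contribution
  dc <- decompose_contributions(fit, n_outputs = 200)
  expect_lt(median(dc$depth_adn) / median(dc$depth_posub), 1)
})
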