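test_that("population vectors have the right bin count and preprocessing", {
  spikes <- list(a = c(0.5, 1.5, 10.2), b = seq(0.05, 19.95, by = 0.1))
  pv <- population_vectors(spikes, c(0, 20), bin_s = 0.2, smooth_sd_s = 0)
  expect_equal(nrow(pv$pv), 100L)
  expect_equal(ncol(pv$pv), 2L)
  # sqrt-transformed counts: unit b fires 2 spikes per 0.2 s bin
  expect_equal(max(abs(pv$pv[, 2] - sqrt(2))), 0, tolerance = 1e-6)
  expect_true(all(pv$pv >= 0))
})

test_that("points on a noisy planar circle embed in their angular order", {
  set.seed(7)
  th <- sort(runif(400, 0, 360))
  X <- cbind(cos(th * pi / 180), sin(th * pi / 180)) +
    matrix(rnorm(800, 0, 0.02), ncol = 2)
  emb <- geodesic_embed(X, k = 12, dims = 2)
  a <- atan2(emb$coords[, 2], emb$coords[, 1]) * 180 / pi
  expect_gt(abs(circ_cor_deg(a, th)), 0.99)
  expect_length(emb$dropped, 0L)
})

test_that("a 1D line embeds preserving order and small inputs are rejected", {
  x <- matrix(seq(0, 10, length.out = 60) + rnorm(60, 0, 0.01), ncol = 1)
  emb <- geodesic_embed(cbind(x, 0 * x), k = 5, dims = 1)
  expect_true(abs(cor(emb$coords[, 1], x[emb$kept])) > 0.999)
  expect_error(geodesic_embed(matrix(rnorm(20), 10), k = 10), "smaller")
})

test_that("duplicate rows are separated deterministically", {
  set.seed(77)
  X <- matrix(rnorm(50), 10, 5)[rep(1:10, each = 6), ]  # duplicate blocks
  e1 <- geodesic_embed(X, k = 8, dims = 2)
  e2 <- geodesic_embed(X, k = 8, dims = 2)
  expect_identical(e1$coords, e2$coords)
})

test_that("tuning auto-correlograms expose the expected symmetries", {
  th <- (0:359) * pi / 180
  ac2 <- circular_xcorr(2 + cos(2 * th), 2 + cos(2 * th))
  peaks2 <- as.numeric(names(ac2))[ac2 > 1 - 1e-9]
  expect_setequal(peaks2, c(0, 180))
  ac3 <- circular_xcorr(2 + cos(3 * th), 2 + cos(3 * th))
  peaks3 <- as.numeric(names(ac3))[ac3 > 1 - 1e-9]
  expect_setequal(peaks3, c(0, 120, 240))
})

test_that("shape space separates onefold/twofold/threefold archetypes", {
  set.seed(8)
  th <- (0:359) * pi / 180
  make_arch <- function(k, n) t(vapply(seq_len(n), function(i) {
    curve <- 2 + cos(k * (th + runif(1, 0, 2 * pi))) + rnorm(360, 0, 0.05)
    unname(circular_xcorr(curve, curve))
  }, numeric(360)))
  ac <- rbind(make_arch(1, 15), make_arch(2, 15), make_arch(3, 15))
  sigs <- lapply(seq_len(45), function(i) {
    k <- c(1, 2, 3)[ceiling(i / 15)]
    fourier_signature(2 + cos(k * th))
  })
  ss <- shape_space(ac, sigs, k = 20)  # k > cluster size keeps the graph connected
  labels <- rep(1:3, each = 15)[ss$kept]
  expect_gt(silhouette_mean(ss$embedding$coords, labels), 0.8)
  # archetype coloring: each cluster dominated by its own component
  for (k in 1:3) {
    expect_true(all(ss$rgb[labels == k, k] > 0.9))
  }
  expect_error(shape_space(matrix(1, 30, 360)), "degenerate")
})

test_that("virtual HD recovers a latent angle and an imposed offset", {
  set.seed(9)
  n_bins <- 1500
  lat <- runif(n_bins, 0, 360)
  lat_tr <- data.frame(t = (seq_len(n_bins) - 1) * 0.2, hd = lat)
  pop <- make_hd_population(60, peak_rate_range = c(20, 60), seed = 10)
  spikes <- lapply(seq_len(60), function(i)
    generate_spikes(pop$curves[i, ], lat_tr, seed = 1000 + i))
  names(spikes) <- sprintf("u%02d", seq_len(60))
  pv <- population_vectors(spikes, c(0, n_bins * 0.2), smooth_sd_s = 0)
  emb <- geodesic_embed(pv$pv, k = 12, dims = 3)
  tt <- pv$t[emb$kept]
  latent <- lat[pmax(findInterval(tt, lat_tr$t), 1)]
  vhd <- virtual_hd(emb, tt, real_hd = latent, hd_spikes = spikes)
  expect_gt(circ_cor_deg(vhd$alpha_deg, latent), 0.98)
  expect_lt(median(abs(circ_diff_deg(vhd$alpha_deg, latent))), 10)
  # radial coordinate is tight for a well-sampled ring
  expect_lt(sd(vhd$d) / mean(vhd$d), 0.15)
  # negating the latent angle flips the chosen orientation
  vhd_neg <- virtual_hd(emb, tt, real_hd = wrap_deg(-latent),
                        hd_spikes = NULL)
  expect_false(identical(vhd$flipped, vhd_neg$flipped))
  # alignment recovers an imposed global offset within +/- 3 degrees
  vhd37 <- virtual_hd(emb, tt, real_hd = wrap_deg(latent + 37),
                      hd_spikes = lapply(spikes, function(s) s))
  expect_lt(abs(circ_mean_deg(circ_diff_deg(vhd37$alpha_deg, latent + 37))), 3)
  # without a reference the angle comes back unaligned and flagged
  raw <- virtual_hd(emb, tt)
  expect_false(raw$aligned)
})

test_that("joint WAKE/REM embedding needs enough REM and matches trivially", {
  spikes <- list(a = sort(runif(500, 0, 100)), b = sort(runif(500, 0, 100)))
  pv <- population_vectors(spikes, c(0, 100))
  short <- list(pv = pv$pv[1:100, ], t = pv$t[1:100], bin_s = 0.2)
  expect_warning(
    expect_null(rem_joint_embedding(pv, list(pv = pv$pv[1:10, ],
                                             t = pv$t[1:10], bin_s = 0.2),
                                    runif(500, 0, 360), spikes)),
    "REM")
})
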