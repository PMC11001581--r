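test_that("tuning curves are occupancy-normalized and conserve mass", {
  # homogeneous train on uniform occupancy -> flat curve at the true rate
  tr <- data.frame(t = seq(0, 359.99, by = 0.01),
                   hd = rep(0:359, each = 100) + 0.5,
                   speed = 5)
  spk <- seq(0.1, 359.9, by = 0.2)  # 5 Hz homogeneous
  tc <- compute_tuning_curve(spk, tr)
  expect_length(tc$rates, 360L)
  expect_lt(max(abs(tc$rates - 5)), 0.6)
  # occupancy conservation after filtering
  expect_equal(sum(tc$occupancy_s), 360, tolerance = 1e-6)
  # smoothing conserves spike mass within 0.1%
  expect_lt(abs(sum(tc$rates * tc$occupancy_s) - length(spk)) / length(spk),
            0.001)
})

test_that("a single spike integrates to one and peaks at its direction", {
  # oracle: unsmoothed histogram + discrete kernel sum
  tr <- data.frame(t = seq(0, 359.99, by = 0.01),
                   hd = rep(0:359, each = 100) + 0.5, speed = 5)
  spk <- tr$t[tr$hd == 90.5][50]
  tc <- compute_tuning_curve(spk, tr, smooth_sd_deg = 3)
  expect_equal(sum(tc$rates * tc$occupancy_s), 1, tolerance = 1e-9)
  expect_equal(which.max(tc$rates) - 1L, 90L)
  raw <- compute_tuning_curve(spk, tr, smooth_sd_deg = 0)
  expect_equal(sum(raw$rates > 0), 1L)
  expect_equal(raw$rates[91], 1 / raw$occupancy_s[91])
})

test_that("speed filtering excludes slow samples and can be disabled", {
  tr <- data.frame(t = seq(0, 99.99, by = 0.01), hd = runif(10000, 0, 360),
                   speed = rep(c(0, 10), each = 5000))
  tc <- compute_tuning_curve(numeric(0), tr, speed_min_cms = 2)
  expect_equal(sum(tc$occupancy_s), 50, tolerance = 1e-6)
  tc0 <- compute_tuning_curve(numeric(0), tr, speed_min_cms = 0)
  expect_equal(sum(tc0$occupancy_s), 100, tolerance = 1e-6)
  expect_error(compute_tuning_curve(numeric(0), tr, epoch = c(0, 49.99)),
               "occupancy")
})

test_that("HD information matches closed-form values and its invariances", {
  expect_equal(hd_information(tuning_curve(rep(4, 360)))$info_bits_per_spike,
               0)
  # two effective bins, p = (1/2, 1/2), rates (2, 0) -> 1 bit/spike
  two <- tuning_curve(c(rep(2, 180), rep(0, 180)))
  expect_equal(hd_information(two)$info_bits_per_spike, 1)
  expect_equal(hd_information(two)$info_bits_per_s, 1)
  x <- vm_vec(120, 3, peak = 8, baseline = 1)
  i1 <- hd_information(tuning_curve(x))
  i10 <- hd_information(tuning_curve(10 * x))
  expect_equal(i1$info_bits_per_spike, i10$info_bits_per_spike,
               tolerance = 1e-12)
  rot <- hd_information(tuning_curve(c(x[101:360], x[1:100])))
  expect_equal(i1$info_bits_per_spike, rot$info_bits_per_spike,
               tolerance = 1e-12)
  expect_true(is.nan(hd_information(tuning_curve(rep(0, 360)))$info_bits_per_spike))
})

test_that("time-reversed control preserves marginals but kills tuning", {
  ses <- fixture_session()
  spk <- ses$spikes[[1]]
  tc <- compute_tuning_curve(spk, ses$trajectory)
  ctrl <- time_reversed_control(spk, ses$trajectory)
  expect_equal(sum(ctrl$curve$occupancy_s), sum(tc$occupancy_s),
               tolerance = 1e-6)
  expect_equal(sum(ctrl$curve$rates * ctrl$curve$occupancy_s),
               sum(tc$rates * tc$occupancy_s), tolerance = 0.02)
  expect_lt(ctrl$info$info_bits_per_spike,
            hd_information(tc)$info_bits_per_spike / 3)
})

test_that("HD classification applies the percentile or the fixed cut", {
  expect_identical(classify_hd(c(0.25, 0.1), fixed_cut = 0.2), c(TRUE, FALSE))
  info <- c(rep(0.05, 50), 1.5)
  ctrl <- runif(51, 0, 0.1)
  set.seed(1)
  flags <- classify_hd(info, ctrl)
  expect_true(flags[51])
  expect_lt(mean(flags[1:50]), 0.5)
  expect_error(classify_hd(1, control = 0.5), "control")
})

test_that("unit classification follows the waveform/rate rule", {
  expect_identical(classify_units(c(25, 3, 25, 3), c(0.2, 0.7, 0.7, 0.3)),
                   c("FS", "excitatory", "unclassified", "unclassified"))
})

test_that("circular cross-correlograms locate rotations", {
  a <- vm_vec(100, 4)
  xc <- circular_xcorr(a, a)
  expect_equal(unname(xc["0"]), 1, tolerance = 1e-12)
  expect_equal(xcorr_peak_offset(xc), 0)
  b90 <- vm_vec(190, 4)  # same shape rotated +90
  expect_equal(xcorr_peak_offset(circular_xcorr(a, b90)), 90)
  # two von Mises 60 degrees apart, kappa = 4 -> argmax 60 +/- 1
  b60 <- vm_vec(160, 4)
  expect_lt(abs(xcorr_peak_offset(circular_xcorr(a, b60)) - 60), 1.01)
  expect_warning(circular_xcorr(rep(1, 360), a), "zero-variance")
})

test_that("cross-validated auto-correlogram of a stationary cell peaks at 0", {
  # a 30-minute session: each epoch half must cover the whole circle
  ses <- simulate_session(session_config(
    duration_s = 1800, hd = list(n = 4, peak_rate_range = c(10, 40)),
    fs = list(n = 1), seed = 31415))
  i <- which.max(ses$ground_truth$hd_pop$peak_hz)
  xc <- cv_tuning_xcorr(ses$spikes[[i]], ses$trajectory)
  expect_equal(xcorr_peak_offset(xc), 0, tolerance = 3)
  expect_gt(max(xc), 0.8)
})

test_that("width, multipeak and contamination metrics behave", {
  # FWHM matches the closed form for known kappa
  for (k in c(1, 3, 8)) {
    expect_lt(abs(width_fwhm(vm_vec(77, k)) - vm_fwhm(k)), 1)
  }
  expect_true(is.nan(width_fwhm(rep(2, 360))))
  expect_lt(multipeak_score(vm_vec(0, 6)), 0.05)
  two_fields <- vm_vec(0, 6) + vm_vec(150, 6, peak = 8)
  expect_gt(multipeak_score(two_fields), 0.15)
  # perfectly refractory train -> contamination 0; flagged above 0.2
  regular <- seq(0, 100, by = 0.05)
  cs <- contamination_score(regular)
  expect_equal(cs$score, 0)
  expect_false(cs$noisy)
  set.seed(2)
  poisson <- sort(runif(5000, 0, 250))  # no refractoriness
  cs2 <- contamination_score(poisson)
  expect_gt(cs2$score, 0.2)
  expect_true(cs2$noisy)
})

test_that("population rotation alignment recovers a common shift", {
  pop <- make_hd_population(15, peak_rate_range = c(10, 30), seed = 9)
  env1 <- lapply(seq_len(15), function(i) pop$curves[i, ])
  env2 <- lapply(env1, function(x) c(x[324:360], x[1:323]))  # +37 deg
  al <- align_population_rotation(env1, env2)
  expect_equal(al$rotation_deg, 37, tolerance = 1)
  expect_gt(cor(al$corrected_env2[[3]], env1[[3]]), 0.999)
})
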