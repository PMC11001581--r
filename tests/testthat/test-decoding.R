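test_that("decoding follows single-cell and hand-computed likelihoods", {
  # a single sharp cell firing: decoded bin = its preferred direction
  tun <- list(vm_vec(90, 8, peak = 20, baseline = 0.1),
              rep(0.1, 360))
  spikes <- list(a = seq(0.01, 0.99, by = 0.05), b = numeric(0))
  dec <- bayes_decode(spikes, tun, c(0, 1), smooth_sd_s = 0)
  expect_true(all(abs(circ_diff_deg(dec$decoded_deg, 90)) < 10))
  # two cells, two effective directions, hand-computed log-likelihoods
  lam <- rbind(c(10, 1), c(1, 10))
  ll <- function(counts, j) sum(counts * log(lam[, j])) - sum(lam[, j])
  expect_gt(ll(c(8, 1), 1), ll(c(8, 1), 2))  # frozen oracle for the rule
  tun2 <- list(c(rep(10, 180), rep(1, 180)), c(rep(1, 180), rep(10, 180)))
  spikes2 <- list(a = seq(0.05, 0.95, length.out = 8), b = c(0.5))
  dec2 <- bayes_decode(spikes2, tun2, c(0, 1), bin_s = 1, smooth_sd_s = 0)
  expect_lt(dec2$decoded_deg, 180)
})

test_that("decoder recovers the trajectory with small median error", {
  ses <- simulate_session(session_config(
    duration_s = 400, hd = list(n = 20, peak_rate_range = c(20, 60)),
    fs = list(n = 1), seed = 5150))
  hd_ids <- ses$units$unit_id[ses$units$type == "hd"]
  curves <- lapply(ses$spikes[hd_ids], compute_tuning_curve, ses$trajectory,
                   epoch = c(0, 200))
  dec <- bayes_decode(ses$spikes[hd_ids], curves, c(200, 400),
                      trajectory = ses$trajectory)
  expect_lt(median(abs(dec$error_deg)), 15)
  expect_true(all(dec$error_deg > -180 & dec$error_deg <= 180))
})

test_that("decoder is rotation-equivariant", {
  ses <- fixture_session()
  hd_ids <- ses$units$unit_id[ses$units$type == "hd"][1:8]
  curves <- lapply(ses$spikes[hd_ids], compute_tuning_curve, ses$trajectory,
                   epoch = c(0, 150))
  dec <- bayes_decode(ses$spikes[hd_ids], curves, c(150, 200))
  delta <- 60L
  rotated <- lapply(curves, function(tc)
    tuning_curve(c(tc$rates[(360 - delta + 1):360],
                   tc$rates[1:(360 - delta)]), tc$occupancy_s))
  dec_rot <- bayes_decode(ses$spikes[hd_ids], rotated, c(150, 200))
  expect_equal(wrap_deg(dec$decoded_deg + delta), dec_rot$decoded_deg,
               tolerance = 1e-9)
})

test_that("realignment analysis recovers scheduled rotations and excludes", {
  ses <- generate_cue_session(
    session_config(hd = list(n = 25, peak_rate_range = c(20, 60)),
                   fs = list(n = 8, n_inputs = 5),
                   trajectory = list(angular_diffusion = 800), seed = 77),
    n_rotations = 4, stable_s = 250, sigmoid_duration_s = 5)
  hd_ids <- ses$units$unit_id[ses$units$type == "hd"]
  curves <- lapply(ses$spikes[hd_ids], compute_tuning_curve, ses$trajectory,
                   epoch = c(0, 250), speed_min_cms = 0)
  dec <- bayes_decode(ses$spikes[hd_ids], curves,
                      c(200, ses$config$duration_s),
                      trajectory = ses$trajectory)
  ra <- realignment_analysis(dec, ses$trajectory, ses$spikes, ses$units$type,
                             ses$ground_truth$cue$event_t, smooth_sd_deg = 6)
  # rotations toward the cue realign and are detected; rotations back leave
  # near-zero decoder error and are excluded by the 45-degree rule
  expect_identical(ra$epochs$included, c(TRUE, FALSE, TRUE, FALSE))
  # fitted midpoint close to the true event
  expect_true(all(abs(ra$epochs$t0[c(1, 3)] -
                        ses$ground_truth$cue$event_t[c(1, 3)]) < 15))
  is_hd <- ses$units$type == "hd"
  for (k in c(1, 3)) {
    rot <- circ_mean_deg(ra$rotations[is_hd, k], na.rm = TRUE)
    expect_lt(abs(circ_diff_deg(rot, ses$ground_truth$cue$step_deg[k])), 7)
  }
  # FS cells share the population rotation
  expect_equal(unname(abs(circ_diff_deg(ra$hd_pooled_rotation, 90))) < 5, TRUE)
  expect_lt(median(ra$fs_minus_hd), 10)
})
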