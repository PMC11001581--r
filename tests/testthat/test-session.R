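test_that("sessions are seed-deterministic and ground truth is exact", {
  cfg <- session_config(duration_s = 60, hd = list(n = 4), fs = list(n = 2),
                        seed = 10)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trajectory, s2$trajectory)
  gt <- s1$ground_truth
  fs_rows <- which(s1$units$type == "fs")
  expect_equal(gt$curves[fs_rows, ],
               gt$fs_weights %*% gt$curves[seq_len(4), ], tolerance = 1e-14)
})

test_that("epoch schedules are validated", {
  expect_error(session_config(
    duration_s = 100,
    epochs = data.frame(label = c("WAKE", "REM"),
                        start_s = c(0, 50), end_s = c(60, 100))),
    "non-overlapping")
  expect_error(session_config(
    duration_s = 100,
    epochs = data.frame(label = "WAKE", start_s = 0, end_s = 200)),
    "within")
})

test_that("empirical tuning recovered from generated spikes matches truth", {
  ses <- fixture_session()
  hd_rows <- which(ses$units$type == "hd")
  r <- vapply(hd_rows, function(i) {
    tc <- compute_tuning_curve(ses$spikes[[i]], ses$trajectory)
    cor(tc$rates, ses$ground_truth$curves[i, ])
  }, numeric(1))
  expect_gt(min(r), 0.9)
  expect_gt(median(r), 0.95)
})

test_that("REM epochs freeze the head and retain the latent angle", {
  ep <- data.frame(label = c("WAKE", "REM"), start_s = c(0, 60),
                   end_s = c(60, 120))
  ses <- simulate_session(session_config(duration_s = 120, epochs = ep,
                                         hd = list(n = 4), fs = list(n = 1),
                                         seed = 3))
  sel <- ses$trajectory$t >= 60
  expect_equal(length(unique(ses$trajectory$hd[sel])), 1L)
  expect_true(all(ses$trajectory$speed[sel] == 0))
  expect_equal(nrow(ses$ground_truth$latent_hd), sum(sel))
})

test_that("cue sessions rotate the whole population on schedule", {
  # fast head turning (small platform): every epoch covers the circle
  ses <- generate_cue_session(session_config(
    hd = list(n = 6, peak_rate_range = c(20, 60)), fs = list(n = 2),
    trajectory = list(angular_diffusion = 800), seed = 4),
    n_rotations = 16, stable_s = 100, sigmoid_duration_s = 4)
  cue <- ses$ground_truth$cue
  expect_length(cue$event_t, 16L)
  expect_equal(nrow(ses$epochs), 17L)
  # recomputed per-epoch tuning offsets equal the schedule within 3 degrees
  # (oracle: cross-correlation of per-epoch empirical curves of a sharp cell)
  tr <- ses$trajectory
  offs <- vapply(1:6, function(k) {
    e <- ses$epochs[k + 1, ]
    per <- vapply(1:6, function(i) {
      cur <- compute_tuning_curve(ses$spikes[[i]], tr,
                                  c(e$start_s + 20, e$end_s),
                                  speed_min_cms = 0)
      base <- compute_tuning_curve(ses$spikes[[i]], tr, c(0, 100),
                                   speed_min_cms = 0)
      xcorr_peak_offset(circular_xcorr(base, cur))
    }, numeric(1))
    circ_mean_deg(per)
  }, numeric(1))
  expect_true(all(abs(circ_diff_deg(offs, cue$target_deg[1:6])) < 3))
  # instantaneous realignment in the zero-duration limit
  ses0 <- generate_cue_session(session_config(hd = list(n = 2),
                                              fs = list(n = 1), seed = 5),
                               n_rotations = 2, stable_s = 50,
                               sigmoid_duration_s = 0)
  off <- ses0$ground_truth$cue$offset_series
  expect_setequal(unique(off), c(0, 90))
})

test_that("session directories round-trip through write/read", {
  ses <- simulate_session(session_config(duration_s = 30, hd = list(n = 3),
                                         fs = list(n = 1), seed = 6))
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  expect_true(all(file.exists(file.path(dir,
    c("config.json", "trajectory.csv", "spikes.csv", "units.csv",
      "epochs.csv", "groundtruth.json")))))
  back <- read_session(dir)
  expect_equal(back$trajectory$hd, ses$trajectory$hd, tolerance = 1e-9)
  expect_equal(as.numeric(back$spikes[["hd001"]]),
               as.numeric(ses$spikes[["hd001"]]), tolerance = 1e-9)
  expect_equal(back$units$unit_id, ses$units$unit_id)
  expect_equal(as.numeric(back$ground_truth$curves[2, ]),
               as.numeric(ses$ground_truth$curves[2, ]), tolerance = 1e-9)
  expect_silent(validate_session(back))
})
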