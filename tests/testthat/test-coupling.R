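test_that("binning and smoothing are mass-conserving and linear", {
  spk <- list(a = c(30.05), b = sort(runif(500, 0, 100)))
  s1 <- bin_smooth(spk$a, c(0, 100))
  expect_equal(sum(s1), 1, tolerance = 1e-9)  # kernel-shaped bump, mass 1
  expect_equal(attr(s1, "bin_s"), 0.1)
  # population rate of one unit equals that unit's series
  expect_equal(as.numeric(population_rate(spk["a"], c(0, 100))),
               as.numeric(s1), tolerance = 1e-12)
  # sum of per-unit series equals the population series
  pop <- population_rate(spk, c(0, 100))
  s2 <- bin_smooth(spk$b, c(0, 100))
  expect_lt(max(abs(pop - (s1 + s2))) / max(pop), 0.001)
  expect_error(bin_smooth(spk$a, c(0, 30)), "too short")
})

test_that("a cell is maximally coupled to itself at zero offset", {
  set.seed(21)
  lat <- generate_latent_hd(400, diffusion = 150, dt_s = 0.01, seed = 22)
  tun <- vm_vec(90, 3, 20, 1)
  a <- generate_spikes(tun, lat, seed = 23)
  others <- lapply(1:6, function(i)
    generate_spikes(vm_vec(runif(1, 0, 360), 3, 15, 1), lat, seed = 30 + i))
  pop <- population_rate(others, c(0, 400))
  sa <- bin_smooth(a, c(0, 400))
  cc <- pair_coupling(sa, sa, pop, offsets_s = seq(-1, 1, by = 0.5))
  expect_true(cc$ok)
  expect_gt(cc$beta[cc$offsets_s == 0], 0)
  expect_equal(cc$offsets_s[which.max(cc$beta)], 0)
})

test_that("coupling sign tracks tuning alignment and pop conditioning shrinks it", {
  set.seed(24)
  lat <- generate_latent_hd(400, diffusion = 150, dt_s = 0.01, seed = 25)
  epo <- c(0, 400)
  mk <- function(pd, seed) generate_spikes(vm_vec(pd, 3, 25, 0.5), lat,
                                           seed = seed)
  a <- mk(0, 26); b_near <- mk(20, 27); b_opp <- mk(180, 28)
  pool <- lapply(seq(0, 330, by = 30), function(p) mk(p, 100 + p))
  pop <- population_rate(pool, epo)
  sa <- bin_smooth(a, epo)
  b1 <- pair_coupling(sa, bin_smooth(b_near, epo), pop, 0)
  b2 <- pair_coupling(sa, bin_smooth(b_opp, epo), pop, 0)
  expect_gt(b1$beta, 0)
  expect_lt(b2$beta, 0)
  # conditionally independent pair: beta shrinks toward 0 when the
  # population rate is in the model
  pop_null <- runif(length(sa))  # uninformative covariate = pop-free model
  cpl_nopop <- pair_coupling(sa, bin_smooth(b_near, epo), pop_null, 0)
  expect_lt(abs(b1$beta), abs(cpl_nopop$beta) + 0.05)
  # symmetrized curve is exactly symmetric under pair exchange
  offs <- seq(-0.5, 0.5, by = 0.1)
  c_ab <- pair_coupling(sa, bin_smooth(b_near, epo), pop, offs)
  c_ba <- pair_coupling(bin_smooth(b_near, epo), sa, pop, offs)
  expect_equal(c_ab$beta, rev(c_ba$beta), tolerance = 1e-9)
})

test_that("WAKE/REM conservation is positive for shared structure, nil for noise", {
  set.seed(29)
  latw <- generate_latent_hd(300, diffusion = 150, dt_s = 0.01, seed = 30)
  latr <- generate_latent_hd(300, diffusion = 300, dt_s = 0.01, seed = 31)
  pds <- seq(0, 315, by = 45)
  mk <- function(lat, seedo) lapply(seq_along(pds), function(i)
    generate_spikes(vm_vec(pds[i], 3, 25, 0.5), lat, seed = seedo + i))
  sw <- mk(latw, 40); sr <- mk(latr, 60)
  pairs <- rbind(c(1, 2), c(1, 5), c(2, 6), c(3, 4), c(4, 8), c(2, 3))
  run <- function(trains) {
    pop <- population_rate(trains, c(0, 300))
    lapply(seq_len(nrow(pairs)), function(r)
      pair_coupling(bin_smooth(trains[[pairs[r, 1]]], c(0, 300)),
                    bin_smooth(trains[[pairs[r, 2]]], c(0, 300)), pop, 0))
  }
  cw <- run(sw); cr <- run(sr)
  cons <- wake_rem_conservation(cw, cr, rep("HD:HD", nrow(pairs)))
  expect_gt(cons$r, 0.5)
  # decoupled control: independent Poisson trains in "REM"
  noise <- lapply(seq_along(pds), function(i) sort(runif(3000, 0, 300)))
  cn <- run(noise)
  cons0 <- wake_rem_conservation(cw, cn, rep("HD:HD", nrow(pairs)))
  expect_lt(abs(cons0$r), 0.6)
  # fewer than 3 pairs -> NA
  expect_true(is.na(wake_rem_conservation(cw[1:2], cr[1:2],
                                          rep("FS:FS", 2))$r))
})
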