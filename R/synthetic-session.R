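# Full synthetic recording sessions with retained ground truth. A session
# bundles a trajectory, per-unit spike trains, unit metadata, epoch labels
# and the generating ground truth, mirroring the structure of a curated
# electrophysiology session (spike-sorted units + tracked head direction).

#' Session configuration with defaults
#'
#' Defaults describe a realistic cortical HD recording: a 30-minute wake
#' exploration, 40 HD cells with 60-120 degree FWHM tuning, 10 fast-spiking
#' cells mixing all HD inputs through log-normal weights with CV 2 (the
#' heavy-tailed regime), and no opto/cue/synapse manipulations.
#'
#' @param duration_s total session duration (s)
#' @param epochs data.frame with `label`, `start_s`, `end_s`; non-overlapping
#'   and within `[0, duration_s]`. Default: a single WAKE epoch.
#' @param hd list: `n`, `width_range_fwhm_deg`, `peak_rate_range`,
#'   `baseline_rate_range`, `region`
#' @param fs list: `n`, `family`, `mean` (per-input weight mean; default
#'   `3 / n_inputs`, which puts FS mean rates in the fast-spiking range),
#'   `cv`, `n_inputs`
#' @param opto list: `multiplicative`, `additive`, `schedule` (ON interval
#'   matrix) or NULL
#' @param rem list: `diffusion` (deg^2/s) of the latent drifting angle
#' @param synapses data.frame with `pre`, `post`, `efficacy`, `latency_ms`,
#'   `jitter_ms` (unit ids), or NULL
#' @param trajectory list passed to [generate_trajectory()]
#' @param seed master seed; every stochastic stage consumes a named
#'   substream of it
#' @return a `session_config` list
#' @export
session_config <- function(duration_s = 1800, epochs = NULL,
                           hd = list(), fs = list(), opto = NULL,
                           rem = list(), synapses = NULL,
                           trajectory = list(), seed = 1) {
  hd <- utils::modifyList(list(n = 40, width_range_fwhm_deg = c(60, 120),
                               peak_rate_range = c(5, 40),
                               baseline_rate_range = c(0.1, 1),
                               region = "PoSub"), hd)
  fs <- utils::modifyList(list(n = 10, family = "lognormal", mean = NULL,
                               cv = 2, n_inputs = hd$n), fs)
  rem <- utils::modifyList(list(diffusion = 400), rem)
  trajectory <- utils::modifyList(list(angular_diffusion = 200, dt_s = 0.01),
                                  trajectory)
  if (is.null(epochs))
    epochs <- data.frame(label = "WAKE", start_s = 0, end_s = duration_s)
  validate_epochs(epochs, duration_s)
  structure(list(duration_s = duration_s, epochs = epochs, hd = hd, fs = fs,
                 opto = opto, rem = rem, synapses = synapses,
                 trajectory = trajectory, seed = seed),
            class = "session_config")
}

validate_epochs <- function(epochs, duration_s) {
  stopifnot(all(c("label", "start_s", "end_s") %in% names(epochs)))
  if (any(epochs$start_s < 0) || any(epochs$end_s > duration_s + 1e-9) ||
      any(epochs$end_s <= epochs$start_s))
    stop("epochs must be within [0, duration] with start < end")
  o <- order(epochs$start_s)
  s <- epochs$start_s[o]; e <- epochs$end_s[o]
  if (nrow(epochs) > 1 && any(s[-1] < e[-length(e)] - 1e-9))
    stop("epochs must be non-overlapping")
  invisible(epochs)
}

#' Simulate a full recording session
#'
#' Generates a trajectory, ground-truth HD and FS tuning, and per-unit
#' inhomogeneous Poisson spike trains. During REM epochs the real head is
#' still (constant hd, zero speed) and spiking is driven by a latent
#' drifting angle retained in the ground truth; during opto ON intervals
#' rates are gain-modulated. Identical config + seed gives an identical
#' session.
#'
#' @param config a [session_config()]
#' @return object of class `hd_session`: list with `config`, `trajectory`,
#'   `spikes` (named list of spike-time vectors), `units` (data.frame with
#'   `unit_id`, `region`, `type`, `mean_rate_hz`, `trough_to_peak_ms`),
#'   `epochs`, `ground_truth` (true curves, FS weights, REM latent hd,
#'   applied gain, injected synapse counts)
#' @examples
#' ses <- simulate_session(session_config(duration_s = 120,
#'   hd = list(n = 8), fs = list(n = 2), seed = 42))
#' names(ses$spikes)[1:3]
#' @export
simulate_session <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  seed <- config$seed
  tr <- do.call(generate_trajectory,
                c(list(duration_s = config$duration_s,
                       seed = substream_seed(seed, "trajectory")),
                  config$trajectory))
  dt <- stats::median(diff(tr$t))

  # REM: freeze the head, zero the speed, build a latent drifting angle
  rem_rows <- config$epochs[config$epochs$label == "REM", , drop = FALSE]
  latent <- NULL
  drive <- data.frame(t = tr$t, hd = tr$hd)
  if (nrow(rem_rows) > 0) {
    latent_list <- list()
    for (r in seq_len(nrow(rem_rows))) {
      sel <- tr$t >= rem_rows$start_s[r] & tr$t < rem_rows$end_s[r]
      tr$hd[sel] <- tr$hd[which(sel)[1]]
      tr$speed[sel] <- 0
      lat <- generate_latent_hd(rem_rows$end_s[r] - rem_rows$start_s[r],
                                diffusion = config$rem$diffusion, dt_s = dt,
                                seed = substream_seed(seed, paste0("rem", r)))
      lat$t <- lat$t + rem_rows$start_s[r]
      n <- min(sum(sel), nrow(lat))
      drive$hd[which(sel)[seq_len(n)]] <- lat$hd[seq_len(n)]
      latent_list[[r]] <- lat
    }
    latent <- do.call(rbind, latent_list)
  }

  hd_pop <- make_hd_population(config$hd$n, config$hd$width_range_fwhm_deg,
                               config$hd$peak_rate_range,
                               config$hd$baseline_rate_range,
                               region = config$hd$region,
                               seed = substream_seed(seed, "hd_pop"))
  w_mean <- config$fs$mean
  if (is.null(w_mean)) w_mean <- 3 / config$fs$n_inputs
  fs_gt <- make_fs_ground_truth(hd_pop, config$fs$n, config$fs$family,
                                w_mean, config$fs$cv, config$fs$n_inputs,
                                seed = substream_seed(seed, "fs_weights"))

  gain <- if (is.null(config$opto)) NULL else
    list(multiplicative = config$opto$multiplicative %||% 1,
         additive = config$opto$additive %||% 0,
         schedule = config$opto$schedule)

  ids <- c(sprintf("hd%03d", seq_len(config$hd$n)),
           sprintf("fs%03d", seq_len(config$fs$n)))
  all_curves <- rbind(hd_pop$curves, fs_gt$curves)
  spikes <- vector("list", length(ids)); names(spikes) <- ids
  for (i in seq_along(ids))
    spikes[[i]] <- generate_spikes(all_curves[i, ], drive, gain = gain,
                                   seed = substream_seed(seed, ids[i]))

  injected <- NULL
  if (!is.null(config$synapses)) {
    sy <- config$synapses
    injected <- integer(nrow(sy))
    for (r in seq_len(nrow(sy))) {
      out <- inject_synapse(spikes[[sy$pre[r]]], spikes[[sy$post[r]]],
                            sy$efficacy[r],
                            sy$latency_ms[r] %||% 2, sy$jitter_ms[r] %||% 0.2,
                            seed = substream_seed(seed, paste0("syn", r)))
      injected[r] <- attr(out, "n_injected")
      spikes[[sy$post[r]]] <- as.numeric(out)
    }
  }

  units <- data.frame(
    unit_id = ids,
    region = config$hd$region,
    type = rep(c("hd", "fs"), c(config$hd$n, config$fs$n)),
    mean_rate_hz = vapply(spikes, length, numeric(1)) / config$duration_s,
    trough_to_peak_ms = rep(c(0.65, 0.25), c(config$hd$n, config$fs$n)))

  structure(list(config = config, trajectory = tr, spikes = spikes,
                 units = units, epochs = config$epochs,
                 ground_truth = list(curves = all_curves,
                                     hd_pop = hd_pop,
                                     fs_weights = fs_gt$weights,
                                     latent_hd = latent,
                                     gain = gain,
                                     injected = injected)),
            class = "hd_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hd_session <- function(x, ...) {
  cat(sprintf("hd_session: %.0f s, %d units (%d HD, %d FS), epochs: %s\n",
              x$config$duration_s, nrow(x$units),
              sum(x$units$type == "hd"), sum(x$units$type == "fs"),
              paste(unique(x$epochs$label), collapse = ", ")))
  invisible(x)
}

#' Simulate a cue-rotation session
#'
#' A visual cue switches back and forth between two positions 90 degrees
#' apart every 200 s (16 rotations by default, after a stable baseline
#' period). All ground-truth tuning rotates coherently with a sigmoidal time
#' course of the given duration; the latent offset series and the event
#' schedule are retained in the ground truth.
#'
#' @param config a [session_config()]; its duration is overridden to
#'   `stable_s + n_rotations * 200`
#' @param rotation_deg rotation magnitude (deg) between the two cue positions
#' @param n_rotations number of cue switches
#' @param interval_s time between switches (s)
#' @param stable_s initial stable-cue baseline (s)
#' @param sigmoid_duration_s 1-99% duration of the sigmoidal realignment
#'   (0 gives an instantaneous step)
#' @return an `hd_session` whose epochs are labeled `cue_0` (baseline) to
#'   `cue_<n>`; `ground_truth$cue` holds the event times, scheduled angles
#'   and the continuous offset series
#' @export
generate_cue_session <- function(config = session_config(),
                                 rotation_deg = 90, n_rotations = 16,
                                 interval_s = 200, stable_s = 400,
                                 sigmoid_duration_s = 10) {
  duration <- stable_s + n_rotations * interval_s
  ev_t <- stable_s + (seq_len(n_rotations) - 1L) * interval_s
  # cue alternates between offset 0 and offset rotation_deg
  target <- rep(c(rotation_deg, 0), length.out = n_rotations)
  step <- c(target[1], diff(target))
  epochs <- data.frame(
    label = paste0("cue_", 0:n_rotations),
    start_s = c(0, ev_t), end_s = c(ev_t, duration))
  cfg <- config
  cfg$duration_s <- duration
  cfg$epochs <- epochs
  validate_epochs(epochs, duration)

  seed <- cfg$seed
  tr <- do.call(generate_trajectory,
                c(list(duration_s = duration,
                       seed = substream_seed(seed, "trajectory")),
                  cfg$trajectory))
  hd_pop <- make_hd_population(cfg$hd$n, cfg$hd$width_range_fwhm_deg,
                               cfg$hd$peak_rate_range,
                               cfg$hd$baseline_rate_range,
                               region = cfg$hd$region,
                               seed = substream_seed(seed, "hd_pop"))
  w_mean <- cfg$fs$mean %||% (3 / cfg$fs$n_inputs)
  fs_gt <- make_fs_ground_truth(hd_pop, cfg$fs$n, cfg$fs$family, w_mean,
                                cfg$fs$cv, cfg$fs$n_inputs,
                                seed = substream_seed(seed, "fs_weights"))

  # sigmoidal offset time course; sigmoid_duration_s spans 1% -> 99%
  offset <- numeric(length(tr$t))
  cum <- 0
  for (k in seq_len(n_rotations)) {
    if (sigmoid_duration_s <= 0) {
      offset[tr$t >= ev_t[k]] <- offset[tr$t >= ev_t[k]] + step[k]
    } else {
      s <- sigmoid_duration_s / (2 * log(99))
      offset <- offset + step[k] / (1 + exp(-(tr$t - ev_t[k] -
                                               sigmoid_duration_s / 2) / s))
    }
    cum <- cum + step[k]
  }

  ids <- c(sprintf("hd%03d", seq_len(cfg$hd$n)),
           sprintf("fs%03d", seq_len(cfg$fs$n)))
  all_curves <- rbind(hd_pop$curves, fs_gt$curves)
  drive <- data.frame(t = tr$t, hd = wrap_deg(tr$hd - offset))
  spikes <- vector("list", length(ids)); names(spikes) <- ids
  for (i in seq_along(ids))
    spikes[[i]] <- generate_spikes(all_curves[i, ], drive,
                                   seed = substream_seed(seed, ids[i]))

  units <- data.frame(
    unit_id = ids, region = cfg$hd$region,
    type = rep(c("hd", "fs"), c(cfg$hd$n, cfg$fs$n)),
    mean_rate_hz = vapply(spikes, length, numeric(1)) / duration,
    trough_to_peak_ms = rep(c(0.65, 0.25), c(cfg$hd$n, cfg$fs$n)))

  structure(list(config = cfg, trajectory = tr, spikes = spikes,
                 units = units, epochs = epochs,
                 ground_truth = list(curves = all_curves, hd_pop = hd_pop,
                                     fs_weights = fs_gt$weights,
                                     cue = list(event_t = ev_t,
                                                step_deg = step,
                                                target_deg = target,
                                                offset_series = offset))),
            class = "hd_session")
}

#' Write a session to a directory of plain-text files
#'
#' Layout: `config.json`, `trajectory.csv` (t_s, hd_deg, speed_cms),
#' `spikes.csv` (unit_id, t_s), `units.csv`, `epochs.csv`,
#' `groundtruth.json`.
#' @param session an `hd_session`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- session$config
  cfg$epochs <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  tr <- session$trajectory
  utils::write.csv(data.frame(t_s = tr$t, hd_deg = tr$hd, speed_cms = tr$speed),
                   file.path(dir, "trajectory.csv"), row.names = FALSE)
  spk <- data.frame(
    unit_id = rep(names(session$spikes),
                  vapply(session$spikes, length, integer(1))),
    t_s = unlist(session$spikes, use.names = FALSE))
  utils::write.csv(spk, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$units, file.path(dir, "units.csv"), row.names = FALSE)
  utils::write.csv(session$epochs, file.path(dir, "epochs.csv"),
                   row.names = FALSE)
  gt <- session$ground_truth
  gt$hd_pop <- NULL
  jsonlite::write_json(gt, file.path(dir, "groundtruth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#' @param dir session directory
#' @return an `hd_session` (without the generating `hd_population` object)
#' @export
read_session <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "trajectory.csv"))
  trajectory <- structure(data.frame(t = tr$t_s, hd = tr$hd_deg,
                                     speed = tr$speed_cms),
                          class = c("trajectory", "data.frame"))
  spk <- utils::read.csv(file.path(dir, "spikes.csv"))
  units <- utils::read.csv(file.path(dir, "units.csv"))
  spikes <- lapply(split(spk$t_s, factor(spk$unit_id, levels = units$unit_id)),
                   sort)
  epochs <- utils::read.csv(file.path(dir, "epochs.csv"))
  gt_path <- file.path(dir, "groundtruth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  if (!is.null(gt$curves)) gt$curves <- as.matrix(gt$curves)
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path))
    jsonlite::read_json(cfg_path, simplifyVector = TRUE) else NULL
  structure(list(config = cfg, trajectory = trajectory, spikes = spikes,
                 units = units, epochs = epochs, ground_truth = gt),
            class = "hd_session")
}
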