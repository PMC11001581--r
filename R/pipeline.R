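# End-to-end orchestration: validate a session, run the analysis stages in
# dependency order, write per-stage tables and a summary.

#' Validate a session object against the expected schema
#' @param session an `hd_session` (from [simulate_session()] or
#'   [read_session()])
#' @return the session, invisibly; errors on schema violations
#' @export
validate_session <- function(session) {
  need <- c("trajectory", "spikes", "units", "epochs")
  miss <- setdiff(need, names(session))
  if (length(miss)) stop("session is missing: ", paste(miss, collapse = ", "))
  tr <- session$trajectory
  if (!all(c("t", "hd") %in% names(tr))) stop("trajectory needs `t` and `hd`")
  if (is.unsorted(tr$t, strictly = TRUE)) stop("trajectory t must be strictly increasing")
  if (any(tr$hd < 0 | tr$hd >= 360)) stop("hd must be in [0, 360)")
  if (!all(session$units$unit_id %in% names(session$spikes)))
    stop("units and spikes must match")
  validate_epochs(session$epochs, max(tr$t) + stats::median(diff(tr$t)))
  invisible(session)
}

epoch_intervals <- function(session, label) {
  e <- session$epochs[session$epochs$label == label, , drop = FALSE]
  if (nrow(e) == 0) stop("no epoch labeled ", label)
  as.matrix(e[, c("start_s", "end_s")])
}

#' Run the analysis pipeline on a session
#'
#' Executes the requested stages in dependency order (tuning before
#' fourier; both before manifold) and optionally writes per-stage CSV/JSON
#' artifacts plus a summary. Reruns with the same session and seed are
#' deterministic.
#'
#' @param session an `hd_session`
#' @param stages subset of `c("tuning", "fourier", "manifold")` (default
#'   all); an empty vector validates the session only
#' @param epoch epoch label analyzed (default `"WAKE"`)
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @param seed integer seed for the stochastic stages
#' @param speed_min_cms speed filter for tuning (default 2)
#' @return list of class `pipeline_result` with one element per executed
#'   stage plus `summary`
#' @export
run_pipeline <- function(session, stages = c("tuning", "fourier", "manifold"),
                         epoch = "WAKE", out_dir = NULL, seed = 1,
                         speed_min_cms = 2) {
  validate_session(session)
  known <- c("tuning", "fourier", "manifold")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]  # enforce dependency order
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  ep <- epoch_intervals(session, epoch)
  ids <- session$units$unit_id
  res <- list()

  if ("fourier" %in% stages || "manifold" %in% stages)
    stages <- union(stages, "tuning")

  if ("tuning" %in% stages) {
    curves <- lapply(session$spikes[ids], compute_tuning_curve,
                     session$trajectory, epoch = ep,
                     speed_min_cms = speed_min_cms)
    info <- vapply(seq_along(ids), function(i) {
      hd_information(curves[[i]])$info_bits_per_spike
    }, numeric(1))
    control <- vapply(ids, function(id)
      time_reversed_control(session$spikes[[id]], session$trajectory,
                            ep, speed_min_cms = speed_min_cms
      )$info$info_bits_per_spike, numeric(1))
    is_hd <- classify_hd(info, control)
    uclass <- classify_units(session$units$mean_rate_hz,
                             session$units$trough_to_peak_ms)
    res$tuning <- list(curves = curves, info = info, control = control,
                       is_hd = is_hd, unit_class = uclass)
    if (!is.null(out_dir)) {
      tm <- t(vapply(curves, function(cv) cv$rates,
                     numeric(length(curves[[1]]$rates))))
      utils::write.csv(data.frame(unit_id = ids, tm, check.names = FALSE),
                       file.path(out_dir, "tuning.csv"), row.names = FALSE)
      utils::write.csv(data.frame(unit_id = ids, bits_per_spike = info,
                                  control = control, is_hd = is_hd,
                                  unit_class = uclass),
                       file.path(out_dir, "info.csv"), row.names = FALSE)
    }
  }

  if ("fourier" %in% stages) {
    sigs <- lapply(res$tuning$curves, fourier_signature)
    dom <- vapply(sigs, dominant_component, integer(1))
    popsig <- population_signature(sigs)
    dkl <- signature_dispersion(sigs)
    res$fourier <- list(signatures = sigs, dominant = dom,
                        population = popsig, dkl = dkl)
    if (!is.null(out_dir)) {
      P <- t(vapply(sigs, function(s) s$normalized_power, numeric(10)))
      colnames(P) <- paste0("p", 1:10)
      utils::write.csv(data.frame(unit_id = ids, P,
                                  total_power = vapply(sigs, function(s)
                                    s$total_power, numeric(1)),
                                  dominant_class = dom, dkl_to_popmean = dkl),
                       file.path(out_dir, "signatures.csv"),
                       row.names = FALSE)
    }
  }

  if ("manifold" %in% stages) {
    hd_ids <- ids[session$units$type == "hd"]
    pv <- population_vectors(session$spikes[hd_ids], ep)
    keep <- rowSums(pv$pv) > 0
    pvm <- pv$pv[keep, , drop = FALSE]
    # desk-scale cap on the eigendecomposition
    if (nrow(pvm) > 2500) {
      set.seed(seed)
      sub <- sort(sample.int(nrow(pvm), 2500))
      pvm <- pvm[sub, , drop = FALSE]
      pvt <- pv$t[keep][sub]
    } else pvt <- pv$t[keep]
    emb <- geodesic_embed(pvm, k = 12, dims = 3)
    idx <- pmax(findInterval(pvt[emb$kept], session$trajectory$t), 1L)
    vhd <- virtual_hd(emb, pvt[emb$kept],
                      real_hd = session$trajectory$hd[idx],
                      hd_spikes = session$spikes[hd_ids])
    res$manifold <- list(embedding = emb, vhd = vhd, pv_t = pvt[emb$kept])
    if (!is.null(out_dir)) {
      co <- emb$coords
      utils::write.csv(data.frame(t = pvt[emb$kept], x = co[, 1], y = co[, 2],
                                  z = if (ncol(co) > 2) co[, 3] else NA,
                                  alpha_deg = vhd$alpha_deg, d = vhd$d),
                       file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
    }
  }

  res$summary <- list(
    n_units = nrow(session$units),
    n_hd = if (!is.null(res$tuning)) sum(res$tuning$is_hd) else NA,
    n_fs = if (!is.null(res$tuning)) sum(res$tuning$unit_class == "FS") else NA,
    mean_signature = if (!is.null(res$fourier)) res$fourier$population else NULL,
    class_proportions = if (!is.null(res$fourier))
      as.list(prop.table(table(factor(res$fourier$dominant, levels = 1:10))))
    else NULL)
  if (!is.null(out_dir))
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  structure(res, class = "pipeline_result")
}
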