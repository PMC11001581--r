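# Geodesic (Isomap-style) embeddings: kNN graph on Euclidean distances,
# shortest-path geodesic distances, classical MDS. Used in two modes:
# a 2D shape space of tuning-curve auto-correlograms and a 3D ring manifold
# of HD population vectors, from which a virtual head direction is read out.

#' Bin and smooth spike trains into population vectors
#'
#' Spike counts in `bin_s` bins, Gaussian-smoothed in time
#' (`smooth_sd_s` s.d.) and square-root transformed (variance stabilization
#' for Poisson-like counts), the standard preprocessing ahead of manifold
#' embedding.
#'
#' @param spikes_list named list of spike-time vectors (the HD cell
#'   population)
#' @param epoch `c(start, end)` or interval matrix
#' @param bin_s time bin (default 0.2 s)
#' @param smooth_sd_s temporal Gaussian s.d. (default 0.4 s)
#' @param sqrt_transform take sqrt of smoothed counts (default TRUE)
#' @return list: `pv` (time x cells matrix), `t` (bin centers), `bin_s`
#' @export
population_vectors <- function(spikes_list, epoch, bin_s = 0.2,
                               smooth_sd_s = 0.4, sqrt_transform = TRUE) {
  ep <- as_epoch_matrix(epoch)
  mats <- list(); times <- list()
  for (r in seq_len(nrow(ep))) {
    breaks <- seq(ep[r, 1], ep[r, 2], by = bin_s)
    if (length(breaks) < 2) next
    ctr <- breaks[-length(breaks)] + bin_s / 2
    m <- matrix(vapply(spikes_list, function(s) {
      s <- s[s >= ep[r, 1] & s < breaks[length(breaks)]]
      cnt <- tabulate(findInterval(s, breaks), nbins = length(breaks) - 1L)
      smooth_linear(cnt, smooth_sd_s / bin_s)
    }, numeric(length(ctr))), nrow = length(ctr))
    mats[[length(mats) + 1L]] <- m
    times[[length(times) + 1L]] <- ctr
  }
  pv <- do.call(rbind, mats)
  if (sqrt_transform) pv <- sqrt(pmax(pv, 0))
  list(pv = pv, t = unlist(times), bin_s = bin_s)
}

#' Geodesic (Isomap-style) embedding
#'
#' Builds a k-nearest-neighbour graph on Euclidean distances (ties broken by
#' item index; exact duplicates separated by a 1e-9 jitter with a fixed
#' seed), computes all-pairs shortest-path geodesic distances and embeds
#' them with classical MDS. A disconnected graph is reduced to its largest
#' component and the dropped items are flagged.
#'
#' @param items numeric matrix, one item (population vector, correlogram)
#'   per row
#' @param k number of nearest neighbours (default 12)
#' @param dims embedding dimensionality (2 for shape space, 3 for the ring)
#' @return object of class `geodesic_embedding`: `coords` (kept items x
#'   dims), `kept` (row indices embedded), `dropped`, `k`, `dims`
#' @export
geodesic_embed <- function(items, k = 12, dims = 2) {
  items <- as.matrix(items)
  n <- nrow(items)
  if (k >= n) stop("`k` must be smaller than the number of items")
  if (anyDuplicated(items)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(987654L)
    items <- items + matrix(stats::rnorm(length(items), 0, 1e-9), n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  d <- as.matrix(stats::dist(items))
  edges <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]  # order() breaks ties by index
    edges <- c(edges, rbind(i, nb))
    w <- c(w, d[i, nb])
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  dropped <- setdiff(seq_len(n), keep)
  geo <- igraph::distances(g, v = keep, to = keep)
  coords <- stats::cmdscale(geo, k = dims)
  structure(list(coords = coords, kept = keep, dropped = dropped,
                 k = k, dims = dims),
            class = "geodesic_embedding")
}

#' @export
print.geodesic_embedding <- function(x, ...) {
  cat(sprintf("geodesic_embedding: %d items in %d dims (k = %d%s)\n",
              nrow(x$coords), x$dims, x$k,
              if (length(x$dropped)) paste0(", ", length(x$dropped), " dropped")
              else ""))
  invisible(x)
}

#' Virtual head direction from a ring embedding
#'
#' The angular coordinate `alpha` of each population vector on the embedded
#' ring is the four-quadrant arctangent of the first two embedding
#' dimensions. The ring's directionality (clockwise vs counterclockwise) is
#' arbitrary: when a reference real-HD series is given it is resolved by
#' choosing the sign for which the circular variance of `real - alpha` is
#' smaller. The arbitrary origin is resolved by computing internal tuning
#' curves of reference HD cells from `alpha`, cross-correlating them with
#' their real-HD tuning curves, and rotating `alpha` by the circular mean
#' peak offset. Without a reference, `alpha` is returned unaligned and
#' flagged.
#'
#' @param embedding a `geodesic_embedding` of population vectors (ring mode)
#' @param pv_t time-bin centers of the embedded population vectors (same
#'   order as embedding rows, after any dropping)
#' @param real_hd optional real head direction per population vector (deg)
#' @param hd_spikes optional named list of HD-cell spike trains used for the
#'   origin alignment
#' @param bin_s population-vector bin width (s), used to build internal
#'   tuning curves
#' @param bin_deg,smooth_sd_deg binning and smoothing of the internal tuning
#'   curves used for alignment (1 and 3 degrees for wake)
#' @return list of class `virtual_hd`: `alpha_deg` (in \[0, 360)), `d`
#'   (distance to the manifold center), `flipped`, `origin_offset_deg`,
#'   `aligned` (FALSE when no reference was available)
#' @export
virtual_hd <- function(embedding, pv_t, real_hd = NULL, hd_spikes = NULL,
                       bin_s = 0.2, bin_deg = 1, smooth_sd_deg = 3) {
  co <- embedding$coords
  alpha <- wrap_deg(atan2(co[, 2], co[, 1]) * 180 / pi)
  d <- sqrt(co[, 1]^2 + co[, 2]^2)
  flipped <- FALSE
  offset <- 0
  aligned <- FALSE
  if (!is.null(real_hd)) {
    if (circ_var_deg(real_hd + alpha) < circ_var_deg(real_hd - alpha)) {
      alpha <- wrap_deg(-alpha)
      flipped <- TRUE
    }
    if (!is.null(hd_spikes)) {
      traj_alpha <- data.frame(t = pv_t, hd = alpha)
      traj_real <- data.frame(t = pv_t, hd = real_hd)
      per <- vapply(hd_spikes, function(s) {
        ci <- compute_tuning_curve(s, traj_alpha, bin_deg = bin_deg,
                                   smooth_sd_deg = smooth_sd_deg,
                                   speed_min_cms = 0)
        cr <- compute_tuning_curve(s, traj_real, bin_deg = bin_deg,
                                   smooth_sd_deg = smooth_sd_deg,
                                   speed_min_cms = 0)
        xcorr_peak_offset(circular_xcorr(cr, ci))
      }, numeric(1))
      offset <- circ_mean_deg(per, na.rm = TRUE)
      alpha <- wrap_deg(alpha - offset)
      aligned <- TRUE
    }
  }
  structure(list(alpha_deg = alpha, d = d, flipped = flipped,
                 origin_offset_deg = offset, aligned = aligned),
            class = "virtual_hd")
}

#' Internal tuning curve from a virtual-HD series
#'
#' Occupancy-normalized tuning of any unit against the virtual head
#' direction (wake default: 1 degree bins, 3 degree smoothing; REM: 6 degree
#' bins and smoothing, because virtual-HD occupancy is uneven during sleep).
#'
#' @param spikes spike times (s)
#' @param vhd a `virtual_hd` object (or a numeric alpha series)
#' @param pv_t time-bin centers matching `vhd`
#' @param bin_deg,smooth_sd_deg angular binning / smoothing
#' @return a [tuning_curve()]
#' @export
internal_tuning <- function(spikes, vhd, pv_t, bin_deg = 1, smooth_sd_deg = 3) {
  alpha <- if (inherits(vhd, "virtual_hd")) vhd$alpha_deg else as.numeric(vhd)
  compute_tuning_curve(spikes, data.frame(t = pv_t, hd = alpha),
                       bin_deg = bin_deg, smooth_sd_deg = smooth_sd_deg,
                       speed_min_cms = 0)
}

#' Joint WAKE + REM ring embedding
#'
#' WAKE population vectors are randomly downsampled to the REM count, the
#' two sets are embedded jointly, and the virtual HD is computed for both
#' (aligned on the WAKE part using the real HD). Sessions with less than
#' `min_rem_s` of REM are skipped with a warning.
#'
#' @param pv_wake,pv_rem outputs of [population_vectors()] for the two
#'   epochs
#' @param real_hd_wake real head direction per WAKE population vector (deg)
#' @param hd_spikes named list of HD-cell spike trains (origin alignment)
#' @param k,dims embedding parameters (12 neighbours, 3 dims)
#' @param min_rem_s minimum REM duration (default 100 s)
#' @param seed integer seed for the WAKE downsampling
#' @return list of class `joint_embedding`: `embedding`, `epoch` (label per
#'   embedded row), `vhd` (joint `virtual_hd`), `wake_idx`, `rem_idx`
#'   (row indices into the original PV matrices), or NULL when REM is too
#'   short
#' @export
rem_joint_embedding <- function(pv_wake, pv_rem, real_hd_wake, hd_spikes,
                                k = 12, dims = 3, min_rem_s = 100,
                                seed = NULL) {
  n_rem <- nrow(pv_rem$pv)
  if (n_rem * pv_rem$bin_s < min_rem_s) {
    warning("REM epoch shorter than the minimum; skipping")
    return(NULL)
  }
  if (!is.null(seed)) set.seed(seed)
  n_wake <- nrow(pv_wake$pv)
  sub <- sort(sample.int(n_wake, min(n_rem, n_wake)))
  X <- rbind(pv_wake$pv[sub, , drop = FALSE], pv_rem$pv)
  lab <- rep(c("WAKE", "REM"), c(length(sub), n_rem))
  tt <- c(pv_wake$t[sub], pv_rem$t)
  emb <- geodesic_embed(X, k = k, dims = dims)
  lab <- lab[emb$kept]; tt <- tt[emb$kept]
  real <- rep(NA_real_, length(lab))
  kept_wake <- emb$kept[emb$kept <= length(sub)]
  real[lab == "WAKE"] <- real_hd_wake[sub][kept_wake]
  # orientation + origin from the WAKE part only, then applied jointly
  co <- emb$coords
  alpha <- wrap_deg(atan2(co[, 2], co[, 1]) * 180 / pi)
  wk <- lab == "WAKE"
  flipped <- circ_var_deg(real[wk] + alpha[wk]) < circ_var_deg(real[wk] - alpha[wk])
  if (flipped) alpha <- wrap_deg(-alpha)
  per <- vapply(hd_spikes, function(s) {
    ci <- compute_tuning_curve(s, data.frame(t = tt[wk], hd = alpha[wk]),
                               bin_deg = 1, smooth_sd_deg = 3,
                               speed_min_cms = 0)
    cr <- compute_tuning_curve(s, data.frame(t = tt[wk], hd = real[wk]),
                               bin_deg = 1, smooth_sd_deg = 3,
                               speed_min_cms = 0)
    xcorr_peak_offset(circular_xcorr(cr, ci))
  }, numeric(1))
  offset <- circ_mean_deg(per, na.rm = TRUE)
  alpha <- wrap_deg(alpha - offset)
  vhd <- structure(list(alpha_deg = alpha,
                        d = sqrt(co[, 1]^2 + co[, 2]^2),
                        flipped = flipped, origin_offset_deg = offset,
                        aligned = TRUE),
                   class = "virtual_hd")
  structure(list(embedding = emb, epoch = lab, t = tt, vhd = vhd,
                 wake_rows = sub), class = "joint_embedding")
}

#' Shape-space embedding of tuning-curve auto-correlograms
#'
#' 2D geodesic embedding of cross-validated circular auto-correlograms,
#' annotated with the relative power of the first three Fourier components
#' of each cell's tuning curve (for RGB coloring); cells with pure onefold,
#' twofold and threefold symmetry land at distinct extremes.
#'
#' @param autocorrs matrix of auto-correlograms (cells x offsets)
#' @param signatures optional list of `fourier_signature`s matched to rows
#' @param k neighbours (default 12)
#' @return list of class `shape_space`: `embedding`, `rgb` (kept cells x 3,
#'   relative power of components 1-3), `kept`
#' @export
shape_space <- function(autocorrs, signatures = NULL, k = 12) {
  autocorrs <- as.matrix(autocorrs)
  if (all(apply(autocorrs, 2, stats::var) == 0))
    stop("degenerate auto-correlograms: no variance across cells")
  emb <- geodesic_embed(autocorrs, k = k, dims = 2)
  rgb <- NULL
  if (!is.null(signatures)) {
    p3 <- t(vapply(signatures, function(s) s$power[1:3], numeric(3)))
    rgb <- p3 / pmax(rowSums(p3), 1e-12)
    rgb <- rgb[emb$kept, , drop = FALSE]
  }
  structure(list(embedding = emb, rgb = rgb, kept = emb$kept),
            class = "shape_space")
}
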