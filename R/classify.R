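#' Per-neuron spatial descriptor panel
#'
#' Runs the full scoring pipeline for every neuron of an activity matrix
#' recorded along a trajectory: spike extraction, 3D rate map, spatial
#' information, border scores on the three orthogonal projections,
#' hexagonal/square gridness on the projected autocorrelograms, plane
#' index, accepted plane count, firing-field count, ellipsoid elongation
#' index, and (for multi-field, spatially periodic neurons) the FCC score.
#'
#' @param gamma T x n activity matrix ([lahn_activities()]).
#' @param traj the trajectory the activities were recorded on.
#' @param thresholds a [default_thresholds()] set.
#' @param sigma rate-map smoothing s.d., voxels.
#' @param compute_fcc compute the FCC score for grid-classified periodic
#'   neurons (the expensive transection-plane scan).
#' @param fcc_normals number of transection-plane normals for the FCC scan.
#' @param min_spikes neurons with fewer spikes get an all-NA row (treated
#'   as failing every criterion).
#' @param periodic_ring minimum ring-averaged autocorrelation of the
#'   secondary (non-central) ring, in the best projection, for a neuron
#'   to count as spatially periodic: a genuine lattice or stripe pattern
#'   lifts a whole ring of the correlogram, isolated noise bumps do not
#'   (smoothed 3D grid fields also merge into single connected rate-map
#'   components, so field counts cannot detect periodicity).
#' @return data.frame of class `score_panel`, one row per neuron.
#' @export
score_panel <- function(gamma, traj, thresholds = default_thresholds(),
                        sigma = 3, compute_fcc = TRUE, fcc_normals = 500,
                        min_spikes = 10, periodic_ring = 0.15) {
  n <- ncol(gamma)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spikes <- extract_spikes(gamma[, i], traj, neuron = i)
    row <- data.frame(neuron = i, n_spikes = nrow(spikes), si = NA_real_,
                      bs_xy = NA_real_, bs_yz = NA_real_, bs_xz = NA_real_,
                      bs_top2 = NA_real_, hgs_xy = NA_real_,
                      hgs_yz = NA_real_, hgs_xz = NA_real_,
                      sgs_xy = NA_real_, sgs_yz = NA_real_,
                      sgs_xz = NA_real_, hgs_best = NA_real_,
                      sgs_best = NA_real_, pi = NA_real_,
                      n_planes = NA_integer_, n_fields = NA_integer_,
                      ac_peaks = NA_integer_, ring_max = NA_real_,
                      xi = NA_real_, periodic = FALSE, fcc = NA_real_)
    if (nrow(spikes) >= min_spikes) {
      rm3 <- rate_map(spikes, traj, sigma = sigma)
      row$si <- spatial_information(rm3)
      bs <- border_score_3d(rm3, bs_thr = thresholds$bs)
      row$bs_xy <- bs$bs_xy; row$bs_yz <- bs$bs_yz; row$bs_xz <- bs$bs_xz
      row$bs_top2 <- bs$bs_top2
      pk_max <- 0L
      ring_max <- NA_real_
      for (pl in c("xy", "yz", "xz")) {
        pj <- project_map(rm3, pl)
        gs <- tryCatch(gridness(autocorrelate(pj)),
                       error = function(e) list(hgs = NA, sgs = NA,
                                                n_peaks = NA,
                                                ring_max = NA))
        row[[paste0("hgs_", pl)]] <- gs$hgs
        row[[paste0("sgs_", pl)]] <- gs$sgs
        if (!is.na(gs$n_peaks %||% NA))
          pk_max <- max(pk_max, gs$n_peaks)
        ring_max <- suppressWarnings(max(ring_max, gs$ring_max %||% NA,
                                         na.rm = TRUE))
      }
      row$ac_peaks <- pk_max
      row$ring_max <- if (is.finite(ring_max)) ring_max else NA_real_
      row$hgs_best <- suppressWarnings(
        max(row$hgs_xy, row$hgs_yz, row$hgs_xz, na.rm = TRUE))
      row$sgs_best <- suppressWarnings(
        max(row$sgs_xy, row$sgs_yz, row$sgs_xz, na.rm = TRUE))
      if (!is.finite(row$hgs_best)) row$hgs_best <- NA_real_
      if (!is.finite(row$sgs_best)) row$sgs_best <- NA_real_
      row$pi <- plane_index(rm3)$pi
      ## stack search only matters once the plane criterion can fire
      row$n_planes <- if (!is.na(row$pi) && row$pi > thresholds$pi)
        length(stack_detect(rm3, pi_thr = thresholds$pi)) else 0L
      row$n_fields <- count_fields(rm3)
      ## ellipsoid isotropy only means anything for single-field neurons
      row$xi <- if (isTRUE(row$n_fields == 1)) ellipsoid_fit(rm3)$xi
                else NA_real_
      ## spatially periodic: a secondary correlation ring in some
      ## projected autocorrelogram
      row$periodic <- isTRUE(!is.na(row$ring_max) &
                               row$ring_max > periodic_ring &
                               !is.na(row$si) & row$si > thresholds$si)
      grid_like <- isTRUE(row$periodic &&
                            ((!is.na(row$hgs_best) &&
                                row$hgs_best > thresholds$hgs) ||
                             (!is.na(row$sgs_best) &&
                                row$sgs_best > thresholds$sgs)))
      if (compute_fcc && grid_like) {
        ac3 <- tryCatch(autocorrelate(rm3), error = function(e) NULL)
        if (!is.null(ac3))
          row$fcc <- fcc_score(ac3, n_normals = fcc_normals)$fcc
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_panel", "data.frame")
  out
}

#' Classify a neuron from its descriptor panel
#'
#' Decision cascade (most specific label wins): non-spatial if the spatial
#' information is below threshold; else border (border score above
#' threshold on two orthogonal planes); else grid (hexagonal if best HGS
#' above threshold, square if best SGS above threshold); else plane/stack
#' (plane index above threshold with low aggregate border score; stack when
#' several planes are accepted); else place (a single compact field with
#' sufficient spatial information); else other spatial cell (OSC).
#' Undefined descriptors fail their test.
#'
#' @param panel one row of a [score_panel()] (or a list with the same
#'   fields).
#' @param thr a [default_thresholds()] set.
#' @return character label, one of `"non-spatial"`, `"border"`,
#'   `"grid-hex"`, `"grid-square"`, `"plane"`, `"stack"`, `"place"`,
#'   `"OSC"`.
#' @export
classify_neuron <- function(panel, thr = default_thresholds()) {
  val <- function(x) if (is.null(x) || is.na(x)) -Inf else x
  if (val(panel$si) <= thr$si) return("non-spatial")
  n_high_bs <- sum(c(val(panel$bs_xy), val(panel$bs_yz),
                     val(panel$bs_xz)) > thr$bs)
  if (n_high_bs >= 2) return("border")
  if (val(panel$hgs_best) > thr$hgs) return("grid-hex")
  if (val(panel$sgs_best) > thr$sgs) return("grid-square")
  if (val(panel$pi) > thr$pi && val(panel$bs_top2) < thr$bs) {
    np <- panel$n_planes
    if (!is.null(np) && !is.na(np) && np >= 2) return("stack")
    return("plane")
  }
  nf <- panel$n_fields
  if (!is.null(nf) && !is.na(nf) && nf == 1 &&
      val(panel$si) > thr$place_si) return("place")
  "OSC"
}

#' Classify all neurons of a panel
#'
#' @param panel a [score_panel()].
#' @param thr a [default_thresholds()] set.
#' @return character vector of labels, one per neuron.
#' @export
classify_panel <- function(panel, thr = default_thresholds()) {
  vapply(seq_len(nrow(panel)), function(i)
    classify_neuron(panel[i, ], thr), character(1))
}

#' Cell-type census over retrainings
#'
#' Mean (and s.d.) fraction of each cell type across repeated retrainings.
#' Fractions over all neurons sum to 100%; the `of_spatial` table gives the
#' composition of the spatial population, with grid-hex/grid-square merged
#' into `grid` and plane/stack merged into `plane`.
#'
#' @param labels a character vector of labels (single repeat) or a list of
#'   such vectors (one per repeat).
#' @return list of class `census`: `fractions` (mean % per label over all
#'   neurons), `fractions_sd`, `of_spatial` (mean % per merged type among
#'   spatial cells), `spatial_pct`, `n_repeats`, `per_repeat`.
#' @export
census <- function(labels) {
  if (!is.list(labels)) labels <- list(labels)
  if (length(labels) < 1) stop("need at least one repeat")
  lev <- c("place", "grid-hex", "grid-square", "border", "plane", "stack",
           "OSC", "non-spatial")
  per <- t(vapply(labels, function(l) {
    tab <- table(factor(l, levels = lev))
    100 * as.numeric(tab) / length(l)
  }, numeric(length(lev))))
  colnames(per) <- lev
  merge_types <- function(l) {
    spatial <- l[l != "non-spatial"]
    if (length(spatial) == 0) return(setNames(rep(NA_real_, 5),
      c("place", "grid", "border", "plane", "OSC")))
    m <- ifelse(spatial %in% c("grid-hex", "grid-square"), "grid",
                ifelse(spatial %in% c("plane", "stack"), "plane", spatial))
    tab <- table(factor(m, levels = c("place", "grid", "border", "plane",
                                      "OSC")))
    100 * as.numeric(tab) / length(spatial)
  }
  of_sp <- t(vapply(labels, merge_types, numeric(5)))
  colnames(of_sp) <- c("place", "grid", "border", "plane", "OSC")
  structure(list(
    fractions = colMeans(per),
    fractions_sd = apply(per, 2, sd),
    of_spatial = colMeans(of_sp, na.rm = TRUE),
    of_spatial_sd = apply(of_sp, 2, sd),
    spatial_pct = mean(100 - per[, "non-spatial"]),
    n_repeats = length(labels),
    per_repeat = per
  ), class = "census")
}

#' @export
print.census <- function(x, ...) {
  cat(sprintf("census over %d repeat(s): %.1f%% spatial\n", x$n_repeats,
              x$spatial_pct))
  cat("of spatial cells (%):\n")
  print(round(x$of_spatial, 2))
  invisible(x)
}

#' Eigen-spectrum band analysis of the path-integration input
#'
#' Direct PCA on the path-integration matrix of each supplied trajectory:
#' eigendecomposition of the input covariance, projection of the stream
#' onto each principal component, conversion of each projection trace to a
#' rate map and scoring (SI, border score, gridness, plane index),
#' averaged across trajectories. Bands are contiguous PC-index runs where
#' an averaged descriptor exceeds its threshold.
#'
#' @param trajs a trajectory or list of trajectories.
#' @param n_pcs number of leading PCs to analyze.
#' @param layer head-direction layer used for encoding.
#' @param thresholds threshold set for the band definitions.
#' @param sigma rate-map smoothing, voxels.
#' @return list of class `eigen_spectrum`: `table` (per-PC averaged
#'   variance fraction, cumulative variance and descriptors), `bands`
#'   (per-descriptor index ranges), `n_trajectories`.
#' @export
eigen_spectrum <- function(trajs, n_pcs = 30, layer = make_hd_layer(),
                           thresholds = default_thresholds(), sigma = 3) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  acc <- NULL
  for (traj in trajs) {
    y <- run_encoding(traj, layer, oscillator_bank(layer))
    yc <- sweep(y, 2, colMeans(y))
    ev <- eigen(stats::cov(yc), symmetric = TRUE)
    keep <- ev$values > 1e-12 * ev$values[1]
    vals <- ev$values[keep]
    npc <- min(n_pcs, length(vals))
    var_frac <- vals / sum(vals)
    proj <- yc %*% ev$vectors[, seq_len(npc), drop = FALSE]
    rows <- lapply(seq_len(npc), function(k) {
      spikes <- extract_spikes(proj[, k], traj)
      if (nrow(spikes) < 10)
        return(data.frame(pc = k, var_frac = var_frac[k], si = NA_real_,
                          bs_top2 = NA_real_, hgs_best = NA_real_,
                          pi = NA_real_))
      rm3 <- rate_map(spikes, traj, sigma = sigma)
      bs <- border_score_3d(rm3, bs_thr = thresholds$bs)
      hgs <- suppressWarnings(max(vapply(c("xy", "yz", "xz"), function(pl)
        tryCatch(gridness(autocorrelate(project_map(rm3, pl)))$hgs,
                 error = function(e) NA_real_), numeric(1)), na.rm = TRUE))
      data.frame(pc = k, var_frac = var_frac[k],
                 si = spatial_information(rm3), bs_top2 = bs$bs_top2,
                 hgs_best = if (is.finite(hgs)) hgs else NA_real_,
                 pi = plane_index(rm3)$pi)
    })
    acc <- rbind(acc, do.call(rbind, rows))
  }
  tab <- do.call(rbind, lapply(split(acc, acc$pc), function(d)
    data.frame(pc = d$pc[1], var_frac = mean(d$var_frac),
               si = mean(d$si, na.rm = TRUE),
               bs_top2 = mean(d$bs_top2, na.rm = TRUE),
               hgs_best = mean(d$hgs_best, na.rm = TRUE),
               pi = mean(d$pi, na.rm = TRUE))))
  tab <- tab[order(tab$pc), ]
  tab$cum_var <- cumsum(tab$var_frac)
  band_of <- function(v, thr) {
    hit <- which(!is.na(v) & v > thr)
    if (length(hit) == 0) return(NULL)
    ## contiguous runs
    runs <- split(hit, cumsum(c(1, diff(hit) != 1)))
    lapply(runs, range)
  }
  bands <- list(
    place = band_of(tab$si, thresholds$place_si),
    border = band_of(tab$bs_top2, thresholds$bs),
    grid = band_of(tab$hgs_best, 0),
    plane = band_of(tab$pi, thresholds$pi))
  structure(list(table = tab, bands = bands,
                 n_trajectories = length(trajs)),
            class = "eigen_spectrum")
}

#' Evaluate a trained network on new trajectories without retraining
#'
#' Runs the fixed network (weights untouched) over trajectories generated
#' from each supplied configuration and scores the requested neurons on the
#' resulting maps. For plane-constrained configurations the maps are 2D on
#' the navigation plane; for volumetric ones the 3D map is projected.
#' Implements the horizontal/vertical anisotropy comparison and the
#' critical-angle pitch sweep.
#'
#' @param net a trained [lahn_network()]; never modified.
#' @param configs list of [trajectory_config()]s (named or not).
#' @param arena the arena.
#' @param layer head-direction layer (must match the training encoder).
#' @param neurons indices of neurons to score (default: all).
#' @param sigma rate-map smoothing, voxels.
#' @return list of class `anisotropy_result`, one element per config:
#'   data.frame with per-neuron `hgs`, `sgs`, `si`, `n_spikes`, plus the
#'   config's pitch s.d. and mode.
#' @export
anisotropy_experiment <- function(net, configs, arena = spatialnet3d::arena(),
                                  layer = make_hd_layer(), neurons = NULL,
                                  sigma = 3) {
  stopifnot(inherits(net, "lahn"))
  neurons <- neurons %||% seq_len(net$n)
  q0 <- net$q; p0 <- net$p
  out <- lapply(configs, function(cfg) {
    traj <- generate_trajectory(cfg, arena)
    y <- run_encoding(traj, layer, oscillator_bank(layer))
    g <- lahn_activities(net, y)
    plane <- switch(cfg$mode, `plane-xy` = "xy", `plane-yz` = "yz", NULL)
    rows <- lapply(neurons, function(i) {
      spikes <- extract_spikes(g[, i], traj, neuron = i)
      if (nrow(spikes) < 10)
        return(data.frame(neuron = i, n_spikes = nrow(spikes),
                          hgs = NA_real_, sgs = NA_real_, si = NA_real_))
      m2 <- if (!is.null(plane)) rate_map_2d(spikes, traj, plane,
                                             sigma = sigma)
            else project_map(rate_map(spikes, traj, sigma = sigma), "xy")
      gs <- tryCatch(gridness(autocorrelate(m2)),
                     error = function(e) list(hgs = NA_real_,
                                              sgs = NA_real_))
      si <- tryCatch(spatial_information(m2), error = function(e) NA_real_)
      data.frame(neuron = i, n_spikes = nrow(spikes), hgs = gs$hgs,
                 sgs = gs$sgs, si = si)
    })
    df <- do.call(rbind, rows)
    attr(df, "pitch_sd") <- cfg$pitch_sd
    attr(df, "mode") <- cfg$mode
    df
  })
  stopifnot(identical(net$q, q0), identical(net$p, p0))
  structure(out, class = "anisotropy_result")
}
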