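## ---- FFT helpers ------------------------------------------------------

## n-dimensional FFT of an array zero-padded to dims `pd`
.fft_pad <- function(a, pd) {
  out <- array(0, pd)
  idx <- lapply(dim(a), seq_len)
  out <- do.call(`[<-`, c(list(out), idx, list(value = a)))
  fft(out)
}

## cross-correlation sums  xc(tau) = sum_x A(x) B(x - tau)
## for all lags -(d-1)..(d-1); A, B same dims. Returns array of dims 2d-1.
.xcorr_fft <- function(FA, FB, d, pd) {
  xc <- Re(fft(FA * Conj(FB), inverse = TRUE)) / prod(pd)
  idx <- lapply(seq_along(d), function(k) {
    lags <- -(d[k] - 1):(d[k] - 1)
    (lags %% pd[k]) + 1
  })
  do.call(`[`, c(list(xc), idx, list(drop = FALSE)))
}

## Normalized-convolution Gaussian smoothing of an array with NA support.
## The kernel is renormalized over the defined support; output voxels with
## less than `support_frac` of the kernel mass defined stay NA.
.smooth_norm <- function(a, sigma, support_frac = 0.05) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  r <- ceiling(3 * sigma)
  pd <- vapply(d + 2 * r, function(n) nextn(n, c(2, 3, 5)), numeric(1))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  kern <- if (length(d) == 3) outer(outer(k1, k1), k1) else outer(k1, k1)
  ## centre the kernel at the origin of the circular convolution
  kpad <- array(0, pd)
  kidx <- lapply(seq_along(d), function(k) ((-r:r) %% pd[k]) + 1)
  kpad <- do.call(`[<-`, c(list(kpad), kidx, list(value = kern)))
  FK <- fft(kpad)
  w <- !is.na(a)
  a0 <- ifelse(w, a, 0)
  num <- Re(fft(.fft_pad(a0, pd) * FK, inverse = TRUE)) / prod(pd)
  den <- Re(fft(.fft_pad(w * 1, pd) * FK, inverse = TRUE)) / prod(pd)
  idx <- lapply(d, seq_len)
  num <- do.call(`[`, c(list(num), idx, list(drop = FALSE)))
  den <- do.call(`[`, c(list(den), idx, list(drop = FALSE)))
  out <- array(NA_real_, d)
  ok <- den >= support_frac
  out[ok] <- num[ok] / den[ok]
  out
}

## ---- spikes -----------------------------------------------------------

#' Extract spikes from an activity trace
#'
#' A spike is assigned at every upward crossing of the threshold: sample t
#' fires iff `gamma(t) > theta` and `gamma(t-1) <= theta`. The spike is
#' stamped with the trajectory position at the crossing sample. The default
#' threshold policy is per-neuron `mean + k * sd` of the activity trace,
#' which is scale-free across neurons of different activity magnitude.
#'
#' @param activity numeric activity trace, aligned with the trajectory.
#' @param traj the [generate_trajectory()] the activity was recorded on.
#' @param threshold explicit threshold; overrides the policy if given.
#' @param policy `"mean_sd"` (mean + k sd), `"quantile"` (k-th quantile) or
#'   `"fraction_max"` (k times the maximum).
#' @param k policy parameter (default 2, i.e. mean + 2 sd).
#' @param neuron optional neuron id stored with the train.
#' @return An object of class `spike_train`: data.frame with columns
#'   `t, x, y, z` plus attributes `threshold` and `neuron`.
#' @export
extract_spikes <- function(activity, traj, threshold = NULL,
                           policy = c("mean_sd", "quantile", "fraction_max"),
                           k = 2, neuron = NA_integer_) {
  policy <- match.arg(policy)
  stopifnot(length(activity) == length(traj$x))
  if (is.null(threshold)) {
    threshold <- switch(policy,
      mean_sd = mean(activity) + k * sd(activity),
      quantile = unname(quantile(activity, k)),
      fraction_max = k * max(activity))
  }
  above <- activity > threshold
  idx <- which(above & !c(TRUE, above[-length(above)]))
  structure(data.frame(t = traj$t[idx], x = traj$x[idx],
                       y = traj$y[idx], z = traj$z[idx]),
            threshold = threshold, neuron = neuron,
            class = c("spike_train", "data.frame"))
}

## ---- rate maps --------------------------------------------------------

.voxel_index <- function(coord, extent, bins) {
  pmin(pmax(floor(coord / extent * bins) + 1L, 1L), bins)
}

## shared smoothing of binned counts and occupancy: the smoothed rate is
## the ratio of Gaussian-smoothed spike counts to Gaussian-smoothed
## occupancy time, which weights every voxel's evidence by the time spent
## there and is robust when single voxels hold only a few samples
.smoothed_rate <- function(counts, occ_s, sigma, support_frac = 0.05) {
  if (sigma <= 0) {
    rate <- array(NA_real_, dim(counts))
    def <- occ_s > 0
    rate[def] <- counts[def] / occ_s[def]
    return(rate)
  }
  sm_c <- .smooth_norm(ifelse(occ_s > 0, counts, NA), sigma, support_frac)
  sm_o <- .smooth_norm(ifelse(occ_s > 0, occ_s, NA), sigma, support_frac)
  rate <- array(NA_real_, dim(counts))
  ok <- !is.na(sm_o) & sm_o > 0
  rate[ok] <- sm_c[ok] / sm_o[ok]
  rate
}

#' 3D firing-rate map
#'
#' Bins the arena into a voxel grid (41^3 by default) and estimates the
#' firing rate as the ratio of Gaussian-smoothed spike counts to
#' Gaussian-smoothed occupancy time (sigma = 3 voxels by default); the
#' kernels are renormalized over the visited support, so unvisited voxels
#' neither contribute nor drag rates down. Voxels whose smoothed
#' neighbourhood holds too little visited support stay undefined. The raw
#' (unsmoothed) rate uses an occupancy floor of `min_visits` samples.
#'
#' @param spikes a [extract_spikes()] result.
#' @param traj the trajectory.
#' @param arena the [arena()]; defaults to the trajectory's.
#' @param sigma smoothing s.d. in voxels.
#' @param min_visits occupancy floor (samples) below which a voxel is
#'   undefined in the raw map.
#' @return Class `rate_map3d`: smoothed `rate` (Hz, NA where undefined),
#'   `rate_raw`, `occupancy` (seconds), `counts`, the arena and `sigma`.
#' @export
rate_map <- function(spikes, traj, arena = traj$arena, sigma = 3,
                     min_visits = 3) {
  b <- arena$bins; e <- arena$extent
  vox_t <- cbind(.voxel_index(traj$x, e[1], b[1]),
                 .voxel_index(traj$y, e[2], b[2]),
                 .voxel_index(traj$z, e[3], b[3]))
  occ <- array(tabulate(
    (vox_t[, 3] - 1L) * b[1] * b[2] + (vox_t[, 2] - 1L) * b[1] + vox_t[, 1],
    nbins = prod(b)), b)
  if (sum(occ) == 0) stop("zero total occupancy")
  counts <- array(0L, b)
  if (nrow(spikes) > 0) {
    vox_s <- cbind(.voxel_index(spikes$x, e[1], b[1]),
                   .voxel_index(spikes$y, e[2], b[2]),
                   .voxel_index(spikes$z, e[3], b[3]))
    counts <- array(tabulate(
      (vox_s[, 3] - 1L) * b[1] * b[2] + (vox_s[, 2] - 1L) * b[1] + vox_s[, 1],
      nbins = prod(b)), b)
  }
  occ_s <- occ * traj$dt
  raw <- array(NA_real_, b)
  def <- occ >= min_visits
  raw[def] <- counts[def] / occ_s[def]
  structure(list(rate = .smoothed_rate(counts, occ_s, sigma),
                 rate_raw = raw,
                 occupancy = occ_s, counts = counts, arena = arena,
                 sigma = sigma, min_visits = min_visits),
            class = "rate_map3d")
}

#' 2D firing-rate map for planar trajectories
#'
#' As [rate_map()] but binning the two in-plane coordinates of a
#' plane-constrained trajectory.
#'
#' @inheritParams rate_map
#' @param plane which coordinate pair to bin: `"xy"`, `"yz"` or `"xz"`.
#' @return Class `rate_map2d`.
#' @export
rate_map_2d <- function(spikes, traj, plane = c("xy", "yz", "xz"),
                        arena = traj$arena, sigma = 3, min_visits = 3) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c(1, 2), yz = c(2, 3), xz = c(1, 3))
  b <- arena$bins[ax]; e <- arena$extent[ax]
  co_t <- cbind(traj$x, traj$y, traj$z)[, ax, drop = FALSE]
  vox_t <- cbind(.voxel_index(co_t[, 1], e[1], b[1]),
                 .voxel_index(co_t[, 2], e[2], b[2]))
  occ <- array(tabulate((vox_t[, 2] - 1L) * b[1] + vox_t[, 1],
                        nbins = prod(b)), b)
  if (sum(occ) == 0) stop("zero total occupancy")
  counts <- array(0L, b)
  if (nrow(spikes) > 0) {
    co_s <- cbind(spikes$x, spikes$y, spikes$z)[, ax, drop = FALSE]
    vox_s <- cbind(.voxel_index(co_s[, 1], e[1], b[1]),
                   .voxel_index(co_s[, 2], e[2], b[2]))
    counts <- array(tabulate((vox_s[, 2] - 1L) * b[1] + vox_s[, 1],
                             nbins = prod(b)), b)
  }
  occ_s <- occ * traj$dt
  raw <- array(NA_real_, b)
  def <- occ >= min_visits
  raw[def] <- counts[def] / occ_s[def]
  structure(list(rate = .smoothed_rate(counts, occ_s, sigma),
                 rate_raw = raw,
                 occupancy = occ_s, counts = counts, arena = arena,
                 plane = plane, sigma = sigma, min_visits = min_visits),
            class = "rate_map2d")
}

## wrap a bare rate array (fixtures, projections) into a map object
.as_rate_map <- function(rate, occupancy = NULL) {
  cls <- if (length(dim(rate)) == 3) "rate_map3d" else "rate_map2d"
  occupancy <- occupancy %||% array(1, dim(rate))
  structure(list(rate = rate, rate_raw = rate, occupancy = occupancy,
                 counts = NULL, arena = NULL, sigma = 0),
            class = cls)
}

## ---- autocorrelation --------------------------------------------------

#' Spatial autocorrelation map
#'
#' Pearson correlation of the (smoothed) rate map with itself at every
#' spatial lag, computed over the overlap of defined voxels with the
#' overlap count as the normalizer. Lags whose overlap falls below
#' `min_overlap` voxels are undefined. Works for 2D and 3D maps; FFT-based.
#'
#' @param map a `rate_map3d` or `rate_map2d` (or a bare array with NAs).
#' @param min_overlap minimum number of overlapping defined voxels per lag.
#' @return Class `autocorr_map`: correlation array `r` (dims `2*d - 1`),
#'   overlap counts `n`, and `lags` per axis.
#' @export
autocorrelate <- function(map, min_overlap = 20) {
  a <- if (is.list(map)) map$rate else map
  d <- dim(a)
  def <- !is.na(a)
  if (sum(def) < 2) stop("need at least 2 defined voxels")
  vals <- a[def]
  if (stats::var(vals) == 0) stop("constant map: autocorrelation undefined")
  pd <- vapply(2 * d - 1, function(n) nextn(n, c(2, 3, 5)), numeric(1))
  A <- ifelse(def, a, 0)
  W <- def * 1
  FA <- .fft_pad(A, pd); FW <- .fft_pad(W, pd); FA2 <- .fft_pad(A^2, pd)
  N <- round(.xcorr_fft(FW, FW, d, pd))
  S1 <- .xcorr_fft(FA, FW, d, pd)
  S2 <- .xcorr_fft(FW, FA, d, pd)
  Q1 <- .xcorr_fft(FA2, FW, d, pd)
  Q2 <- .xcorr_fft(FW, FA2, d, pd)
  S11 <- .xcorr_fft(FA, FA, d, pd)
  v1 <- N * Q1 - S1^2
  v2 <- N * Q2 - S2^2
  r <- array(NA_real_, dim(N))
  ok <- N >= max(2, min_overlap) & v1 > 1e-12 * pmax(N, 1)^2 &
    v2 > 1e-12 * pmax(N, 1)^2
  r[ok] <- ((N * S11 - S1 * S2)[ok]) / sqrt(v1[ok] * v2[ok])
  r[r > 1] <- 1; r[r < -1] <- -1
  structure(list(r = r, n = N, lags = lapply(d, function(k) -(k - 1):(k - 1)),
                 dim = length(d)), class = "autocorr_map")
}

#' Project a 3D rate map onto an orthogonal plane
#'
#' Occupancy-weighted mean of the rate over the collapsed axis.
#'
#' @param map a `rate_map3d`.
#' @param plane `"xy"` (collapse z), `"yz"` (collapse x), `"xz"` (collapse y).
#' @return A `rate_map2d`.
#' @export
project_map <- function(map, plane = c("xy", "yz", "xz")) {
  plane <- match.arg(plane)
  keep <- switch(plane, xy = c(1, 2), yz = c(2, 3), xz = c(1, 3))
  r <- map$rate
  occ <- map$occupancy
  w <- ifelse(is.na(r), 0, occ)
  rw <- ifelse(is.na(r), 0, r) * w
  num <- apply(rw, keep, sum)
  den <- apply(w, keep, sum)
  out <- array(NA_real_, dim(num))
  out[den > 0] <- num[den > 0] / den[den > 0]
  occ2 <- apply(occ, keep, sum)
  m <- .as_rate_map(out, occ2)
  m$plane <- plane
  m
}

## ---- slicing ----------------------------------------------------------

## NA-aware trilinear interpolation; pts in 1-based index coordinates
.interp3 <- function(vol, pts) {
  d <- dim(vol)
  out <- rep(NA_real_, nrow(pts))
  inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2] &
            pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- pmin(floor(p), matrix(rep(d - 1, each = nrow(p)), ncol = 3))
  fr <- p - i0
  acc_v <- numeric(nrow(p)); acc_w <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
         (if (cy) fr[, 2] else 1 - fr[, 2]) *
         (if (cz) fr[, 3] else 1 - fr[, 3])
    v <- vol[cbind(i0[, 1] + cx, i0[, 2] + cy, i0[, 3] + cz)]
    ok <- !is.na(v) & w > 0
    acc_v[ok] <- acc_v[ok] + w[ok] * v[ok]
    acc_w[ok] <- acc_w[ok] + w[ok]
  }
  val <- rep(NA_real_, nrow(p))
  good <- acc_w >= 0.5
  val[good] <- acc_v[good] / acc_w[good]
  out[inside] <- val
  out
}

## deterministic in-plane axes for a plane normal
.plane_axes <- function(normal) {
  n <- unit3(normal)
  ref <- diag(3)[, which.min(abs(n))]
  e1 <- unit3(cross3(n, ref))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

#' Central slice of a 3D autocorrelation map
#'
#' Resamples the autocorrelation volume on the plane through the central
#' peak with the given normal, by trilinear interpolation on a regular
#' in-plane grid. In-plane axes are chosen deterministically from the
#' normal.
#'
#' @param ac an `autocorr_map` from a 3D rate map.
#' @param normal plane normal (3-vector, any norm).
#' @param radius in-plane half-extent in lag units (default 3/4 of the
#'   maximum lag).
#' @param res in-plane sampling step, lag units.
#' @return matrix (class `autocorr_slice`) with attributes `lags`,
#'   `normal`, `e1`, `e2`.
#' @export
slice_autocorr <- function(ac, normal, radius = NULL, res = 1) {
  stopifnot(inherits(ac, "autocorr_map"), ac$dim == 3)
  d <- dim(ac$r)
  ctr <- (d + 1) / 2
  radius <- radius %||% floor(max(ac$lags[[1]]) * 0.75)
  ax <- .plane_axes(normal)
  uv <- seq(-radius, radius, by = res)
  g <- expand.grid(u = uv, v = uv)
  pts <- cbind(ctr[1] + g$u * ax$e1[1] + g$v * ax$e2[1],
               ctr[2] + g$u * ax$e1[2] + g$v * ax$e2[2],
               ctr[3] + g$u * ax$e1[3] + g$v * ax$e2[3])
  vals <- .interp3(ac$r, pts)
  m <- matrix(vals, length(uv), length(uv))
  structure(m, lags = uv, normal = unit3(normal), e1 = ax$e1, e2 = ax$e2,
            class = c("autocorr_slice", "matrix", "array"))
}

#' Write spikes as CSV
#'
#' Columns `t, x, y, z, neuron`.
#' @param spikes a `spike_train`.
#' @param path file path.
#' @export
write_spikes_csv <- function(spikes, path) {
  d <- as.data.frame(spikes)
  d$neuron <- attr(spikes, "neuron")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
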