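## ---- segmentation helpers ---------------------------------------------

## connected components of a logical array mask (4-connectivity in 2D,
## 6-connectivity in 3D); returns integer label array, 0 = background
.label_components <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  lab <- array(0L, d)
  if (length(lin) == 0) return(lab)
  strides <- c(1, cumprod(d))[seq_along(d)]
  pos <- arrayInd(lin, d)
  edges <- NULL
  for (ax in seq_along(d)) {
    ok <- pos[, ax] < d[ax]
    nb <- lin[ok] + strides[ax]
    hit <- mask[nb]
    if (any(hit)) edges <- rbind(edges, cbind(lin[ok][hit], nb[hit]))
  }
  idx_of <- integer(prod(d))
  idx_of[lin] <- seq_along(lin)
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, rbind(idx_of[edges[, 1]], idx_of[edges[, 2]]))
  comp <- igraph::components(g)$membership
  lab[lin] <- as.integer(comp)
  lab
}

## firing fields: connected components above a fraction of the map peak
.fields <- function(rate, field_thresh = 0.3) {
  r <- rate
  r[is.na(r)] <- 0
  pk <- max(r)
  if (pk <= 0) return(list(labels = array(0L, dim(r)), n = 0L, peak = pk))
  lab <- .label_components(r >= field_thresh * pk)
  list(labels = lab, n = max(lab), peak = pk)
}

#' Count firing fields of a rate map
#'
#' Connected components (6-connectivity in 3D, 4 in 2D) above
#' `field_thresh` of the map peak; components holding less than `min_mass`
#' of the total suprathreshold rate mass are ignored as specks.
#'
#' @param map a rate map (or bare array).
#' @param field_thresh field threshold as a fraction of the peak rate.
#' @param min_mass minimum mass fraction for a component to count.
#' @return integer number of fields.
#' @export
count_fields <- function(map, field_thresh = 0.3, min_mass = 0.05) {
  rate <- if (is.list(map)) map$rate else map
  f <- .fields(rate, field_thresh)
  if (f$n == 0) return(0L)
  r0 <- ifelse(is.na(rate), 0, rate)
  mass <- vapply(seq_len(f$n), function(k) sum(r0[f$labels == k]), numeric(1))
  sum(mass >= min_mass * sum(mass))
}

## ---- spatial information ----------------------------------------------

#' Spatial information (bits per spike)
#'
#' `SI = sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` over defined
#' voxels, with `p_i` the occupancy fraction and `lambda` the
#' occupancy-weighted mean rate.
#'
#' @param map a rate map (2D or 3D); its occupancy is used unless
#'   `occupancy` is given.
#' @param occupancy optional occupancy array (seconds), same dims.
#' @return spatial information, bits/spike.
#' @export
spatial_information <- function(map, occupancy = NULL) {
  rate <- if (is.list(map)) map$rate else map
  occupancy <- occupancy %||% (if (is.list(map)) map$occupancy else NULL)
  occupancy <- occupancy %||% array(1, dim(rate))
  ok <- !is.na(rate) & occupancy > 0
  if (!any(ok)) stop("no defined voxels with occupancy")
  p <- occupancy[ok] / sum(occupancy[ok])
  lam <- rate[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) stop("zero mean rate: spatial information undefined")
  rel <- lam / lbar
  pos <- rel > 0
  sum(p[pos] * rel[pos] * log2(rel[pos]))
}

## ---- 2D rotation and gridness -----------------------------------------

## NA-aware bilinear interpolation on a matrix; pts in index coords
.interp2 <- function(m, pts) {
  d <- dim(m)
  out <- rep(NA_real_, nrow(pts))
  inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2]
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- pmin(floor(p), matrix(rep(d - 1, each = nrow(p)), ncol = 2))
  fr <- p - i0
  acc_v <- numeric(nrow(p)); acc_w <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) {
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
         (if (cy) fr[, 2] else 1 - fr[, 2])
    v <- m[cbind(i0[, 1] + cx, i0[, 2] + cy)]
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

## rotate a matrix about its centre by `angle` degrees (bilinear)
.rotate2 <- function(m, angle) {
  d <- dim(m)
  ctr <- (d + 1) / 2
  th <- deg2rad(angle)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  di <- g$i - ctr[1]; dj <- g$j - ctr[2]
  src <- cbind(ctr[1] + cos(th) * di + sin(th) * dj,
               ctr[2] - sin(th) * di + cos(th) * dj)
  matrix(.interp2(m, src), d[1], d[2])
}

## ring-averaged radial profile of a centred correlogram
.radial_profile <- function(m) {
  d <- dim(m)
  ctr <- (d + 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  rad <- round(sqrt((g$i - ctr[1])^2 + (g$j - ctr[2])^2))
  v <- as.vector(m)
  ok <- !is.na(v)
  tapply(v[ok], rad[ok], mean)
}

## local maxima of a correlogram (8-neighbourhood), outside radius r_min
.find_peaks2 <- function(m, r_min = 0, min_val = 0) {
  d <- dim(m)
  ctr <- (d + 1) / 2
  v <- m
  v[is.na(v)] <- -Inf
  is_pk <- array(TRUE, d)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- array(-Inf, d)
    si <- seq_len(d[1]) + di; sj <- seq_len(d[2]) + dj
    ok_i <- si >= 1 & si <= d[1]; ok_j <- sj >= 1 & sj <= d[2]
    sh[ok_i, ok_j] <- v[si[ok_i], sj[ok_j]]
    is_pk <- is_pk & (v >= sh)
  }
  idx <- which(is_pk & v > min_val & is.finite(v), arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  dist <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  idx <- idx[dist > r_min, , drop = FALSE]
  attr(idx, "dist") <- dist[dist > r_min]
  idx
}

#' Hexagonal and square gridness scores
#'
#' From a 2D autocorrelogram: the central peak is masked out to its first
#' radial minimum, the annulus extends to 1.25 times the median distance of
#' the six peaks nearest the centre (or a profile-based fallback when too
#' few peaks are detectable), and the annulus is correlated with itself
#' rotated by 30/60/90/120/150 degrees (hexagonal) and 45/90/135 degrees
#' (square):
#' `HGS = min(cor60, cor120) - max(cor30, cor90, cor150)`;
#' `SGS = cor90 - max(cor45, cor135)`.
#'
#' @param ac a 2D `autocorr_map`, an `autocorr_slice`, or a bare matrix of
#'   correlations at lags.
#' @param annulus optional `c(r_inner, r_outer)` in lag units, overriding
#'   peak detection (used for transection-plane scans).
#' @param min_pixels minimum annulus overlap for a rotation correlation.
#' @return list with `hgs`, `sgs`, `annulus`, `n_peaks`, and the rotation
#'   correlations `cors`.
#' @export
gridness <- function(ac, annulus = NULL, min_pixels = 20) {
  m <- if (inherits(ac, "autocorr_map")) ac$r else unclass(ac)
  m <- as.matrix(m)
  d <- dim(m)
  ctr <- (d + 1) / 2
  maxlag <- min(d - 1) / 2
  n_peaks <- NA_integer_
  if (is.null(annulus)) {
    ## beyond half the maximal lag the overlap support shrinks and its
    ## shape correlates with rotation angle, biasing the correlations;
    ## keep the annulus in the well-supported half
    r_lim <- 0.5 * maxlag
    prof <- .radial_profile(m)
    rr <- as.numeric(names(prof))
    ## central-peak radius: where the radial profile first drops below
    ## 0.2, or its first local minimum if it never does
    drop <- which(prof < 0.2)
    loc_min <- which(diff(sign(diff(prof))) > 0) + 1
    r_in <- if (length(drop) > 0) rr[drop[1]]
            else if (length(loc_min) > 0) rr[loc_min[1]]
            else max(2, 0.15 * maxlag)
    r_in <- min(max(r_in, 2), 0.7 * r_lim)
    pks <- .find_peaks2(m, r_min = r_in, min_val = 0.2)
    n_peaks <- nrow(pks)
    if (n_peaks >= 3) {
      dd <- sort(attr(pks, "dist"))
      six <- dd[seq_len(min(6, length(dd)))]
      r_out <- min(1.25 * stats::median(six), r_lim)
    } else {
      r_out <- min(3 * r_in, r_lim)
    }
    if (r_out <= r_in + 2) r_out <- min(r_in + 3, maxlag)
    annulus <- c(r_in, r_out)
    ## strength of the secondary (first non-central) correlation ring:
    ## the ring-averaged profile beyond the central peak; a genuine
    ## periodic structure lifts a whole ring, isolated noise bumps do not
    ring_max <- suppressWarnings(max(prof[rr > r_in & rr <= r_lim]))
    if (!is.finite(ring_max)) ring_max <- NA_real_
  }
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  rad <- sqrt((g$i - ctr[1])^2 + (g$j - ctr[2])^2)
  ring <- rad >= annulus[1] & rad <= annulus[2]
  base <- as.vector(m)
  angles <- c(30, 45, 60, 90, 120, 135, 150)
  cors <- vapply(angles, function(a) {
    rot <- as.vector(.rotate2(m, a))
    ok <- ring & !is.na(base) & !is.na(rot)
    if (sum(ok) < min_pixels) return(NA_real_)
    if (sd(base[ok]) == 0 || sd(rot[ok]) == 0) return(NA_real_)
    cor(base[ok], rot[ok])
  }, numeric(1))
  names(cors) <- paste0("r", angles)
  hgs <- min(cors["r60"], cors["r120"]) -
    max(cors["r30"], cors["r90"], cors["r150"])
  sgs <- cors["r90"] - max(cors["r45"], cors["r135"])
  if (!exists("ring_max", inherits = FALSE)) ring_max <- NA_real_
  list(hgs = unname(hgs), sgs = unname(sgs), annulus = annulus,
       n_peaks = n_peaks, ring_max = ring_max, cors = cors)
}

## ---- border score ------------------------------------------------------

#' Border score of a 2D rate map
#'
#' `BS = (C_M - d_M) / (C_M + d_M)` where `C_M` is the maximal fraction of
#' any single wall covered by one firing field and `d_M` is the
#' rate-weighted mean distance of map bins to their nearest wall,
#' normalized by half the shorter side so that BS lies in \[-1, 1\].
#'
#' @param map a `rate_map2d` (or bare matrix).
#' @param field_thresh field threshold, fraction of peak.
#' @return border score in \[-1, 1\], or NA when the map has no field.
#' @export
border_score <- function(map, field_thresh = 0.3) {
  rate <- if (is.list(map)) map$rate else map
  d <- dim(rate)
  f <- .fields(rate, field_thresh)
  if (f$n == 0) return(NA_real_)
  ## C_M: max fraction of one wall covered by a single field
  cm <- 0
  for (k in seq_len(f$n)) {
    sel <- f$labels == k
    cm <- max(cm,
              sum(sel[1, ]) / d[2], sum(sel[d[1], ]) / d[2],
              sum(sel[, 1]) / d[1], sum(sel[, d[2]]) / d[1])
  }
  ## d_M: rate-weighted mean distance to the nearest wall
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  dist_wall <- pmin(g$i - 1, d[1] - g$i, g$j - 1, d[2] - g$j)
  w <- as.vector(ifelse(is.na(rate), 0, rate))
  if (sum(w) <= 0) return(NA_real_)
  dm <- sum(w * dist_wall) / sum(w) / ((min(d) - 1) / 2)
  if (cm + dm == 0) return(NA_real_)
  (cm - dm) / (cm + dm)
}

#' Border scores of a 3D rate map on the orthogonal planes
#'
#' Border score on each orthogonal projection (XY, YZ, XZ); the aggregate
#' is the mean of the top two. A neuron qualifies as a 3D border cell when
#' the score exceeds the threshold on any two of the planes.
#'
#' @param map a `rate_map3d`.
#' @param bs_thr border-score threshold for the border-cell flag.
#' @param field_thresh field threshold, fraction of peak.
#' @return list with `bs_xy`, `bs_yz`, `bs_xz`, `bs_top2`, `is_border`.
#' @export
border_score_3d <- function(map, bs_thr = 0.5228, field_thresh = 0.3) {
  bs <- vapply(c("xy", "yz", "xz"), function(pl)
    border_score(project_map(map, pl), field_thresh), numeric(1))
  srt <- sort(bs, decreasing = TRUE, na.last = TRUE)
  top2 <- mean(srt[1:2], na.rm = TRUE)
  list(bs_xy = bs[["xy"]], bs_yz = bs[["yz"]], bs_xz = bs[["xz"]],
       bs_top2 = top2, is_border = sum(bs > bs_thr, na.rm = TRUE) >= 2)
}

## ---- plane index -------------------------------------------------------

## axis-robust planarity: 1 - lambda_min / lambda_mid of the weighted
## coordinate covariance. The dependent-axis regression R^2 is
## blind to planes normal to a coordinate axis, whose dependent variable
## carries only the slab-thickness variance; the total-least-squares form
## measures thinness relative to in-plane extent for any orientation.
.planarity_tls <- function(coords, w) {
  mu <- colSums(coords * w) / sum(w)
  cc <- sweep(coords, 2, mu)
  S <- crossprod(cc * sqrt(w / sum(w)))
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  if (lam[2] < 1e-10) return(list(r2 = 1, normal = ev$vectors[, 3],
                                  centroid = mu, lam = lam))
  list(r2 = max(0, 1 - lam[3] / lam[2]), normal = ev$vectors[, 3],
       centroid = mu, lam = lam)
}

## TLS planarity only overrides the regression R^2 for genuinely thin
## fields (out-of-plane spread under ~2 voxels); thick blobs otherwise
## score spuriously planar because their smallest axis is still the
## smallest eigenvalue
.tls_r2_gated <- function(tls, thick_limit = 4) {
  if (tls$lam[3] < thick_limit) tls$r2 else 0
}

## weighted least-squares plane fit: coords k x 3, dep = axis predicted
.fit_plane <- function(coords, w, dep_axis) {
  dep <- coords[, dep_axis]
  reg <- coords[, -dep_axis, drop = FALSE]
  sst <- sum(w * (dep - weighted.mean(dep, w))^2)
  if (sst < 1e-10) {
    ## degenerate geometry: all mass at one level of the dependent axis --
    ## a perfectly flat axis-aligned plane
    return(list(coef = c(weighted.mean(dep, w), 0, 0), ssr = 0, sst = sst,
                r2 = 1, dep_axis = dep_axis))
  }
  fit <- lm(dep ~ reg[, 1] + reg[, 2], weights = w)
  ssr <- sum(w * fit$residuals^2)
  list(coef = unname(coef(fit)), ssr = ssr, sst = sst,
       r2 = max(0, 1 - ssr / sst), dep_axis = dep_axis)
}

#' Plane index of a 3D firing field
#'
#' Weighted least-squares plane fit (`y_hat = a0 + a1 x1 + a2 x2`) to the
#' rate-weighted suprathreshold voxel coordinates; each of the three axes
#' is tried as the dependent variable and the best fit is kept. The plane
#' index is the goodness of fit `R^2 = 1 - SSR/SST`.
#'
#' @param map a `rate_map3d` (or bare 3D array).
#' @param field_thresh field threshold, fraction of peak.
#' @return list with the winning `fit` (class `plane_fit`) and `pi` (R^2);
#'   `pi` is NA when fewer than 4 suprathreshold voxels exist.
#' @export
plane_index <- function(map, field_thresh = 0.3) {
  rate <- if (is.list(map)) map$rate else map
  r0 <- ifelse(is.na(rate), 0, rate)
  pk <- max(r0)
  if (pk <= 0) return(list(fit = NULL, pi = NA_real_))
  sel <- which(r0 >= field_thresh * pk)
  if (length(sel) < 4) return(list(fit = NULL, pi = NA_real_))
  coords <- arrayInd(sel, dim(r0))
  w <- r0[sel]
  fits <- lapply(1:3, function(ax) .fit_plane(coords, w, ax))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "r2"))]]
  tls <- .planarity_tls(coords, w)
  best$r2_tls <- .tls_r2_gated(tls)
  best$normal <- tls$normal
  class(best) <- "plane_fit"
  list(fit = best, pi = max(best$r2, best$r2_tls))
}

#' Detect multiple firing-field planes (stack cells)
#'
#' Segments the suprathreshold voxels into connected components, fits a
#' rate-weighted plane to each sufficiently large component, keeps fits
#' whose R^2 exceeds `pi_thr`, and merges coplanar components (same
#' dependent axis, near-parallel, similar offset) before refitting.
#'
#' @param map a `rate_map3d`.
#' @param field_thresh field threshold, fraction of peak.
#' @param pi_thr acceptance threshold on the per-plane R^2.
#' @param max_planes maximum number of planes returned.
#' @param min_voxels minimum component size to attempt a fit.
#' @return list of accepted `plane_fit` objects (possibly empty), ordered
#'   by component mass.
#' @export
stack_detect <- function(map, field_thresh = 0.3, pi_thr = 0.7528,
                         max_planes = 3, min_voxels = 8) {
  rate <- if (is.list(map)) map$rate else map
  r0 <- ifelse(is.na(rate), 0, rate)
  f <- .fields(r0, field_thresh)
  if (f$n == 0) return(list())
  comps <- list()
  for (k in seq_len(f$n)) {
    sel <- which(f$labels == k)
    if (length(sel) < min_voxels) next
    coords <- arrayInd(sel, dim(r0))
    w <- r0[sel]
    fits <- lapply(1:3, function(ax) .fit_plane(coords, w, ax))
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "r2"))]]
    tls <- .planarity_tls(coords, w)
    best$r2 <- max(best$r2, .tls_r2_gated(tls))
    best$normal <- tls$normal
    if (best$r2 > pi_thr)
      comps[[length(comps) + 1]] <-
        list(fit = best, coords = coords, w = w, mass = sum(w))
  }
  if (length(comps) == 0) return(list())
  ## merge coplanar components: near-parallel normals, similar offset
  merged <- list()
  used <- rep(FALSE, length(comps))
  cen_of <- function(cmp) colSums(cmp$coords * cmp$w) / sum(cmp$w)
  for (i in seq_along(comps)) {
    if (used[i]) next
    grp <- i
    for (j in seq_along(comps)) {
      if (j <= i || used[j]) next
      ni <- comps[[i]]$fit$normal
      nj <- comps[[j]]$fit$normal
      if (plane_angle(ni, nj) > 10) next
      off <- abs(sum((cen_of(comps[[i]]) - cen_of(comps[[j]])) * ni))
      if (off <= 2) { grp <- c(grp, j); used[j] <- TRUE }
    }
    used[grp] <- TRUE
    coords <- do.call(rbind, lapply(comps[grp], `[[`, "coords"))
    w <- unlist(lapply(comps[grp], `[[`, "w"))
    fits <- lapply(1:3, function(ax) .fit_plane(coords, w, ax))
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "r2"))]]
    tls <- .planarity_tls(coords, w)
    best$r2 <- max(best$r2, .tls_r2_gated(tls))
    best$normal <- tls$normal
    class(best) <- "plane_fit"
    merged[[length(merged) + 1]] <- list(fit = best, mass = sum(w))
  }
  merged <- merged[order(vapply(merged, `[[`, numeric(1), "mass"),
                         decreasing = TRUE)]
  lapply(utils::head(merged, max_planes), `[[`, "fit")
}

## ---- ellipsoid fit -----------------------------------------------------

#' Axis-aligned ellipsoid fit of a firing field
#'
#' Fits `(x-cx)^2/rx^2 + (y-cy)^2/ry^2 + (z-cz)^2/rz^2 = 1` to the boundary
#' voxels of the largest firing field by nonlinear least squares,
#' initialized from the field's second-moment ellipsoid. The elongation
#' index `xi` is the ratio of the largest to the smallest semi-axis; a
#' field is isotropic when `xi` falls below the isotropy threshold (1.38).
#'
#' @param map a `rate_map3d` (or bare 3D array).
#' @param field_thresh field threshold, fraction of peak.
#' @param min_voxels minimum field size to attempt a fit.
#' @return list with `centre`, `semi_axes` (voxel units), `xi`, `residual`,
#'   and `fallback` (TRUE when the moment ellipsoid was used because the
#'   least-squares fit failed to converge). NA fields when no usable field.
#' @export
ellipsoid_fit <- function(map, field_thresh = 0.3, min_voxels = 10) {
  rate <- if (is.list(map)) map$rate else map
  r0 <- ifelse(is.na(rate), 0, rate)
  f <- .fields(r0, field_thresh)
  empty <- list(centre = rep(NA_real_, 3), semi_axes = rep(NA_real_, 3),
                xi = NA_real_, residual = NA_real_, fallback = FALSE)
  if (f$n == 0) return(empty)
  mass <- vapply(seq_len(f$n), function(k) sum(r0[f$labels == k]),
                 numeric(1))
  k <- which.max(mass)
  sel <- which(f$labels == k)
  if (length(sel) < min_voxels) return(empty)
  coords <- arrayInd(sel, dim(r0))
  w <- r0[sel]
  cen0 <- colSums(coords * w) / sum(w)
  sds <- sqrt(colSums(w * sweep(coords, 2, cen0)^2) / sum(w))
  r_mom <- pmax(sqrt(5) * sds, 0.5)  # uniform solid: var = r^2 / 5
  ## boundary voxels: field voxels with a 6-neighbour outside the field
  d <- dim(r0)
  infield <- array(FALSE, d)
  infield[sel] <- TRUE
  interior <- array(TRUE, d)
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    shifted <- array(FALSE, d)
    src <- lapply(seq_along(d), seq_len)
    dst <- src
    n_ax <- d[ax]
    src[[ax]] <- if (sgn > 0) 1:(n_ax - 1) else 2:n_ax
    dst[[ax]] <- if (sgn > 0) 2:n_ax else 1:(n_ax - 1)
    shifted <- do.call(`[<-`, c(list(shifted), dst,
                                list(value = do.call(`[`, c(list(infield),
                                                            src)))))
    interior <- interior & shifted
  }
  on_boundary <- infield & !interior
  bnd <- which(on_boundary[sel])
  bnd <- coords[bnd, , drop = FALSE]
  if (nrow(bnd) < 6)
    return(list(centre = cen0, semi_axes = r_mom,
                xi = max(r_mom) / min(r_mom), residual = NA_real_,
                fallback = TRUE))
  resid_fun <- function(par) {
    cen <- par[1:3]; rr <- par[4:6]
    (bnd[, 1] - cen[1])^2 / rr[1]^2 + (bnd[, 2] - cen[2])^2 / rr[2]^2 +
      (bnd[, 3] - cen[3])^2 / rr[3]^2 - 1
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(cen0, r_mom), fn = resid_fun,
                       lower = c(rep(-Inf, 3), rep(0.5, 3)),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$par)))
    return(list(centre = cen0, semi_axes = r_mom,
                xi = max(r_mom) / min(r_mom), residual = NA_real_,
                fallback = TRUE))
  rr <- abs(fit$par[4:6])
  list(centre = fit$par[1:3], semi_axes = rr, xi = max(rr) / min(rr),
       residual = sum(fit$fvec^2), fallback = FALSE)
}

## ---- thresholds --------------------------------------------------------

#' Default classification thresholds
#'
#' The fixed threshold set: spatial information 1.0609 bits/spike,
#' hexagonal gridness 0.1686, square gridness 0.1952, border score 0.5228,
#' plane index 0.7528, elongation-index isotropy 1.38. `place_si` is the
#' extra spatial-information requirement for place cells; by default it
#' equals the spatial threshold (a shuffling-based estimate can be plugged
#' in via [shuffle_threshold()]).
#'
#' @param ... named overrides of individual thresholds.
#' @return list of class `threshold_set`.
#' @export
default_thresholds <- function(...) {
  thr <- list(si = 1.0609, hgs = 0.1686, sgs = 0.1952, bs = 0.5228,
              pi = 0.7528, xi = 1.38, place_si = 1.0609,
              provenance = "fixed-table")
  ov <- list(...)
  thr[names(ov)] <- ov
  structure(thr, class = "threshold_set")
}

#' Shuffling-based significance threshold for a spatial descriptor
#'
#' Circularly time-shifts the spike train relative to the trajectory by a
#' uniform random offset of at least `min_shift` seconds, recomputes the
#' descriptor for each shuffle, and returns the stated percentile of the
#' shuffled distribution.
#'
#' @param spikes a `spike_train`.
#' @param traj the trajectory.
#' @param descriptor function `(spikes, traj) -> numeric` computing the
#'   descriptor.
#' @param n_shuffles number of shuffles (>= 100 recommended).
#' @param percentile percentile of the shuffled distribution returned.
#' @param min_shift minimum time shift, seconds.
#' @param min_spikes below this spike count the threshold is undefined (NA).
#' @return the percentile of the shuffled descriptor values.
#' @export
shuffle_threshold <- function(spikes, traj, descriptor, n_shuffles = 100,
                              percentile = 0.95, min_shift = 20,
                              min_spikes = 30) {
  if (nrow(spikes) < min_spikes) return(NA_real_)
  t_tot <- length(traj$x) * traj$dt
  if (t_tot <= 2 * min_shift) stop("trajectory too short for the minimum shift")
  vals <- vapply(seq_len(n_shuffles), function(s) {
    shift <- runif(1, min_shift, t_tot - min_shift)
    tt <- (spikes$t + shift) %% t_tot
    idx <- pmin(floor(tt / traj$dt) + 1L, length(traj$x))
    sh <- structure(data.frame(t = tt, x = traj$x[idx], y = traj$y[idx],
                               z = traj$z[idx]),
                    class = c("spike_train", "data.frame"))
    descriptor(sh, traj)
  }, numeric(1))
  structure(unname(quantile(vals, percentile, na.rm = TRUE)),
            values = vals)
}


#' Shuffling-calibrated significance thresholds
#'
#' Spatial information and the border score have pipeline-dependent
#' baselines: SI scales with spike counts, binning and smoothing, and the
#' border score of a dense, weakly modulated map sits near 0.5 by
#' construction (a map-wide field gives coverage ~ 1 while the normalized
#' mean wall distance is ~ 1/3). Their significance thresholds are
#' therefore estimated the way such thresholds are defined in the first
#' place: circularly time-shift each neuron's spike train, recompute the
#' descriptor per shuffle, and take a high percentile of the pooled
#' shuffled distribution. The rotation-correlation (HGS/SGS), plane-index
#' and elongation thresholds have stable baselines and keep their fixed
#' values.
#'
#' @param gamma T x n activity matrix.
#' @param traj the trajectory the activities were recorded on.
#' @param neurons neuron indices to include (default: an evenly spaced
#'   subset of 10).
#' @param n_shuffles shuffles per neuron.
#' @param percentile percentile of the pooled shuffled distributions.
#' @param sigma rate-map smoothing, voxels.
#' @return list with elements `si` and `bs` (calibrated thresholds).
#' @export
calibrate_thresholds <- function(gamma, traj, neurons = NULL,
                                 n_shuffles = 20, percentile = 0.95,
                                 sigma = 3) {
  neurons <- neurons %||%
    unique(round(seq(1, ncol(gamma), length.out = min(10, ncol(gamma)))))
  t_tot <- length(traj$x) * traj$dt
  si_vals <- c(); bs_vals <- c()
  for (i in neurons) {
    sp <- extract_spikes(gamma[, i], traj, neuron = i)
    if (nrow(sp) < 30) next
    for (s in seq_len(n_shuffles)) {
      shift <- runif(1, 20, t_tot - 20)
      tt <- (sp$t + shift) %% t_tot
      idx <- pmin(floor(tt / traj$dt) + 1L, length(traj$x))
      sh <- structure(data.frame(t = tt, x = traj$x[idx], y = traj$y[idx],
                                 z = traj$z[idx]),
                      class = c("spike_train", "data.frame"))
      m <- tryCatch(rate_map(sh, traj, sigma = sigma),
                    error = function(e) NULL)
      if (is.null(m)) next
      si_vals <- c(si_vals, tryCatch(spatial_information(m),
                                     error = function(e) NA_real_))
      bs_vals <- c(bs_vals, tryCatch(border_score_3d(m)$bs_top2,
                                     error = function(e) NA_real_))
    }
  }
  list(si = if (length(si_vals)) unname(quantile(si_vals, percentile,
                                                 na.rm = TRUE)) else NA_real_,
       bs = if (length(bs_vals)) unname(quantile(bs_vals, percentile,
                                                 na.rm = TRUE)) else NA_real_)
}
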