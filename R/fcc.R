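## package-local cache (analytic FCC reference statistics)
.sn3d_cache <- new.env(parent = emptyenv())

#' Analytic face-centered-cubic lattice rate map
#'
#' Builds an ideal FCC firing map as the sum of four 3D cosine plane waves
#' whose wave vectors point to alternating vertices of a cube (pairwise
#' angles of ~109.47 degrees), rectified to non-negative. The peaks form
#' ABC-stacked hexagonal layers; serves as the FCC-score denominator and as
#' a scoring fixture.
#'
#' @param shape voxel grid dims (length 3).
#' @param wavelength plane-wave wavelength in voxels.
#' @return a `rate_map3d` with uniform occupancy; attribute `wave_vectors`
#'   holds the four wave vectors (rows).
#' @export
analytic_fcc <- function(shape = c(41, 41, 41), wavelength = 12) {
  if (wavelength > min(shape)) stop("wavelength does not fit the grid")
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  k <- 2 * pi / wavelength
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  rho <- 0
  for (i in 1:4)
    rho <- rho + cos(k * (g$x * dirs[i, 1] + g$y * dirs[i, 2] +
                            g$z * dirs[i, 3]))
  rho <- pmax(rho, 0)
  m <- .as_rate_map(array(rho, shape))
  attr(m, "wave_vectors") <- k * dirs
  m
}

#' Fibonacci-distributed hemisphere normals
#'
#' Approximately uniform directions on the upper hemisphere, used as the
#' transection-plane grid for the FCC symmetry scan.
#'
#' @param n number of normals.
#' @return n x 3 matrix of unit normals (z >= 0).
#' @export
fibonacci_normals <- function(n = 500) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

## HGS of every transection slice of a 3D autocorrelogram, with a shared
## profile-based annulus
.slice_hgs_scan <- function(ac, normals, radius = NULL, annulus = NULL) {
  radius <- radius %||% floor(max(ac$lags[[1]]) * 0.75)
  if (is.null(annulus)) {
    ## central-peak radius from the 3D radial profile
    d <- dim(ac$r)
    ctr <- (d + 1) / 2
    sl <- slice_autocorr(ac, c(0, 0, 1), radius = radius)
    g0 <- gridness(sl)
    annulus <- g0$annulus
  }
  hgs <- vapply(seq_len(nrow(normals)), function(i) {
    sl <- slice_autocorr(ac, normals[i, ], radius = radius)
    gridness(sl, annulus = annulus)$hgs
  }, numeric(1))
  list(hgs = hgs, annulus = annulus, radius = radius)
}

## FCC plane statistic: best-HGS reference slice, then the best triplet of
## candidate planes at 72 deg from the reference and pairwise ~72 deg
## apart; returns the mean HGS of the (up to 3) selected planes.
.fcc_statistic <- function(ac, normals, angle_tol = 3, radius = NULL,
                           annulus = NULL) {
  scan <- .slice_hgs_scan(ac, normals, radius = radius, annulus = annulus)
  hgs <- scan$hgs
  ok <- which(!is.na(hgs))
  if (length(ok) == 0) return(list(stat = NA_real_, ref = NA_integer_))
  ref <- ok[which.max(hgs[ok])]
  ang_ref <- vapply(seq_len(nrow(normals)), function(i)
    plane_angle(normals[ref, ], normals[i, ]), numeric(1))
  cand <- setdiff(which(abs(ang_ref - 72) <= angle_tol & !is.na(hgs)), ref)
  if (length(cand) == 0)
    return(list(stat = 0, ref = ref, hgs = hgs))
  ## greedy pairwise-compatible selection, best HGS first
  cand <- cand[order(hgs[cand], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in cand) {
    if (length(chosen) == 3) break
    compat <- all(vapply(chosen, function(j)
      abs(plane_angle(normals[i, ], normals[j, ]) - 72) <= 2 * angle_tol,
      logical(1)))
    if (compat) chosen <- c(chosen, i)
  }
  list(stat = mean(hgs[chosen]), ref = ref, planes = chosen, hgs = hgs)
}

#' FCC symmetry score of a 3D autocorrelation map
#'
#' Scans transection planes through the central peak, takes the slice with
#' the highest hexagonal gridness as the reference plane, finds the
#' candidate planes at 72 degrees from the reference (and approximately 72
#' degrees from one another), and averages the top three of their HGS
#' values. The score is this statistic divided by the same statistic
#' computed on the autocorrelogram of an analytic FCC lattice; negative
#' values are clamped to zero and the score is capped at 1.
#'
#' @param ac an `autocorr_map` of a 3D rate map.
#' @param n_normals number of Fibonacci transection-plane normals.
#' @param angle_tol tolerance (degrees) around the 72-degree plane angles.
#' @param wavelength wavelength (voxels) of the analytic FCC reference.
#' @param radius slice half-extent in lag voxels.
#' @return list with `fcc` (in \[0, 1\]), the raw `stat`, the reference
#'   statistic `stat_ref`, and the reference-plane index.
#' @export
fcc_score <- function(ac, n_normals = 500, angle_tol = 3, wavelength = 12,
                      radius = NULL) {
  stopifnot(inherits(ac, "autocorr_map"), ac$dim == 3)
  if (n_normals < 1) stop("empty plane grid")
  normals <- fibonacci_normals(n_normals)
  key <- sprintf("fccref_%d_%g_%g_%s", n_normals, angle_tol, wavelength,
                 paste(dim(ac$r), collapse = "x"))
  ref_stat <- .sn3d_cache[[key]]
  if (is.null(ref_stat)) {
    fcc_map <- analytic_fcc(shape = rep(41, 3), wavelength = wavelength)
    fcc_ac <- autocorrelate(fcc_map)
    ref_stat <- .fcc_statistic(fcc_ac, normals, angle_tol,
                               radius = radius)$stat
    .sn3d_cache[[key]] <- ref_stat
  }
  res <- .fcc_statistic(ac, normals, angle_tol, radius = radius)
  if (is.na(res$stat) || is.na(ref_stat) || ref_stat <= 0)
    return(list(fcc = NA_real_, stat = res$stat, stat_ref = ref_stat,
                ref = res$ref))
  list(fcc = min(1, max(0, res$stat / ref_stat)), stat = res$stat,
       stat_ref = ref_stat, ref = res$ref)
}
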