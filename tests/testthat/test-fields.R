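simple_traj <- function(n = 2000, seed = 13, mode = "volumetric") {
  generate_trajectory(trajectory_config(n_steps = n, seed = seed,
                                        mode = mode))
}

test_that("spikes are upward threshold crossings stamped with position", {
  tr <- simple_traj(300)
  ## constant subthreshold activity: no spikes
  sp <- extract_spikes(rep(0.1, 300), tr, threshold = 0.5)
  expect_equal(nrow(sp), 0)
  ## sin(2*pi*t) over 3 s at dt = 0.01, threshold 0.5: one crossing/cycle
  act <- sin(2 * pi * tr$t)
  sp <- extract_spikes(act, tr, threshold = 0.5)
  expect_equal(nrow(sp), 3)
  ## brute-force scan oracle on a rough random trace
  set.seed(77)
  act <- rnorm(300)
  th <- 0.8
  sp <- extract_spikes(act, tr, threshold = th)
  oracle <- sum(vapply(2:300, function(t)
    act[t] > th && act[t - 1] <= th, logical(1))) +
    as.integer(act[1] > th)
  expect_equal(nrow(sp), oracle)
})

test_that("rate-map binning conserves spike counts", {
  tr <- simple_traj(20000)
  set.seed(5)
  idx <- sample(20000, 400)
  sp <- structure(data.frame(t = tr$t[idx], x = tr$x[idx], y = tr$y[idx],
                             z = tr$z[idx]),
                  class = c("spike_train", "data.frame"))
  m <- rate_map(sp, tr, sigma = 3)
  expect_equal(sum(m$counts), 400)
  ## no spikes: all-defined voxels read zero
  m0 <- rate_map(sp[0, ], tr)
  expect_true(all(m0$rate_raw[!is.na(m0$rate_raw)] == 0))
  ## rates are non-negative after smoothing
  expect_true(all(m$rate[!is.na(m$rate)] >= -1e-12))
})

test_that("normalized-convolution smoothing preserves mass approximately", {
  a <- array(0, c(21, 21, 21))
  a[11, 11, 11] <- 10
  sm <- spatialnet3d:::.smooth_norm(a, sigma = 2)
  expect_true(all(sm >= -1e-12))
  expect_equal(sum(sm), sum(a), tolerance = 0.01)
})

test_that("autocorrelation matches the brute-force lag formula", {
  set.seed(9)
  a <- array(runif(125), c(5, 5, 5))
  a[sample(125, 10)] <- NA
  ac <- autocorrelate(a, min_overlap = 5)
  ## brute-force Pearson at every lag over the defined overlap
  lags <- -4:4
  for (tx in lags) for (ty in c(-2, 0, 3)) for (tz in c(-4, 0, 2)) {
    vals1 <- c(); vals2 <- c()
    for (x in 1:5) for (y in 1:5) for (z in 1:5) {
      xs <- x - tx; ys <- y - ty; zs <- z - tz
      if (xs >= 1 && xs <= 5 && ys >= 1 && ys <= 5 && zs >= 1 && zs <= 5 &&
          !is.na(a[x, y, z]) && !is.na(a[xs, ys, zs])) {
        vals1 <- c(vals1, a[x, y, z]); vals2 <- c(vals2, a[xs, ys, zs])
      }
    }
    i <- tx + 5; j <- ty + 5; k <- tz + 5
    M <- length(vals1)
    if (M < 5 || sd(vals1) == 0 || sd(vals2) == 0) {
      expect_true(is.na(ac$r[i, j, k]))
    } else {
      num <- M * sum(vals1 * vals2) - sum(vals1) * sum(vals2)
      den <- sqrt((M * sum(vals1^2) - sum(vals1)^2) *
                    (M * sum(vals2^2) - sum(vals2)^2))
      expect_equal(ac$r[i, j, k], num / den, tolerance = 1e-10)
    }
  }
})

test_that("autocorrelation is 1 at zero lag and symmetric", {
  set.seed(10)
  a <- array(runif(9^3), c(9, 9, 9))
  ac <- autocorrelate(a, min_overlap = 10)
  ctr <- c(9, 9, 9)
  expect_equal(ac$r[ctr[1], ctr[2], ctr[3]], 1, tolerance = 1e-10)
  rr <- ac$r
  rev_r <- rr[rev(seq_len(17)), rev(seq_len(17)), rev(seq_len(17))]
  expect_equal(rr, rev_r, tolerance = 1e-10)
  ## degenerate constant map is rejected
  expect_error(autocorrelate(array(1, c(5, 5, 5))), "constant")
})

test_that("projections collapse the chosen axis with occupancy weights", {
  ## mass confined to one z-slab projects to that slab's XY pattern
  a <- array(NA_real_, c(15, 15, 15))
  a[, , 8] <- matrix(runif(225), 15, 15)
  a[, , -8] <- 0
  m <- spatialnet3d:::.as_rate_map(a)
  pj <- project_map(m, "xy")
  expect_equal(pj$rate, a[, , 8] / 15, tolerance = 1e-12)
  ## spherically symmetric blob projects to concentric discs on all planes
  blob <- blob_map_3d(c(21, 21, 21), radius = 4)
  for (pl in c("xy", "yz", "xz")) {
    p <- project_map(blob, pl)
    expect_equal(p$rate, t(p$rate), tolerance = 1e-9)  # radial symmetry
    expect_equal(which(p$rate == max(p$rate)), 221)    # centred peak
  }
})

test_that("slices through the autocorrelogram behave geometrically", {
  blob <- blob_map_3d(c(21, 21, 21), radius = 4)
  ac <- autocorrelate(blob, min_overlap = 10)
  sl_z <- slice_autocorr(ac, c(0, 0, 1), radius = 10)
  ## z-normal slice equals the central tau_z = 0 section (up to in-plane
  ## orientation); compare rotation-invariant radial profiles
  sec <- ac$r[11:31, 11:31, 21]
  expect_equal(sort(spatialnet3d:::.radial_profile(unclass(sl_z))),
               sort(spatialnet3d:::.radial_profile(sec)), tolerance = 0.02)
  ## exactly isotropic Gaussian correlogram: all slice orientations agree
  lag <- -15:15
  g3 <- expand.grid(x = lag, y = lag, z = lag)
  iso <- structure(list(
    r = array(exp(-(g3$x^2 + g3$y^2 + g3$z^2) / (2 * 5^2)), rep(31, 3)),
    n = array(100, rep(31, 3)), lags = list(lag, lag, lag), dim = 3),
    class = "autocorr_map")
  s1 <- slice_autocorr(iso, c(1, 0, 0), radius = 8)
  s2 <- slice_autocorr(iso, c(1, 1, 1), radius = 8)
  s3 <- slice_autocorr(iso, c(0, 1, 2), radius = 8)
  expect_equal(unclass(s1), unclass(s2), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(unclass(s1), unclass(s3), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("2D rate maps bin the in-plane coordinates", {
  tr <- simple_traj(20000, mode = "plane-xy")
  set.seed(6)
  idx <- sample(20000, 300)
  sp <- structure(data.frame(t = tr$t[idx], x = tr$x[idx], y = tr$y[idx],
                             z = tr$z[idx]),
                  class = c("spike_train", "data.frame"))
  m <- rate_map_2d(sp, tr, "xy")
  expect_equal(dim(m$rate), c(41, 41))
  expect_equal(sum(m$counts), 300)
})
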