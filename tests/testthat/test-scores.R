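test_that("spatial information has its closed-form values", {
  ## uniform map: zero information
  m <- spatialnet3d:::.as_rate_map(array(2, c(4, 4, 4)))
  expect_equal(spatial_information(m), 0)
  ## all firing in 1 of 64 equally occupied voxels: log2(64) = 6 bits/spike
  a <- array(0, c(4, 4, 4))
  a[1, 1, 1] <- 1
  m <- spatialnet3d:::.as_rate_map(a)
  expect_equal(spatial_information(m), 6)
  ## zero mean rate is an error
  expect_error(spatial_information(spatialnet3d:::.as_rate_map(
    array(0, c(3, 3, 3)))), "zero mean rate")
})

test_that("gridness separates hexagonal, square and isotropic maps", {
  hex <- lattice_map_2d("hex", c(41, 41), wavelength = 12)
  gs_hex <- gridness(autocorrelate(hex, min_overlap = 10))
  expect_gt(gs_hex$hgs, 0.1686)
  expect_lt(gs_hex$sgs, 0.1952)

  sq <- lattice_map_2d("square", c(41, 41), wavelength = 12)
  gs_sq <- gridness(autocorrelate(sq, min_overlap = 10))
  expect_gt(gs_sq$sgs, 0.1952)
  expect_lt(gs_sq$hgs, 0)

  ## radially symmetric (ringed) correlogram: all rotations equal, ~ 0
  g <- expand.grid(i = -20:20, j = -20:20)
  d <- sqrt(g$i^2 + g$j^2)
  iso_m <- matrix(cos(2 * pi * d / 9) * exp(-d / 15), 41, 41)
  iso <- gridness(iso_m)
  expect_lt(abs(iso$hgs), 0.1)
  expect_lt(abs(iso$sgs), 0.1)
})

test_that("hexagonality is invariant under 90-degree map rotation", {
  hex <- lattice_map_2d("hex", c(41, 41), wavelength = 12, angle = 13)
  rot <- spatialnet3d:::.as_rate_map(t(hex$rate)[, 41:1])
  g1 <- gridness(autocorrelate(hex, min_overlap = 10))
  g2 <- gridness(autocorrelate(rot, min_overlap = 10))
  expect_equal(g1$hgs, g2$hgs, tolerance = 0.05)
})

test_that("border score hits its endpoints and matches brute force", {
  ## full-wall field at zero depth: BS -> +1
  wall <- wall_map_2d(c(41, 41), "x0", depth = 1)
  expect_gt(border_score(wall), 0.9)
  ## compact central field: C_M = 0 so BS = -1 exactly
  ctr <- array(0, c(41, 41))
  ctr[19:23, 19:23] <- 1
  expect_equal(border_score(spatialnet3d:::.as_rate_map(ctr)), -1)
  ## hand-built 5x5 map with one wall-hugging 3-bin field vs brute force
  m5 <- array(0, c(5, 5))
  m5[1, 2:4] <- c(1, 2, 1)
  bs <- border_score(spatialnet3d:::.as_rate_map(m5))
  ## oracle: C_M = 3/5 on wall x0; d_M = weighted mean wall distance / 2
  w <- c(1, 2, 1)
  dists <- c(0, 0, 0)        # all bins on the wall row
  dm <- sum(w * dists) / sum(w) / 2
  cm <- 3 / 5
  expect_equal(bs, (cm - dm) / (cm + dm))
  ## no field: undefined
  expect_true(is.na(border_score(spatialnet3d:::.as_rate_map(
    array(0, c(5, 5))))))
})

test_that("3D border scores flag wall-hugging fields on two planes", {
  ## slab on the z = 0 floor: the floor is an edge of the XZ and YZ
  ## projections, and the whole-face field also covers the XY projection
  floor_map <- slab_map_3d(c(41, 41, 41), axis = 3, levels = 2,
                           thickness = 3)
  bs <- border_score_3d(floor_map)
  expect_true(bs$is_border)
  expect_gt(bs$bs_top2, 0.5228)
  ## central spherical blob: all three scores strongly negative
  blob <- blob_map_3d(radius = 4)
  bs_blob <- border_score_3d(blob)
  expect_lt(bs_blob$bs_xy, 0)
  expect_lt(bs_blob$bs_yz, 0)
  expect_lt(bs_blob$bs_xz, 0)
})

test_that("plane index is 1 on planes and near 0 on spheres", {
  ## voxels exactly on a tilted plane
  a <- array(0, c(31, 31, 31))
  for (x in 1:31) for (y in 1:31) {
    z <- round(5 + 0.3 * x + 0.4 * y)
    if (z >= 1 && z <= 31) a[x, y, z] <- 1
  }
  res <- plane_index(spatialnet3d:::.as_rate_map(a))
  expect_gt(res$pi, 0.99)
  ## isotropic spherical cloud
  blob <- blob_map_3d(radius = 6)
  expect_lt(plane_index(blob)$pi, 0.1)
  ## degenerate: too few suprathreshold voxels
  tiny <- array(0, c(9, 9, 9)); tiny[5, 5, 5] <- 1
  expect_true(is.na(plane_index(spatialnet3d:::.as_rate_map(tiny))$pi))
})

test_that("stack detection recovers the right number of planes", {
  two <- slab_map_3d(levels = c(12, 30), thickness = 3)
  fits <- stack_detect(two)
  expect_length(fits, 2)
  expect_true(all(vapply(fits, `[[`, numeric(1), "r2") > 0.9))
  one <- slab_map_3d(levels = 21, thickness = 3)
  expect_length(stack_detect(one), 1)
  expect_length(stack_detect(blob_map_3d(radius = 6)), 0)
})

test_that("ellipsoid fits recover isotropy and elongation", {
  sphere <- ellipsoid_map_3d(semi_axes = c(6, 6, 6))
  fs <- ellipsoid_fit(sphere)
  expect_equal(fs$xi, 1, tolerance = 0.05)
  ell <- ellipsoid_map_3d(semi_axes = c(8, 4, 4))
  fe <- ellipsoid_fit(ell)
  expect_equal(fe$xi, 2, tolerance = 0.05 * 2)
  ## voxelized boundary centres sit up to ~a voxel inside the surface
  expect_true(all(abs(sort(fe$semi_axes) - c(4, 4, 8)) < 1.5))
})

test_that("analytic FCC lattice has tetrahedral wave vectors and ABC layers", {
  fcc <- analytic_fcc(c(41, 41, 41), wavelength = 12)
  wv <- attr(fcc, "wave_vectors")
  for (i in 1:3) for (j in (i + 1):4) {
    ang <- acos(sum(wv[i, ] * wv[j, ]) /
                  sqrt(sum(wv[i, ]^2) * sum(wv[j, ]^2))) * 180 / pi
    expect_equal(ang, 109.47, tolerance = 0.01)
  }
  ## best transection slice of its autocorrelogram is hexagonal
  ac <- autocorrelate(fcc)
  scan <- spatialnet3d:::.slice_hgs_scan(ac, fibonacci_normals(100))
  expect_gt(max(scan$hgs, na.rm = TRUE), 0.1686)
})

test_that("FCC score is 1 on the analytic lattice and ~0 on noise", {
  fcc <- analytic_fcc(c(41, 41, 41), wavelength = 12)
  ac <- autocorrelate(fcc)
  sc <- fcc_score(ac, n_normals = 200)
  expect_equal(sc$fcc, 1, tolerance = 1e-9)
  ## spatially random maps: negative-clamped scores stay near zero
  set.seed(12)
  vals <- replicate(3, {
    noise <- array(runif(41^3), c(41, 41, 41))
    sm <- spatialnet3d:::.smooth_norm(noise, 2)
    fcc_score(autocorrelate(sm), n_normals = 200)$fcc
  })
  expect_lt(mean(vals), 0.25)
})

test_that("shuffling thresholds separate tuned from untuned neurons", {
  tr <- generate_trajectory(trajectory_config(n_steps = 40000, seed = 17))
  ## strongly place-tuned synthetic neuron: fires near one corner region
  sel <- which(tr$x < 2 & tr$y < 2 & tr$z < 2)
  set.seed(3)
  idx <- sort(sample(sel, 120))
  sp <- structure(data.frame(t = tr$t[idx], x = tr$x[idx], y = tr$y[idx],
                             z = tr$z[idx]),
                  class = c("spike_train", "data.frame"))
  si_of <- function(spikes, traj)
    spatial_information(rate_map(spikes, traj, sigma = 2))
  si_orig <- si_of(sp, tr)
  set.seed(4)
  thr <- shuffle_threshold(sp, tr, si_of, n_shuffles = 50)
  expect_gt(si_orig, thr)
  ## too few spikes: undefined
  expect_true(is.na(shuffle_threshold(sp[1:5, ], tr, si_of,
                                      n_shuffles = 10)))
})
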