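test_that("heading angles follow the four-quadrant convention", {
  h <- compute_heading(rbind(c(0, 0, 0), c(1, 1, 0)))
  expect_equal(h$azimuth[2], 45)
  expect_equal(h$pitch[2], 0)

  h <- compute_heading(rbind(c(0, 0, 0), c(1, 0, 1)))
  expect_equal(h$azimuth[2], 0)
  expect_equal(h$pitch[2], 45)

  ## vertical ascent: pitch 90, azimuth undefined and carried over
  h <- compute_heading(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)))
  expect_equal(h$pitch[3], 90)
  expect_equal(h$azimuth[3], h$azimuth[2])
  expect_true(h$carried[3])

  ## negative quadrant
  h <- compute_heading(rbind(c(0, 0, 0), c(-1, -1, 0)))
  expect_equal(h$azimuth[2], -135)
})

test_that("plane-constrained modes freeze the off-plane coordinate", {
  tr_xy <- generate_trajectory(
    trajectory_config(n_steps = 2000, mode = "plane-xy", seed = 1))
  expect_true(all(diff(tr_xy$z) == 0))
  expect_true(all(abs(tr_xy$pitch) < 1e-12))

  tr_yz <- generate_trajectory(
    trajectory_config(n_steps = 2000, mode = "plane-yz", pitch_sd = 30,
                      seed = 2))
  expect_true(all(diff(tr_yz$x) == 0))
})

test_that("zero pitch spread confines motion to the horizontal", {
  tr <- generate_trajectory(
    trajectory_config(n_steps = 2000, pitch_sd = 0, seed = 3))
  expect_true(all(abs(diff(tr$z)) < 1e-12))
})

test_that("trajectory stays inside the arena and moves smoothly", {
  ar <- arena(c(5, 5, 5))
  cfg <- trajectory_config(n_steps = 30000, seed = 4)
  tr <- generate_trajectory(cfg, ar)
  expect_true(all(tr$x >= 0 & tr$x <= 5))
  expect_true(all(tr$y >= 0 & tr$y <= 5))
  expect_true(all(tr$z >= 0 & tr$z <= 5))
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
  expect_true(all(step <= cfg$speed * cfg$dt * 1.01))
})

test_that("identical seed and config give a bit-identical trajectory", {
  cfg <- trajectory_config(n_steps = 5000, seed = 99)
  t1 <- generate_trajectory(cfg)
  t2 <- generate_trajectory(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$z, t2$z)
})

test_that("azimuth is uniform and pitch Gaussian in the long run", {
  ## headings of a correlated walk are serially dependent; test the
  ## stationary marginals on temporally thinned (~3 s apart) samples
  ## faster heading mixing than the flight default so that ~3 s thinning
  ## yields effectively independent draws from the stationary marginals
  tr <- generate_trajectory(
    trajectory_config(n_steps = 120000, pitch_sd = 7.63, seed = 5,
                      az_step_sd = 15, pitch_rho = 0.99))
  thin <- seq(500, length(tr$x), by = 300)
  az <- tr$azimuth[thin]
  cs <- chisq.test(table(cut(az, breaks = seq(-180, 180, by = 30))))
  expect_gt(cs$p.value, 0.01)
  pit <- tr$pitch[thin]
  ks <- suppressWarnings(stats::ks.test(pit, "pnorm", 0, 7.63))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated session time matches the sampling arithmetic", {
  cfg <- trajectory_config(n_steps = 175000, dt = 0.01)
  expect_equal(cfg$n_steps * cfg$dt, 1750)
  expect_equal(cfg$n_steps * cfg$dt / 60, 29.2, tolerance = 0.01)
})

test_that("pitch sweep builds one config per s.d., rejecting empty input", {
  base <- trajectory_config(n_steps = 1000)
  sw <- pitch_sweep_configs(seq(10, 100, by = 10), base)
  expect_length(sw, 10)
  expect_equal(vapply(sw, `[[`, numeric(1), "pitch_sd"),
               seq(10, 100, by = 10))
  expect_equal(vapply(sw, `[[`, character(1), "mode"),
               rep(base$mode, 10))
  expect_length(pitch_sweep_configs(c(10, 25, 75), base), 3)
  expect_error(pitch_sweep_configs(numeric(0), base), "non-empty")
})

test_that("configuration errors are signalled", {
  expect_error(trajectory_config(n_steps = 1), "n_steps")
  expect_error(trajectory_config(dt = 0), "dt")
  expect_error(trajectory_config(pitch_sd = -1), "pitch_sd")
  expect_error(generate_trajectory(trajectory_config(n_steps = 100,
                                                     speed = 1000),
                                   arena(c(5, 5, 5))),
               "arena too small")
})

test_that("trajectory CSV round-trips", {
  tr <- generate_trajectory(trajectory_config(n_steps = 500, seed = 8))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  tr2 <- read_trajectory_csv(f)
  expect_equal(tr2$x, tr$x, tolerance = 1e-12)
  expect_equal(tr2$azimuth, tr$azimuth, tolerance = 1e-9)
  unlink(f)
})
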