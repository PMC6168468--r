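panel_row <- function(...) {
  base <- list(si = 2, bs_xy = 0, bs_yz = 0, bs_xz = 0, bs_top2 = 0,
               hgs_best = -0.5, sgs_best = -0.5, pi = 0.2,
               n_planes = 0L, n_fields = 3L)
  modifyList(base, list(...))
}

test_that("the classification cascade applies the threshold rules", {
  thr <- default_thresholds()
  ## border: BS above threshold on two orthogonal planes
  expect_equal(classify_neuron(panel_row(bs_xy = 0.8, bs_yz = 0.7,
                                         bs_top2 = 0.75), thr), "border")
  ## one high plane is not enough
  expect_equal(classify_neuron(panel_row(bs_xy = 0.8), thr), "OSC")
  ## plane: high plane index with low border score
  expect_equal(classify_neuron(panel_row(pi = 0.9, bs_top2 = 0.2), thr),
               "plane")
  expect_equal(classify_neuron(panel_row(pi = 0.9, n_planes = 2L), thr),
               "stack")
  ## non-spatial: SI below 1.0609
  expect_equal(classify_neuron(panel_row(si = 0.5), thr), "non-spatial")
  ## grid takes precedence over plane
  expect_equal(classify_neuron(panel_row(hgs_best = 0.3, pi = 0.9), thr),
               "grid-hex")
  expect_equal(classify_neuron(panel_row(sgs_best = 0.3), thr),
               "grid-square")
  ## place: single compact field
  expect_equal(classify_neuron(panel_row(n_fields = 1L), thr), "place")
  ## undefined descriptors fail their tests
  expect_equal(classify_neuron(panel_row(si = NA), thr), "non-spatial")
  expect_equal(classify_neuron(panel_row(pi = NA, n_fields = NA), thr),
               "OSC")
})

test_that("census fractions are consistent", {
  cen <- census(rep("non-spatial", 10))
  expect_equal(unname(cen$fractions["non-spatial"]), 100)
  expect_equal(cen$spatial_pct, 0)
  labs <- list(c("place", "grid-hex", "border", "plane", "non-spatial"),
               c("place", "place", "grid-square", "stack", "OSC"))
  cen <- census(labs)
  expect_equal(sum(cen$fractions), 100, tolerance = 1e-9)
  expect_equal(sum(cen$of_spatial), 100, tolerance = 1e-9)
  expect_equal(cen$n_repeats, 2)
  ## grid-hex/grid-square merge into grid: 1/4 then 1/5 of spatial cells
  expect_equal(unname(cen$of_spatial["grid"]), mean(c(25, 20)))
  ## plane/stack merge into plane
  expect_equal(unname(cen$of_spatial["plane"]), mean(c(25, 20)))
})

test_that("eigen spectrum matches an SVD oracle and PCA properties", {
  tr <- generate_trajectory(trajectory_config(n_steps = 30000, seed = 23))
  layer <- make_hd_layer(14, 6)
  es <- eigen_spectrum(tr, n_pcs = 8, layer = layer)
  ## independent SVD oracle for the variance fractions
  y <- run_encoding(tr, layer, oscillator_bank(layer))
  yc <- sweep(y, 2, colMeans(y))
  sv <- svd(yc)$d^2 / (nrow(y) - 1)
  expect_equal(es$table$var_frac, (sv / sum(sv))[1:8], tolerance = 1e-8)
  expect_true(all(diff(es$table$cum_var) >= -1e-12))
  expect_true(all(es$table$cum_var <= 1 + 1e-9))
  ## projections onto distinct PCs are uncorrelated over the sample
  ev <- eigen(cov(yc), symmetric = TRUE)
  proj <- yc %*% ev$vectors[, 1:4]
  cc <- cor(proj)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("flat input spectra give flat variance fractions", {
  ## i.i.d. equal-variance columns: variance spectrum is flat
  set.seed(31)
  y <- matrix(rnorm(4000 * 10), 4000, 10)
  v <- eigen(cov(y), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(v) / min(v), 1.3)
})

test_that("anisotropy evaluation never touches the trained weights", {
  tr <- generate_trajectory(trajectory_config(n_steps = 20000, seed = 29,
                                              mode = "plane-xy"))
  layer <- make_hd_layer(14, 6)
  y <- run_encoding(tr, layer, oscillator_bank(layer))
  net <- lahn_network(5, 20, seed = 31)
  net <- lahn_train(net, y, max_epochs = 2)$net
  q0 <- net$q; p0 <- net$p
  cfgs <- list(h = trajectory_config(n_steps = 8000, mode = "plane-xy",
                                     seed = 1),
               v = trajectory_config(n_steps = 8000, mode = "plane-yz",
                                     pitch_sd = 10, seed = 2))
  res <- anisotropy_experiment(net, cfgs, layer = layer, neurons = 1:3)
  expect_identical(net$q, q0)
  expect_identical(net$p, p0)
  expect_length(res, 2)
  expect_equal(attr(res[[2]], "pitch_sd"), 10)
  expect_equal(nrow(res[[1]]), 3)
})
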