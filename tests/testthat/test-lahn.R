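## low-rank synthetic stream with a well-separated spectrum. Latents are
## slow AR(1) processes: the lagged anti-Hebbian rule decorrelates via
## E[gamma(t) gamma(t-1)], which only reflects instantaneous correlations
## when the stream is temporally smooth (as the oscillator input is).
make_lowrank <- function(T = 6000, m = 20, evs = c(6, 4, 2), noise = 0.05,
                         seed = 11, rho = 0.98) {
  set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(m * length(evs)), m, length(evs))))
  lat <- vapply(evs, function(s) {
    e <- rnorm(T, sd = s * sqrt(1 - rho^2))
    as.numeric(stats::filter(e, rho, method = "recursive"))
  }, numeric(T))
  list(y = lat %*% t(basis) + matrix(rnorm(T * m, sd = noise), T, m),
       basis = basis)
}

max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, min(s))) * 180 / pi
}

test_that("response follows the one-step-lagged recurrence exactly", {
  net <- lahn_network(2, 3, eta_f = 0, eta_l = 0, seed = 1)
  net$q <- rbind(c(1, 0, 0), c(0.5, -1, 2))
  net$p <- rbind(c(0, 0.3), c(-0.2, 0))
  ys <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))
  ## scalar recurrence oracle, computed step by step
  g_prev <- c(0, 0)
  expected <- list()
  for (y in ys) {
    g <- c(sum(net$q[1, ] * y) + sum(net$p[1, ] * g_prev),
           sum(net$q[2, ] * y) + sum(net$p[2, ] * g_prev))
    expected[[length(expected) + 1]] <- g
    g_prev <- g
  }
  for (k in seq_along(ys)) {
    net <- lahn_response(net, ys[[k]])
    expect_equal(net$gamma, expected[[k]])
  }
})

test_that("pure feedforward response when lateral weights are zero", {
  net <- lahn_network(1, 4, seed = 2)
  net$q <- matrix(c(1, 0, 0, 0), 1, 4)
  net <- lahn_response(net, c(1, 0, 0, 0))
  expect_equal(net$gamma, 1)
})

test_that("weight updates carry the Oja and Stent structure", {
  net <- lahn_network(3, 4, eta_f = 0.1, eta_l = 0.1, seed = 3)
  y <- c(0.5, -0.2, 0.1, 0.9)
  up <- lahn_update(net, y, gamma = c(0, 1, 2), gamma_prev = c(1, 1, 1))
  ## silent neuron: zero updates on its row
  expect_true(all(up$dq[1, ] == 0))
  expect_true(all(up$dp[1, ] == 0))
  ## co-active pair: lateral weight strictly suppressed
  expect_lt(up$dp[2, 1], 0)
  expect_lt(up$dp[3, 2], 0)
  expect_true(all(diag(up$dp) == 0))
  ## Oja form
  expect_equal(up$dq[2, ], 0.1 * (y * 1 - net$q[2, ] * 1))
})

test_that("zero learning rates converge after one epoch with zero trace", {
  d <- make_lowrank(T = 200)
  net <- lahn_network(2, 20, eta_f = 0, eta_l = 0, seed = 4)
  r <- lahn_train(net, d$y, tol = 1e-9, max_epochs = 5)
  expect_true(r$report$converged)
  expect_equal(r$report$epochs, 1)
  expect_equal(r$report$trace[1], 0)
})

test_that("a single Oja neuron converges to the leading eigenvector", {
  set.seed(21)
  m <- 5
  A <- matrix(rnorm(m * m), m)
  Sigma <- crossprod(A) + diag(c(25, rep(0, m - 1)))
  y <- MASS::mvrnorm(4000, mu = rep(0, m), Sigma = Sigma)
  net <- lahn_network(1, m, eta_f = 1e-3, eta_l = 0, seed = 5)
  r <- lahn_train(net, y, tol = 0, max_epochs = 10)
  ## eigendecomposition oracle
  v1 <- eigen(cov(y), symmetric = TRUE)$vectors[, 1]
  cs <- abs(sum(r$net$q * v1)) / sqrt(sum(r$net$q^2))
  expect_gt(cs, 0.99)
})

test_that("training spans the PCA subspace and decorrelates the outputs", {
  d <- make_lowrank(T = 8000, evs = c(6, 4, 2), seed = 31)
  net0 <- lahn_network(3, 20, eta_f = 2e-4, eta_l = 2e-4, seed = 6)
  g0 <- lahn_activities(net0, d$y)
  r <- lahn_train(net0, d$y, tol = 0, max_epochs = 60)
  ## eigendecomposition oracle for the top-n subspace
  pcs <- eigen(cov(d$y), symmetric = TRUE)$vectors[, 1:3]
  expect_lt(max_principal_angle(t(r$net$q), pcs), 10)
  ## time-averaged pairwise output correlation does not exceed initial
  g1 <- lahn_activities(r$net, d$y)
  offdiag <- function(g) {
    cc <- abs(cor(g))
    mean(cc[upper.tri(cc)])
  }
  expect_lte(offdiag(g1), offdiag(g0) + 1e-8)
})

test_that("training is reproducible and divergence is signalled", {
  d <- make_lowrank(T = 1000)
  n1 <- lahn_network(2, 20, seed = 8)
  n2 <- lahn_network(2, 20, seed = 8)
  r1 <- lahn_train(n1, d$y, max_epochs = 2)
  r2 <- lahn_train(n2, d$y, max_epochs = 2)
  expect_identical(r1$net$q, r2$net$q)
  expect_identical(r1$net$p, r2$net$p)
  bad <- lahn_network(5, 20, eta_f = 5, eta_l = 5, seed = 9)
  expect_error(lahn_train(bad, 10 * d$y, max_epochs = 3), "diverged")
})

test_that("network capacity is bounded by the input dimension", {
  expect_error(lahn_network(100, 100), "n_neurons must be <= m - 1")
  expect_silent(lahn_network(99, 100))
})
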