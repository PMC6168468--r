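#' Lateral anti-Hebbian network (LAHN)
#'
#' A recurrent linear network of `n` neurons receiving an `m`-dimensional
#' input stream. Afferent weights `q` (n x m) are trained with the
#' Hebbian/Oja rule; lateral weights `p` (n x n, zero diagonal) with the
#' anti-Hebbian Stent rule. After training on a stationary input the row
#' space of `q` converges to the subspace spanned by the top `n` principal
#' components of the input, so network capacity is bounded by `n <= m - 1`.
#'
#' @param n_neurons network size `n`.
#' @param m input dimensionality (number of path-integration oscillators).
#' @param eta_f afferent (Hebbian) learning rate.
#' @param eta_l lateral (anti-Hebbian) learning rate.
#' @param seed optional RNG seed for weight initialization.
#' @param init_scale half-width of the uniform afferent initialization.
#' @param lateral lateral connectivity: `"full"` (every pair, both
#'   directions) or `"hierarchical"` (neuron i is inhibited only by
#'   neurons k < i, the Rubner-Tavan configuration). With full
#'   connectivity the afferent rows converge to rotations within the
#'   principal subspace; with hierarchical connectivity the network
#'   converges to the leading principal components themselves, one per
#'   neuron in variance order, and the lagged recurrence is
#'   unconditionally stable (a strictly triangular lateral matrix is
#'   nilpotent).
#' @param response how activities are computed during training and replay:
#'   `"settled"` (default) uses the steady state of the recurrent
#'   dynamics, `gamma = (I - p)^-1 q y`; `"lagged"` uses the literal
#'   one-step-lagged recurrence. The lagged iteration relaxes to the same
#'   steady state while the lateral spectral radius stays below 1, but it
#'   oscillates and diverges once decorrelation drives the inhibition
#'   beyond that bound, although the steady state itself remains
#'   well-defined; see the methods vignette.
#' @return An object of class `lahn` with weights `q`, `p`, activity state
#'   `gamma_prev`, and learning rates.
#' @export
lahn_network <- function(n_neurons = 50, m = 100, eta_f = 5e-5, eta_l = 5e-4,
                         seed = NULL, init_scale = 0.01,
                         lateral = c("hierarchical", "full"),
                         response = c("lagged", "settled")) {
  response <- match.arg(response)
  lateral <- match.arg(lateral)
  if (n_neurons > m - 1)
    stop("network capacity bound: n_neurons must be <= m - 1")
  if (n_neurons < 1) stop("need at least one neuron")
  if (!is.null(seed)) set.seed(seed)
  q <- matrix(runif(n_neurons * m, -init_scale, init_scale), n_neurons, m)
  q <- q / sqrt(rowSums(q^2))
  p <- matrix(0, n_neurons, n_neurons)
  structure(list(q = q, p = p, gamma_prev = rep(0, n_neurons),
                 eta_f = eta_f, eta_l = eta_l, response = response,
                 lateral = lateral,
                 n = as.integer(n_neurons), m = as.integer(m)),
            class = "lahn")
}

#' @export
print.lahn <- function(x, ...) {
  cat(sprintf("LAHN: %d neurons, %d inputs, eta_F %.3g, eta_L %.3g\n",
              x$n, x$m, x$eta_f, x$eta_l))
  invisible(x)
}

#' LAHN response to one input sample
#'
#' One-step-lagged recurrence: the activity of neuron i is
#' `gamma_i(t) = sum_j q_ij y_j(t) + sum_k p_ik gamma_k(t-1)`,
#' with no fixed-point settling. The network's stored previous activity is
#' advanced.
#'
#' @param net a [lahn_network()].
#' @param y_pi input vector of length `m`.
#' @return Updated network; element `gamma` holds the activities.
#' @export
lahn_response <- function(net, y_pi) {
  stopifnot(inherits(net, "lahn"))
  if (length(y_pi) != net$m) stop("input length must equal m")
  g <- drop(net$q %*% y_pi + net$p %*% net$gamma_prev)
  net$gamma <- g
  net$gamma_prev <- g
  net
}

#' Weight updates for one sample
#'
#' Oja-style afferent update `dq_ij = eta_F (y_j gamma_i - q_ij gamma_i^2)`
#' and strictly anti-Hebbian lateral update
#' `dp_ik = -eta_L gamma_i(t) gamma_k(t-1)`, diagonal forced to zero.
#'
#' @param net a [lahn_network()].
#' @param y_pi input vector at time t.
#' @param gamma activities at time t.
#' @param gamma_prev activities at time t - 1.
#' @return list with matrices `dq` (n x m) and `dp` (n x n).
#' @export
lahn_update <- function(net, y_pi, gamma, gamma_prev) {
  stopifnot(inherits(net, "lahn"))
  dq <- net$eta_f * (outer(gamma, y_pi) - net$q * gamma^2)
  dp <- -net$eta_l * outer(gamma, gamma_prev)
  diag(dp) <- 0
  list(dq = dq, dp = dp)
}

#' Train the LAHN on a path-integration stream
#'
#' Fully online learning: samples are presented in temporal order and the
#' weights are updated after each sample; one pass over the stream is one
#' epoch. The previous-step activity is carried across epoch boundaries
#' (continuous stream). Training stops when the per-epoch summed absolute
#' net weight change `sum|dp| + sum|dq|` falls below `tol`, or after
#' `max_epochs` passes. With constant learning rates the weights keep
#' fluctuating around the learned subspace, so the trace typically plateaus
#' above very small tolerances; `max_epochs` then governs.
#'
#' @param net a [lahn_network()].
#' @param y_pi T x m input matrix (a [run_encoding()] result).
#' @param tol convergence tolerance `T`; default
#'   `1e-3 * (n*m + n^2) * eta_f`.
#' @param max_epochs maximum number of passes over the stream.
#' @param guard divergence guard: training aborts with an error if any
#'   afferent weight magnitude exceeds this bound (learning-rate problem).
#' @param spectral_cap stability safeguard on the one-step-lagged
#'   recurrence: at each epoch boundary, if the spectral radius of the
#'   lateral matrix exceeds this value the matrix is rescaled to it. The
#'   decorrelating fixed point of the lateral dynamics lies close to the
#'   stability boundary (spectral radius 1), so stochastic weight
#'   fluctuations can otherwise push a finished network into a regime
#'   where replaying it diverges. Set to `Inf` to disable.
#' @return list with elements `net` (trained network) and `report`
#'   (class `training_report`: `trace`, `tol`, `epochs`, `converged`,
#'   `capped` — the number of epochs at which the safeguard engaged).
#' @export
lahn_train <- function(net, y_pi, tol = NULL, max_epochs = 10, guard = 1e6,
                       spectral_cap = 0.98) {
  stopifnot(inherits(net, "lahn"), is.matrix(y_pi))
  if (nrow(y_pi) < 1) stop("empty input stream")
  if (ncol(y_pi) != net$m) stop("input dimensionality mismatch")
  tol <- tol %||% (1e-3 * (net$n * net$m + net$n^2) * net$eta_f)
  yt <- t(y_pi)
  trace <- numeric(0)
  converged <- FALSE
  capped <- 0L
  for (ep in seq_len(max_epochs)) {
    fit <- lahn_train_cpp(yt, t(net$q), t(net$p),
                          net$eta_f, net$eta_l, -1, 1L,
                          net$gamma_prev, guard,
                          identical(net$response, "settled"),
                          identical(net$lateral %||% "full",
                                    "hierarchical"))
    if (isTRUE(fit$diverged))
      stop("LAHN training diverged; reduce the learning rates")
    qn <- t(fit$q)
    pn <- t(fit$p)
    trace <- c(trace, sum(abs(qn - net$q)) + sum(abs(pn - net$p)))
    net$q <- qn
    net$p <- pn
    net$gamma_prev <- drop(fit$gamma_prev)
    if (is.finite(spectral_cap) && net$n > 1 &&
        !identical(net$response, "settled")) {
      sr <- max(Mod(eigen(net$p, only.values = TRUE)$values))
      if (sr > spectral_cap) {
        net$p <- net$p * (spectral_cap / sr)
        capped <- capped + 1L
      }
    }
    if (trace[ep] < tol) { converged <- TRUE; break }
  }
  report <- structure(list(trace = trace, tol = tol,
                           epochs = length(trace),
                           converged = converged, capped = capped),
                      class = "training_report")
  list(net = net, report = report)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("LAHN training: %d epoch(s), final trace %.4g (tol %.4g), %s\n",
              x$epochs, x$trace[length(x$trace)], x$tol,
              if (x$converged) "converged" else "stopped at max_epochs"))
  invisible(x)
}

#' Activities of a fixed network over a stream
#'
#' Evaluation-only pass (no weight updates): iterates the one-step-lagged
#' response over all samples.
#'
#' @param net a (trained) [lahn_network()].
#' @param y_pi T x m input matrix.
#' @param gamma0 initial previous-step activity (default zero).
#' @return T x n matrix of activities.
#' @export
lahn_activities <- function(net, y_pi, gamma0 = rep(0, net$n)) {
  stopifnot(inherits(net, "lahn"), ncol(y_pi) == net$m)
  lahn_response_cpp(t(y_pi), t(net$q), t(net$p), gamma0,
                    identical(net$response %||% "lagged", "settled"))
}
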