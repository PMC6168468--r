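#' Head-direction layer
#'
#' Two populations of head-direction cells, tuned to azimuth and to pitch,
#' in a 7:3 ratio by default (70 azimuth, 30 pitch cells). Preferred
#' directions of each population are uniformly spaced over the full 360
#' degree angular space.
#'
#' @param n_az number of azimuth-tuned cells.
#' @param n_p number of pitch-tuned cells.
#' @return An object of class `hd_layer` with preferred directions
#'   `pref_az`, `pref_p` (degrees).
#' @export
make_hd_layer <- function(n_az = 70, n_p = 30) {
  if (n_az < 1 || n_p < 1) stop("population sizes must be >= 1")
  structure(list(
    pref_az = wrap180(seq(0, 360, length.out = n_az + 1)[seq_len(n_az)]),
    pref_p = wrap180(seq(0, 360, length.out = n_p + 1)[seq_len(n_p)]),
    n_az = as.integer(n_az), n_p = as.integer(n_p)
  ), class = "hd_layer")
}

#' Head-direction tuning response
#'
#' Signed cosine tuning: the activity of cell i is
#' `cos(theta - theta_i)` with `theta` the current heading and `theta_i` its
#' preferred direction. Azimuth cells read the azimuth angle, pitch cells the
#' pitch angle. No rectification by default.
#'
#' @param layer an [make_hd_layer()] object.
#' @param azimuth current azimuth(s), degrees (scalar or vector over time).
#' @param pitch current pitch(es), degrees.
#' @param rectify clip negative activities to zero.
#' @return list with matrices `az` (T x n_az) and `p` (T x n_p) of
#'   activities in \[-1, 1\].
#' @export
hd_activity <- function(layer, azimuth, pitch, rectify = FALSE) {
  stopifnot(inherits(layer, "hd_layer"))
  az <- cos(outer(deg2rad(azimuth), deg2rad(layer$pref_az), `-`))
  p <- cos(outer(deg2rad(pitch), deg2rad(layer$pref_p), `-`))
  if (rectify) { az <- pmax(az, 0); p <- pmax(p, 0) }
  list(az = az, p = p)
}

#' Oscillatory path-integration bank
#'
#' One phase oscillator per head-direction cell. Each oscillator's phase
#' advances at the base angular frequency `omega = 2*pi*f` plus a term
#' proportional to running speed times the head-direction activity it
#' receives, so displacement along the preferred direction is integrated
#' into phase. Output is the sine of the phase.
#'
#' @param layer the upstream [make_hd_layer()] (one-to-one connectivity).
#' @param f base oscillator frequency, Hz.
#' @param beta speed modulation factor (dimensionless).
#' @param init_phase initial phases, radians: a scalar, a vector of length
#'   `n_az + n_p`, or `"random"` for uniform random phases.
#' @return An object of class `oscillator_bank`.
#' @export
oscillator_bank <- function(layer, f = 0.5, beta = 2, init_phase = 0) {
  stopifnot(inherits(layer, "hd_layer"))
  m <- layer$n_az + layer$n_p
  phase <- if (identical(init_phase, "random")) runif(m, 0, 2 * pi)
           else rep_len(init_phase, m)
  structure(list(phase = phase, f = f, omega = 2 * pi * f, beta = beta,
                 n_az = layer$n_az, n_p = layer$n_p, m = m),
            class = "oscillator_bank")
}

#' Advance the oscillator bank by one time step
#'
#' Explicit Euler step of the phase dynamics
#' `dphase_i/dt = omega + beta * s * phi_i`, followed by `y_i = sin(phase_i)`.
#'
#' @param bank an [oscillator_bank()].
#' @param activities head-direction activities, length `n_az + n_p`
#'   (azimuth population first).
#' @param s running speed, units/s.
#' @param dt time step, seconds.
#' @return The updated bank, with element `y` holding the outputs.
#' @export
pi_step <- function(bank, activities, s, dt) {
  stopifnot(inherits(bank, "oscillator_bank"), dt > 0, s >= 0,
            length(activities) == bank$m)
  bank$phase <- bank$phase + (bank$omega + bank$beta * s * activities) * dt
  bank$y <- sin(bank$phase)
  bank
}

#' Run the encoding stage over a whole trajectory
#'
#' Vectorized integration of the oscillator bank along a trajectory. The
#' concatenated outputs `[azimuth bank | pitch bank]` form the
#' path-integration matrix: the input stream of the anti-Hebbian network and
#' the matrix used for direct PCA.
#'
#' @param traj a [generate_trajectory()] result.
#' @param layer an [make_hd_layer()].
#' @param bank an [oscillator_bank()].
#' @return A T x m matrix of oscillator outputs in \[-1, 1\], class
#'   `pi_matrix`, with attributes `f`, `beta`, `dt`.
#' @export
run_encoding <- function(traj, layer = make_hd_layer(),
                         bank = oscillator_bank(layer)) {
  stopifnot(inherits(traj, "trajectory"))
  act <- hd_activity(layer, traj$azimuth, traj$pitch)
  phi <- cbind(act$az, act$p)
  inc <- (bank$omega + bank$beta * traj$speed * phi) * traj$dt
  rm(phi)
  phases <- apply(inc, 2, cumsum)
  rm(inc)
  phases <- sweep(phases, 2, bank$phase, `+`)
  y <- sin(phases)
  structure(y, class = c("pi_matrix", class(y)),
            f = bank$f, beta = bank$beta, dt = traj$dt,
            n_az = bank$n_az, n_p = bank$n_p)
}
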