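#' Define a navigation arena
#'
#' The arena is the box the virtual animal navigates in. Spatial analyses bin
#' it into a voxel grid (41 voxels per axis by default).
#'
#' @param extent numeric length-3, box side lengths (length units).
#' @param bins integer length-3, voxels per axis.
#' @return An object of class `arena`.
#' @export
arena <- function(extent = c(12, 12, 12), bins = c(41, 41, 41)) {
  extent <- rep_len(as.numeric(extent), 3)
  bins <- rep_len(as.integer(bins), 3)
  if (any(extent <= 0)) stop("arena extents must be > 0")
  if (any(bins < 2)) stop("arena needs at least 2 bins per axis")
  structure(list(extent = extent, bins = bins), class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat("arena:", paste(x$extent, collapse = " x "), "units,",
      paste(x$bins, collapse = " x "), "voxels\n")
  invisible(x)
}

#' Trajectory configuration
#'
#' Movement statistics of the simulated animal. Azimuth heading evolves as a
#' wrapped random walk whose stationary distribution is uniform on the
#' circle; pitch follows a reflected AR(1) process with stationary Gaussian
#' distribution (mean 0, s.d. `pitch_sd`), or a reflected random walk with
#' uniform stationary distribution when `pitch_dist = "uniform"`. Speed is
#' constant.
#'
#' @param n_steps number of samples (default 175,000, i.e. 1750 s at
#'   `dt = 0.01`, about 29.2 min of flight).
#' @param dt sampling interval, seconds.
#' @param speed flight speed, length units per second.
#' @param pitch_sd pitch standard deviation, degrees. The default takes the
#'   reported pitch variance of 58.25 deg^2 literally (s.d. ~ 7.63 deg).
#' @param pitch_dist `"gaussian"` or `"uniform"`.
#' @param mode `"volumetric"`, `"plane-xy"` (horizontal) or `"plane-yz"`
#'   (vertical wall).
#' @param az_step_sd azimuth innovation s.d. per step, degrees. Controls
#'   heading smoothness (smaller = smoother, slower mixing).
#' @param pitch_rho AR(1) coefficient of the pitch process per step.
#' @param seed optional RNG seed for [generate_trajectory()].
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(n_steps = 175000, dt = 0.01, speed = 25,
                              pitch_sd = sqrt(58.25),
                              pitch_dist = c("gaussian", "uniform"),
                              mode = c("volumetric", "plane-xy", "plane-yz"),
                              az_step_sd = 3, pitch_rho = 0.999,
                              seed = NULL) {
  mode <- match.arg(mode)
  pitch_dist <- match.arg(pitch_dist)
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (dt <= 0) stop("dt must be > 0")
  if (speed <= 0) stop("speed must be > 0")
  if (pitch_sd < 0) stop("pitch_sd must be >= 0")
  structure(list(n_steps = as.integer(n_steps), dt = dt, speed = speed,
                 pitch_sd = pitch_sd, pitch_dist = pitch_dist, mode = mode,
                 az_step_sd = az_step_sd, pitch_rho = pitch_rho, seed = seed),
            class = "trajectory_config")
}

#' Simulate a flight trajectory
#'
#' Generates a correlated-random-walk trajectory inside `arena` whose
#' long-run azimuth marginal is uniform over 360 degrees and whose pitch
#' marginal follows the configured distribution. Steps that would exit the
#' arena are reflected inward (billiard rule), which deflects the heading.
#'
#' @param config a [trajectory_config()].
#' @param arena an [arena()].
#' @return An object of class `trajectory`: a list with positions `x`, `y`,
#'   `z`, time `t`, per-step displacement-derived `azimuth` and `pitch`
#'   (degrees), `speed` (units/s), plus `dt`, `mode` and the arena.
#' @export
generate_trajectory <- function(config, arena = spatialnet3d::arena()) {
  stopifnot(inherits(config, "trajectory_config"), inherits(arena, "arena"))
  step <- config$speed * config$dt
  if (step > min(arena$extent) / 2)
    stop("arena too small for one speed*dt step; reduce speed or enlarge arena")
  if (!is.null(config$seed)) set.seed(config$seed)
  mode_i <- match(config$mode, c("volumetric", "plane-xy", "plane-yz")) - 1L
  raw <- traj_core_cpp(config$n_steps, config$dt, config$speed,
                       deg2rad(config$pitch_sd),
                       config$pitch_dist == "uniform",
                       config$pitch_rho,
                       deg2rad(config$az_step_sd),
                       arena$extent, mode_i)
  traj <- structure(list(
    t = seq_len(config$n_steps) * config$dt - config$dt,
    x = raw$x, y = raw$y, z = raw$z,
    dt = config$dt, mode = config$mode, arena = arena, config = config
  ), class = "trajectory")
  hd <- compute_heading(traj)
  traj$azimuth <- hd$azimuth
  traj$pitch <- hd$pitch
  dx <- c(0, diff(raw$x)); dy <- c(0, diff(raw$y)); dz <- c(0, diff(raw$z))
  traj$speed <- sqrt(dx^2 + dy^2 + dz^2) / config$dt
  traj$speed[1] <- traj$speed[2]
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples, dt %.3g s (%.1f s total), mode %s\n",
              length(x$x), x$dt, length(x$x) * x$dt, x$mode))
  invisible(x)
}

#' Heading angles from displacements
#'
#' Azimuth is the four-quadrant angle of the horizontal displacement,
#' `atan2(dy, dx)`; pitch is `atan(dz / sqrt(dx^2 + dy^2))`, in
#' \[-90, 90\] degrees. A step with zero (horizontal) displacement carries
#' the previous heading over; such steps are flagged in the `carried`
#' attribute.
#'
#' @param traj a `trajectory`, or a T x 3 position matrix.
#' @return list with `azimuth` and `pitch` (degrees, aligned with samples;
#'   the first sample repeats the second, since headings are differences).
#' @export
compute_heading <- function(traj) {
  pos <- if (inherits(traj, "trajectory")) cbind(traj$x, traj$y, traj$z)
         else as.matrix(traj)
  if (nrow(pos) < 2) stop("need at least 2 positions")
  dx <- diff(pos[, 1]); dy <- diff(pos[, 2]); dz <- diff(pos[, 3])
  dh <- sqrt(dx^2 + dy^2)
  az <- rad2deg(atan2(dy, dx))
  pit <- rad2deg(atan2(dz, dh))
  ## zero horizontal displacement: azimuth undefined, carry over
  carried_az <- dh == 0 & abs(dz) > 0
  carried <- dh == 0 & dz == 0
  if (any(carried_az | carried)) {
    idx <- which(carried_az | carried)
    for (i in idx) az[i] <- if (i > 1) az[i - 1] else 0
    for (i in idx[carried]) pit[i] <- if (i > 1) pit[i - 1] else 0
  }
  list(azimuth = c(az[1], az), pitch = c(pit[1], pit),
       carried = c(FALSE, carried_az | carried))
}

#' Pitch-sweep configurations
#'
#' One configuration per pitch s.d., identical otherwise. Used for the
#' critical-angle sweep on the vertical plane and the volumetric FCC-tendency
#' comparison.
#'
#' @param sd_list pitch standard deviations, degrees.
#' @param base base [trajectory_config()].
#' @return list of `trajectory_config` objects.
#' @export
pitch_sweep_configs <- function(sd_list, base = trajectory_config()) {
  if (length(sd_list) == 0) stop("sd_list must be non-empty")
  if (any(sd_list < 0)) stop("pitch s.d. values must be >= 0")
  lapply(sd_list, function(s) { cfg <- base; cfg$pitch_sd <- s; cfg })
}

#' Write / read a trajectory as CSV
#'
#' Columns `t, x, y, z`. Headings and speed are recomputed on read.
#' @param traj a `trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(data.frame(t = traj$t, x = traj$x, y = traj$y, z = traj$z),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param dt sampling interval; inferred from the time column if NULL.
#' @param arena arena the positions live in.
#' @param mode trajectory mode tag.
#' @export
read_trajectory_csv <- function(path, dt = NULL,
                                arena = spatialnet3d::arena(),
                                mode = "volumetric") {
  d <- read.csv(path)
  dt <- dt %||% (if (nrow(d) > 1) d$t[2] - d$t[1] else 0.01)
  traj <- structure(list(t = d$t, x = d$x, y = d$y, z = d$z, dt = dt,
                         mode = mode, arena = arena, config = NULL),
                    class = "trajectory")
  hd <- compute_heading(traj)
  traj$azimuth <- hd$azimuth
  traj$pitch <- hd$pitch
  dx <- c(0, diff(d$x)); dy <- c(0, diff(d$y)); dz <- c(0, diff(d$z))
  traj$speed <- sqrt(dx^2 + dy^2 + dz^2) / dt
  if (length(traj$speed) > 1) traj$speed[1] <- traj$speed[2]
  traj
}
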