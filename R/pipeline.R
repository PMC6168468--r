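#' Experiment configuration (model defaults)
#'
#' All model parameters with their default values: 50 LAHN neurons,
#' oscillator base frequency 0.5 Hz, 70 azimuth + 30 pitch head-direction
#' cells, speed modulation beta = 2, dt = 0.01 s, and the fixed
#' classification thresholds (SI 1.0609, HGS 0.1686, SGS 0.1952,
#' BS 0.5228, PI 0.7528). The learning rates default to eta_F = 5e-5 and
#' eta_L = 5e-4: with the 100-dimensional unnormalized oscillator input
#' the discrete dynamics are only stable for small rates, and the
#' afferent rate must additionally sit in the covariance-averaging regime
#' (see the methods vignette for the analysis). The spatial-information
#' and border-score thresholds are re-derived by shuffling under this
#' pipeline by default (`threshold_calibration = "shuffled"`).
#'
#' @param ... named overrides (any of the fields below, plus a nested
#'   `trajectory` list passed to [trajectory_config()]).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n_neurons = 50, f = 0.5, n_az = 70, n_p = 30, beta = 2,
    eta_f = 5e-5, eta_l = 5e-4, dt = 0.01,
    max_epochs = 10, tol = NULL,
    sigma = 3, fcc_normals = 500,
    threshold_calibration = "shuffled", cal_shuffles = 15,
    thresholds = default_thresholds(),
    arena = list(extent = c(12, 12, 12), bins = c(41, 41, 41)),
    trajectory = list(n_steps = 175000, speed = 25,
                      pitch_sd = sqrt(58.25), mode = "volumetric"),
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("trajectory", "arena") && is.list(ov[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param cfg an [experiment_config()].
#' @param path file path.
#' @export
write_config_yaml <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$thresholds <- unclass(lst$thresholds)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  thr <- lst$thresholds
  lst$thresholds <- NULL
  cfg <- do.call(experiment_config, lst)
  if (!is.null(thr)) cfg$thresholds <- do.call(default_thresholds, thr)
  cfg
}

## deterministic per-purpose seed substreams from one named seed
.sub_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 101 + as.numeric(k) * 7919) %% 2147483647)

#' Run one end-to-end model training
#'
#' Simulates a trajectory, runs the encoding stage, trains the LAHN,
#' replays the trained network over the trajectory and scores every
#' neuron. This is the core pipeline behind the population analyses.
#'
#' @param config an [experiment_config()].
#' @param compute_fcc compute FCC scores for periodic neurons (expensive).
#' @param keep_activity keep the T x n activity matrix in the result.
#' @return list of class `model_run`: `traj`, `net`, `report`, `panel`,
#'   `labels`, `config`.
#' @export
run_spatial_model <- function(config = experiment_config(),
                              compute_fcc = TRUE, keep_activity = FALSE) {
  ar <- arena(config$arena$extent, config$arena$bins)
  tc <- do.call(trajectory_config,
                c(config$trajectory, list(dt = config$dt,
                                          seed = .sub_seed(config$seed, 1L))))
  traj <- generate_trajectory(tc, ar)
  layer <- make_hd_layer(config$n_az, config$n_p)
  bank <- oscillator_bank(layer, f = config$f, beta = config$beta)
  y <- run_encoding(traj, layer, bank)
  net <- lahn_network(config$n_neurons, m = layer$n_az + layer$n_p,
                      eta_f = config$eta_f, eta_l = config$eta_l,
                      seed = .sub_seed(config$seed, 2L))
  fit <- lahn_train(net, y, tol = config$tol,
                    max_epochs = config$max_epochs)
  g <- lahn_activities(fit$net, y)
  thresholds <- config$thresholds
  if (identical(config$threshold_calibration, "shuffled")) {
    cal <- calibrate_thresholds(g, traj, sigma = config$sigma,
                                n_shuffles = config$cal_shuffles)
    if (is.finite(cal$si)) {
      thresholds$si <- cal$si
      thresholds$place_si <- cal$si
    }
    if (is.finite(cal$bs)) thresholds$bs <- cal$bs
    thresholds$provenance <- "shuffled"
  }
  panel <- score_panel(g, traj, thresholds = thresholds,
                       sigma = config$sigma, compute_fcc = compute_fcc,
                       fcc_normals = config$fcc_normals)
  labels <- classify_panel(panel, thresholds)
  out <- list(traj = traj, net = fit$net, report = fit$report,
              panel = panel, labels = labels, config = config,
              thresholds = thresholds, layer = layer)
  if (keep_activity) out$gamma <- g
  structure(out, class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat("model run (seed", x$config$seed, "):",
      sum(x$labels != "non-spatial"), "of", length(x$labels),
      "neurons spatial\n")
  print(table(x$labels))
  invisible(x)
}

#' Run a named experiment recipe
#'
#' End-to-end pipelines mirroring the main simulation experiments:
#' \describe{
#'   \item{place_isotropy}{volumetric training; elongation-index
#'     distribution of place cells.}
#'   \item{planar_symmetry}{volumetric training; hexagonal vs square
#'     regime split and FCC-score distribution of periodic neurons.}
#'   \item{anisotropy}{train on the horizontal plane, evaluate the fixed
#'     network on the vertical plane, including the pitch-s.d. sweep for
#'     the critical angle.}
#'   \item{fcc_tendency}{volumetric trainings at pitch s.d. 10/25/75 deg;
#'     FCC-score distribution per condition.}
#'   \item{border_plane}{volumetric training; border and plane cell
#'     detection.}
#'   \item{census}{repeated retrainings; cell-type census.}
#' }
#'
#' @param name recipe name (see above).
#' @param config base [experiment_config()].
#' @param n_repeats retrainings for the census recipe.
#' @param sweep_sd pitch s.d. sweep (degrees) for the anisotropy recipe.
#' @param out_dir optional directory; if given, tables are written as CSV
#'   and a machine-readable `summary.json` (with a provenance block) is
#'   emitted.
#' @return recipe-specific result list; always contains `summary`.
#' @export
run_recipe <- function(name = c("place_isotropy", "planar_symmetry",
                                "anisotropy", "fcc_tendency",
                                "border_plane", "census",
                                "fig2", "fig3", "fig4_5", "fig6", "fig7",
                                "fig8"),
                       config = experiment_config(), n_repeats = 5,
                       sweep_sd = seq(10, 120, by = 10), out_dir = NULL) {
  name <- match.arg(name)
  ## figure-style aliases for the experiment recipes
  name <- switch(name, fig2 = "place_isotropy", fig3 = "planar_symmetry",
                 fig4_5 = "anisotropy", fig6 = "fcc_tendency",
                 fig7 = "border_plane", fig8 = "census", name)
  thr <- config$thresholds
  res <- switch(name,
    place_isotropy = {
      run <- run_spatial_model(config, compute_fcc = FALSE)
      xi <- run$panel$xi[run$labels == "place"]
      xi <- xi[!is.na(xi)]
      list(run = run, xi = xi,
           summary = list(recipe = name, n_place = length(xi),
                          xi_mean = mean(xi),
                          isotropic_pct = 100 * mean(xi < thr$xi)))
    },
    planar_symmetry = {
      run <- run_spatial_model(config, compute_fcc = TRUE)
      per <- run$panel[run$panel$periodic, ]
      list(run = run, periodic = per,
           summary = list(recipe = name, n_periodic = nrow(per),
                          hex_pct = 100 * mean(per$hgs_best > thr$hgs,
                                               na.rm = TRUE),
                          square_pct = 100 * mean(per$sgs_best > thr$sgs &
                                                    per$hgs_best <= thr$hgs,
                                                  na.rm = TRUE),
                          fcc_mean = mean(per$fcc, na.rm = TRUE)))
    },
    anisotropy = {
      cfg_h <- config
      cfg_h$trajectory$mode <- "plane-xy"
      run <- run_spatial_model(cfg_h, compute_fcc = FALSE)
      grid_idx <- which(run$labels %in% c("grid-hex", "grid-square"))
      if (length(grid_idx) == 0)
        grid_idx <- order(run$panel$hgs_best, decreasing = TRUE)[1:5]
      base_tc <- do.call(trajectory_config,
                        c(config$trajectory, list(dt = config$dt)))
      mk <- function(sd_deg, seed_k) {
        tc <- base_tc
        tc$mode <- "plane-yz"
        tc$pitch_sd <- sd_deg
        tc$seed <- .sub_seed(config$seed, 100L + seed_k)
        tc
      }
      configs <- c(list(horizontal = {
        tc <- base_tc; tc$mode <- "plane-xy"
        tc$seed <- .sub_seed(config$seed, 99L); tc
      }), setNames(lapply(seq_along(sweep_sd),
                          function(k) mk(sweep_sd[k], k)),
                   paste0("vertical_sd", sweep_sd)))
      ev <- anisotropy_experiment(run$net, configs,
                                  arena = arena(config$arena$extent,
                                                config$arena$bins),
                                  layer = run$layer, neurons = grid_idx,
                                  sigma = config$sigma)
      mean_hgs <- vapply(ev, function(d) mean(d$hgs, na.rm = TRUE),
                         numeric(1))
      vert <- mean_hgs[-1]
      crossing <- sweep_sd[which(vert > thr$hgs)[1]]
      list(run = run, evaluation = ev, mean_hgs = mean_hgs,
           summary = list(recipe = name, grid_neurons = grid_idx,
                          hgs_horizontal = mean_hgs[[1]],
                          hgs_vertical = as.list(vert),
                          critical_angle = crossing))
    },
    fcc_tendency = {
      sds <- c(10, 25, 75)
      runs <- lapply(seq_along(sds), function(k) {
        cfg <- config
        cfg$trajectory$pitch_sd <- sds[k]
        cfg$seed <- .sub_seed(config$seed, 200L + k)
        run_spatial_model(cfg, compute_fcc = TRUE)
      })
      fcc_means <- vapply(runs, function(r)
        mean(r$panel$fcc[r$panel$periodic], na.rm = TRUE), numeric(1))
      list(runs = runs,
           summary = list(recipe = name, pitch_sd = as.list(sds),
                          fcc_mean = as.list(fcc_means)))
    },
    border_plane = {
      run <- run_spatial_model(config, compute_fcc = FALSE)
      list(run = run,
           summary = list(recipe = name,
                          n_border = sum(run$labels == "border"),
                          n_plane = sum(run$labels %in%
                                          c("plane", "stack"))))
    },
    census = {
      runs <- lapply(seq_len(n_repeats), function(k) {
        cfg <- config
        cfg$seed <- .sub_seed(config$seed, 300L + k)
        run_spatial_model(cfg, compute_fcc = FALSE)
      })
      cen <- census(lapply(runs, `[[`, "labels"))
      list(runs = runs, census = cen,
           summary = list(recipe = name, n_repeats = n_repeats,
                          spatial_pct = cen$spatial_pct,
                          of_spatial = as.list(cen$of_spatial)))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    summ <- res$summary
    summ$provenance <- list(
      package_version = as.character(utils::packageVersion("spatialnet3d")),
      seed = config$seed,
      config_hash = sum(utils::object.size(config)))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(res$run))
      write.csv(res$run$panel, file.path(out_dir, "panel.csv"),
                row.names = FALSE)
  }
  res
}
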