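# Configuration handling and the end-to-end pipeline:
# preprocess -> calibrate -> simulate -> validate.

#' Default run configuration
#'
#' All tunable keys with their packaged defaults: segmentation thresholds,
#' arena geometry, simulation constants and calibration settings. Every key
#' can be overridden from a YAML file ([load_config()]).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    segmentation = list(u_min = 1, body_length = 3, tau_s = 2, tau_l = 60,
                        smooth_window = 3L),
    arena = list(side = 120, corner_radius = 10),
    simulation = list(dt = 0.2, omega_clamp = 15, sigma0 = 12,
                      A = 6.75, B = -0.11),
    calibration = list(loess_span = 0.2, wall_mode = "distance",
                       sigma0_max_omega = 10, sigma0_theta = 2.81)
  )
}

#' Load a run configuration
#'
#' Reads a YAML file of overrides and merges it over [default_config()].
#' Unknown keys are rejected with the list of valid keys, so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested named list with every key populated.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user, prefix = "")
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base))
      stop("unknown config key '", full, "'; valid keys here: ",
           paste(names(base), collapse = ", "))
    if (is.list(base[[key]])) {
      if (!is.list(user[[key]]))
        stop("config key '", full, "' must be a mapping")
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Run the full modelling pipeline
#'
#' For each input trajectory file: extract swimming segments, fit the
#' speed and turning-speed O-U parameters per segment by exact MLE,
#' average them per fish and globally (segment-count weighted), fit the
#' wall response from the pooled wall-corrected turning samples, and
#' simulate one walker per fish plus one global walker for validation.
#' All randomness derives from `cfg$seed`.
#'
#' @param paths character vector of trajectory CSV files (one per fish).
#' @param cfg configuration list from [load_config()].
#' @param out_dir output directory; created if missing.
#' @return A manifest list (also written as `manifest.json` in `out_dir`):
#'   per-segment parameters, per-fish and global averages, wall fit,
#'   sigma0, and paths of the simulated trajectories.
#' @export
run_pipeline <- function(paths, cfg = default_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$segmentation
  seg_cfg <- seg_config(sc$u_min, sc$body_length, sc$tau_s, sc$tau_l,
                        sc$smooth_window)
  ar <- arena(cfg$arena$side, cfg$arena$corner_radius)

  per_fish_speed <- list(); per_fish_turn <- list()
  wall_z <- numeric(); wall_w <- numeric()
  seg_rows <- list()

  for (p in paths) {
    traj <- tryCatch(read_trajectory(p),
                     error = function(e) stop("preprocess: ", conditionMessage(e)))
    fish <- attr(traj, "subject_id")
    segs <- segment_swimming(traj, seg_cfg)
    for (seg in segs) {
      kin <- kinematics(seg)
      ou_u <- fit_ou_mle(kin$u, kin$dt)
      ou_w <- fit_ou_mle(kin$omega, kin$dt)
      per_fish_speed[[fish]] <- c(per_fish_speed[[fish]], list(ou_u))
      per_fish_turn[[fish]] <- c(per_fish_turn[[fish]], list(ou_w))
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        fish = fish, label = attr(seg, "label"),
        start_index = attr(seg, "start_index"),
        mu_u = ou_u$mu, theta_u = ou_u$theta, sigma_u = ou_u$sigma,
        mu_w = ou_w$mu, theta_w = ou_w$theta, sigma_w = ou_w$sigma)
      # pooled wall-corrected turning samples for the wall-response fit
      ok <- which(!kin$flagged)
      for (k in ok) {
        pr <- tryCatch(project_collision(seg$x[k], seg$y[k], kin$phi[k],
                                         kin$u[k], ar),
                       error = function(e) NULL)
        if (!is.null(pr)) {
          wall_z <- c(wall_z, if (cfg$calibration$wall_mode == "time")
            pr$t_w else pr$d_w)
          wall_w <- c(wall_w, wall_corrected_turning(kin$omega[k], pr$phi_w))
        }
      }
    }
  }
  if (length(seg_rows) == 0L)
    stop("no swimming data: no segment passed the filtering rules")

  avg_u <- average_params(per_fish_speed)
  avg_w <- average_params(per_fish_turn)
  wall <- if (sum(is.finite(wall_z)) >= 50)
    tryCatch(fit_wall_response(wall_z[is.finite(wall_z)],
                               wall_w[is.finite(wall_z)],
                               mode = cfg$calibration$wall_mode,
                               span = cfg$calibration$loess_span),
             error = function(e) NULL) else NULL
  sigma0 <- estimate_sigma0(cfg$calibration$sigma0_max_omega,
                            cfg$calibration$sigma0_theta)

  build_params <- function(sp, tu) {
    model_params(speed = sp, turn = tu,
                 sigma0 = max(cfg$simulation$sigma0, tu$sigma * 1.001),
                 A = if (is.null(wall)) cfg$simulation$A else 3 * wall$A,
                 B = if (is.null(wall)) cfg$simulation$B else min(wall$B, 0))
  }

  sims <- list()
  fishes <- names(per_fish_speed)
  for (i in seq_along(fishes)) {
    f <- fishes[i]
    ru <- avg_u$per_fish[avg_u$per_fish$fish == f, ]
    rw <- avg_w$per_fish[avg_w$per_fish$fish == f, ]
    mp <- build_params(ou_params(ru$mu, ru$theta, ru$sigma),
                       ou_params(rw$mu, rw$theta, rw$sigma))
    scfg <- sim_config(dt = cfg$simulation$dt, T = 60 * ru$n,
                       seed = cfg$seed + i,
                       omega_clamp = cfg$simulation$omega_clamp, arena = ar)
    path <- file.path(out_dir, paste0("sim_", f, ".csv"))
    gen_reference_trajectory(mp, scfg, path, subject_id = paste0("sim_", f))
    sims[[f]] <- path
  }
  mp_g <- build_params(avg_u$global, avg_w$global)
  scfg_g <- sim_config(dt = cfg$simulation$dt,
                       T = 60 * sum(avg_u$per_fish$n), seed = cfg$seed,
                       omega_clamp = cfg$simulation$omega_clamp, arena = ar)
  path_g <- file.path(out_dir, "sim_global.csv")
  gen_reference_trajectory(mp_g, scfg_g, path_g, subject_id = "sim_global")

  manifest <- list(
    segments = do.call(rbind, seg_rows),
    per_fish = list(speed = avg_u$per_fish, turn = avg_w$per_fish),
    global = list(speed = unclass(avg_u$global),
                  turn = unclass(avg_w$global)),
    wall_fit = if (is.null(wall)) NULL else
      wall[c("A", "B", "se_A", "se_B", "mode")],
    sigma0 = sigma0,
    simulated = c(sims, list(global = path_g)),
    seed = cfg$seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
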