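# End-to-end orchestration: configuration, file formats (CSV tables, YAML
# configs and rigs, multi-page TIFF stacks), logging, and the staged
# simulate -> calibrate -> detect/track -> metrics -> soundfield -> analyze
# pipeline with resumable intermediates.

#' Experiment configuration
#'
#' @param n_sites,n_nights_per_site,n_blocks_per_night block design
#'   (defaults 3 / 3 / 12, alternating treatment starting with control).
#' @param deterrent_offset speaker distance behind the cameras, m.
#' @param linking a [linking_params()].
#' @param sound a [sound_field_params()].
#' @param rig a [stereo_rig()] (the true rig for simulation).
#' @param n_bats bats rendered in the reference synthetic scene.
#' @param n_frames frames rendered per stack.
#' @param pixel_threshold detection threshold for the rendered stacks.
#' @param noise render noise settings (see [render_frames()]).
#' @param seed master seed; stage seeds are derived from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_sites = 3, n_nights_per_site = 3,
                              n_blocks_per_night = 12, deterrent_offset = 15,
                              linking = linking_params(),
                              sound = sound_field_params(),
                              rig = stereo_rig(), n_bats = 2, n_frames = 60,
                              pixel_threshold = 0.2,
                              noise = list(background_sd = 0,
                                           clutter_rate = 0),
                              seed = 1) {
  if (n_blocks_per_night %% 2 != 0)
    stop("the block schedule must alternate control/treatment (even count)",
         call. = FALSE)
  structure(as.list(environment()), class = "experiment_config")
}

#' Write / read a stereo rig as YAML
#'
#' @param rig a [stereo_rig()].
#' @param path YAML file path.
#' @return `path` / the rig.
#' @export
write_rig_yaml <- function(rig, path) {
  enc <- function(cam) list(
    intrinsics = list(fx = cam$intrinsics$fx, fy = cam$intrinsics$fy,
                      cx = cam$intrinsics$cx, cy = cam$intrinsics$cy,
                      k1 = cam$intrinsics$k1, k2 = cam$intrinsics$k2,
                      image_size = as.integer(cam$intrinsics$image_size)),
    extrinsics = list(R = as.numeric(cam$extrinsics$R),
                      t = as.numeric(cam$extrinsics$t)))
  yaml::write_yaml(list(left = enc(rig$left), right = enc(rig$right),
                        baseline_mm = rig$baseline_mm,
                        rms_px = attr(rig, "rms_px")), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_rig_yaml
#' @export
read_rig_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  dec <- function(cm) camera(
    camera_intrinsics(fx = cm$intrinsics$fx, fy = cm$intrinsics$fy,
                      cx = cm$intrinsics$cx, cy = cm$intrinsics$cy,
                      k1 = cm$intrinsics$k1, k2 = cm$intrinsics$k2,
                      image_size = cm$intrinsics$image_size),
    camera_extrinsics(nearest_rotation(matrix(cm$extrinsics$R, 3, 3)),
                      cm$extrinsics$t))
  structure(list(left = dec(y$left), right = dec(y$right),
                 baseline_mm = y$baseline_mm),
            class = "stereo_rig")
}

#' Read a headered CSV with schema validation
#'
#' @param path CSV path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_csv_checked <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(msg, con)
}

#' Run the full synthetic pipeline
#'
#' Stages: simulate (flights, calibration sequence, block counts, call
#' table), calibrate, track (detect + pair + link + QC), metrics,
#' soundfield, analyze. Every stage writes CSV/YAML intermediates into
#' `out_dir` and is skipped on rerun if its outputs already exist
#' (`resume = TRUE`). Deterministic given the config seed. A manifest with
#' md5 hashes and a timestamped run log are written alongside.
#'
#' @param config an [experiment_config()].
#' @param out_dir run directory (created if missing).
#' @param resume skip stages whose outputs exist (default TRUE).
#' @return invisible list with the key tables and the fitted models.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "a")
  on.exit(close(logf))
  pth <- function(...) file.path(out_dir, ...)
  done <- function(...) all(file.exists(pth(...)))
  seeds <- config$seed + 0:9

  stage <- function(name, outputs, fun) {
    if (resume && done(outputs)) {
      log_line(logf, "stage ", name, ": outputs present, skipped")
      return(invisible(NULL))
    }
    log_line(logf, "stage ", name, ": start")
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     log_line(logf, "stage ", name, " FAILED: ",
                              conditionMessage(e))
                     stop("pipeline halted at stage '", name, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    log_line(logf, "stage ", name, ": done")
  }

  # -- simulate -------------------------------------------------------------
  stage("simulate", c("ground_truth.csv", "calibration_obs.csv",
                      "counts.csv", "call_params.csv"), function() {
    paths <- lapply(seq_len(config$n_bats), function(i) {
      p <- simulate_trajectory(
        flight_regime(if (i %% 2 == 0) "commuting" else "foraging"),
        n_frames = config$n_frames, dt = config$linking$dt,
        seed = seeds[1] + i)
      attr(p, "path_id") <- i
      p
    })
    gt <- do.call(rbind, lapply(seq_along(paths), function(i)
      cbind(path_id = i, as.data.frame(paths[[i]]))))
    utils::write.csv(gt, pth("ground_truth.csv"), row.names = FALSE)
    cal <- simulate_calibration_sequence(config$rig, n_poses = 24,
                                         seed = seeds[2])
    utils::write.csv(cal$observations, pth("calibration_obs.csv"),
                     row.names = FALSE)
    utils::write.csv(simulate_counts(count_sim_params(
      n_sites = config$n_sites,
      n_nights_per_site = config$n_nights_per_site,
      n_blocks_per_night = config$n_blocks_per_night), seed = seeds[3]),
      pth("counts.csv"), row.names = FALSE)
    utils::write.csv(simulate_call_params(seed = seeds[4]),
                     pth("call_params.csv"), row.names = FALSE)
    stacks <- render_frames(paths, config$rig, n_frames = config$n_frames,
                            noise = config$noise, seed = seeds[5])
    write_frame_stack(stacks$left, pth("stack_left.tiff"))
    write_frame_stack(stacks$right, pth("stack_right.tiff"))
  })

  # -- calibrate ------------------------------------------------------------
  stage("calibrate", "rig.yaml", function() {
    obs <- read_csv_checked(pth("calibration_obs.csv"),
                            c("pose_id", "camera", "bulb_id", "u", "v"))
    rig <- calibrate_stereo(obs,
                            image_size = config$rig$left$intrinsics$image_size)
    write_rig_yaml(rig, pth("rig.yaml"))
  })

  # -- track ----------------------------------------------------------------
  stage("track", c("detections.csv", "localisations.csv",
                   "trajectories.csv"), function() {
    rig <- read_rig_yaml(pth("rig.yaml"))
    sl <- read_frame_stack(pth("stack_left.tiff"))
    sr <- read_frame_stack(pth("stack_right.tiff"))
    dl <- detect_stack(sl, config$pixel_threshold, "left")
    dr <- detect_stack(sr, config$pixel_threshold, "right")
    utils::write.csv(rbind(dl, dr), pth("detections.csv"), row.names = FALSE)
    locs <- pair_stereo(dl, dr, rig)
    utils::write.csv(locs, pth("localisations.csv"), row.names = FALSE)
    trajs <- qc_shared_points(build_trajectories(locs, config$linking))
    trajs <- Filter(Negate(is.null),
                    lapply(trajs, smooth_trajectory, params = config$linking))
    td <- do.call(rbind, lapply(seq_along(trajs), function(i)
      cbind(trajectory_id = i, as.data.frame(trajs[[i]]))))
    utils::write.csv(td, pth("trajectories.csv"), row.names = FALSE)
  })

  # -- metrics --------------------------------------------------------------
  stage("metrics", "metrics.csv", function() {
    td <- read_csv_checked(pth("trajectories.csv"),
                           c("trajectory_id", "frame", "x", "y", "z"))
    trajs <- split(td, td$trajectory_id)
    utils::write.csv(
      trajectory_metrics(trajs, dt = config$linking$dt,
                         deterrent_offset = config$deterrent_offset),
      pth("metrics.csv"), row.names = FALSE)
  })

  # -- soundfield -----------------------------------------------------------
  stage("soundfield", "soundfield.csv", function() {
    utils::write.csv(spl_table(config$sound), pth("soundfield.csv"),
                     row.names = FALSE)
  })

  # -- analyze --------------------------------------------------------------
  stage("analyze", c("count_models.csv", "composition.csv"), function() {
    counts <- read_csv_checked(pth("counts.csv"),
                               c("site", "night", "block", "treatment",
                                 "series", "count"))
    res <- NULL
    for (s in unique(counts$series)) {
      cb <- counts[counts$series == s, ]
      m <- tryCatch(fit_count_model(cb), error = function(e) NULL)
      if (is.null(m)) next
      pr <- m$percent_reduction
      res <- rbind(res, data.frame(
        series = s, family = m$family, rate_ratio = m$rate_ratio,
        raw_percent = pr[["raw_percent"]],
        model_percent = pr[["model_percent"]],
        chisq = m$lrt_chisq, df = m$lrt_df, p = m$p))
    }
    utils::write.csv(res, pth("count_models.csv"), row.names = FALSE)
    passes <- counts[counts$event == "pass", ]
    utils::write.csv(composition_table(passes), pth("composition.csv"),
                     row.names = FALSE)
  })

  # manifest ---------------------------------------------------------------
  files <- setdiff(list.files(out_dir), c("manifest.csv", "run.log"))
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(pth(files))))
  utils::write.csv(manifest, pth("manifest.csv"), row.names = FALSE)
  log_line(logf, "pipeline complete: ", nrow(manifest), " artefacts")
  invisible(list(out_dir = out_dir, manifest = manifest))
}
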