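#' Pipeline configuration
#'
#' All stage parameters in one validated bundle. Defaults: ratio threshold
#' 0.80, disc diameter 5 px, feature interval delta = 1 s, step sampling
#' dt = 1 s, turning threshold theta = 40 deg, grid cell 1 mm^2, occupancy
#' interval tau = 60 s, tail floor 10 steps, analysis window 20 minutes,
#' calibration 128 px/mm.
#'
#' @param sigma Gaussian smoothing sigma (px).
#' @param threshold_ratio adaptive threshold ratio in (0, 1).
#' @param window adaptive threshold neighborhood side (odd px).
#' @param disk_width closing disc diameter (odd px).
#' @param min_area,max_area worm area plausibility bounds (px^2).
#' @param reject_border reject components touching the frame border.
#' @param calibration pixels per mm.
#' @param delta movement-feature interval (s).
#' @param dt step-analysis sampling interval (s).
#' @param theta turning threshold angle (deg).
#' @param cell_size occupancy cell side (mm).
#' @param tau occupancy/locality interval (s).
#' @param min_tail smallest admissible power-law tail.
#' @param window_minutes analysis window in minutes (NULL = whole recording).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(sigma = 1, threshold_ratio = 0.80, window = 25L,
                            disk_width = 5L, min_area = 50L, max_area = 5000L,
                            reject_border = TRUE, calibration = 128,
                            delta = 1, dt = 1, theta = 40, cell_size = 1,
                            tau = 60, min_tail = 10L, window_minutes = 20) {
  cfg <- list(sigma = sigma, threshold_ratio = threshold_ratio,
              window = as.integer(window), disk_width = as.integer(disk_width),
              min_area = as.integer(min_area), max_area = as.integer(max_area),
              reject_border = isTRUE(reject_border), calibration = calibration,
              delta = delta, dt = dt, theta = theta, cell_size = cell_size,
              tau = tau, min_tail = as.integer(min_tail),
              window_minutes = window_minutes)
  stopifnot(cfg$sigma > 0, cfg$threshold_ratio > 0, cfg$threshold_ratio < 1,
            cfg$window >= 3L, cfg$window %% 2L == 1L, cfg$disk_width >= 1L,
            cfg$calibration > 0, cfg$delta > 0, cfg$dt > 0,
            cfg$theta > 0, cfg$theta < 180, cfg$cell_size > 0, cfg$tau > 0,
            cfg$min_tail >= 2L)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' Round-trips losslessly; unknown keys in the file are rejected.
#'
#' @param path file path.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$window_minutes) && length(vals$window_minutes) == 0)
    vals$window_minutes <- NULL
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.seg_config <- function(cfg) {
  segmentation_config(sigma = cfg$sigma, threshold_ratio = cfg$threshold_ratio,
                      window = cfg$window, disk_width = cfg$disk_width,
                      min_area = cfg$min_area, max_area = cfg$max_area,
                      reject_border = cfg$reject_border)
}

#' Run the analysis pipeline
#'
#' Executes every stage downstream of the entry point: segmentation (when
#' frames are given), global path reconstruction, movement features, cell
#' occupancy and locality, turning-event step lengths, and the power-law fit
#' over the configured analysis window. Entering with a ready-made centroid
#' path skips the imaging stages and yields identical downstream output.
#'
#' @param path a `worm_path` (mm) or path to a path CSV; alternatively NULL
#'   when `frames` + `camera_log` are given.
#' @param frames a [frame_stack()] of camera views (optional entry point).
#' @param camera_log camera log data.frame or CSV path (required with
#'   `frames`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; stage CSVs, a summary row and a run log
#'   are written there.
#' @return list with `path`, `features`, `occupancy`, `locality`, `steps`,
#'   `fit` (a `powerlaw_fit`), and `summary` (one Table-style row: recording
#'   length, step counts and tail statistics plus `walk_class`).
#' @export
run_pipeline <- function(path = NULL, frames = NULL, camera_log = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.null(path)) {
    if (is.null(frames) || is.null(camera_log))
      stop("either `path` or both `frames` and `camera_log` must be given")
    if (is.character(camera_log)) camera_log <- read_camera_log(camera_log)
    cens <- segment_stack(frames, .seg_config(config))
    path <- reconstruct_global(cens, camera_log, config$calibration)
  } else if (is.character(path)) {
    path <- read_path_csv(path, calibration = config$calibration)
  }
  features <- movement_features(path, config$delta)
  occupancy <- cell_occupancy(path, config$cell_size, config$tau)
  loc <- locality(features, occupancy)
  steps <- path_steps(path, dt = config$dt, theta = config$theta)
  fit <- fit_steps(steps, min_tail = config$min_tail,
                   window_minutes = config$window_minutes)
  summary_row <- summary(fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_path_csv(path, file.path(out_dir, "path.csv"))
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(loc, file.path(out_dir, "locality.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(occupancy), file.path(out_dir, "occupancy.csv"),
                     row.names = FALSE)
    write_steps_csv(steps, file.path(out_dir, "steps.csv"))
    utils::write.csv(summary_row, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(package = "wormpath",
           version = as.character(utils::packageVersion("wormpath")),
           config = unclass(config)),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(path = path, features = features, occupancy = occupancy,
       locality = loc, steps = steps, fit = fit, summary = summary_row)
}

#' Simulate, record, track and analyze a virtual experiment
#'
#' End-to-end closure over the whole stack: simulates a trajectory, renders
#' it through a virtual camera, runs the difference-image tracking loop
#' (segmenting each view on the fly), reconstructs the global path from the
#' synthetic camera log, and runs the analysis pipeline on the result.
#'
#' @param spec a [trajectory_spec()].
#' @param world a [world_spec()]; defaults to a world matching the spec's
#'   arena with 5 artifacts.
#' @param config a [pipeline_config()] (calibration is taken from the world).
#' @param tracker_cfg a [tracker_config()]; view size is taken from the
#'   world.
#' @param seed seed for rendering noise.
#' @return list as [run_pipeline()], plus `truth` (ground-truth world-px
#'   centroids), `camera_log`, `n_moves` and `sim` (the simulation output).
#' @export
run_virtual_experiment <- function(spec, world = NULL, config = NULL,
                                   tracker_cfg = NULL, seed = 1L) {
  if (is.null(world)) world <- add_artifacts(world_spec(arena = spec$arena), seed = seed)
  if (is.null(config))
    config <- pipeline_config(calibration = world$calibration,
                              min_area = 60L, max_area = 2000L)
  if (is.null(tracker_cfg))
    tracker_cfg <- tracker_config(subsample_hz = 1 / spec$dt,
                                  view_width = world$view_px[[1L]],
                                  view_height = world$view_px[[2L]],
                                  crop_size = 80L)
  sim <- simulate_trajectory(spec)
  src <- make_world_source(world, sim$path, seed = seed)
  seg_cfg <- .seg_config(config)
  cens <- new.env(parent = emptyenv()); cens$rows <- list()
  cb <- function(view, frame, cam, t) {
    seg <- segment_frame(worm_frame(view, index = frame, timestamp = t), seg_cfg)
    cen <- seg$centroid
    cens$rows[[as.character(frame)]] <- data.frame(
      frame = frame, t = t,
      cx = if (cen$valid) cen$x else NA_real_,
      cy = if (cen$valid) cen$y else NA_real_,
      area = cen$area, valid = cen$valid)
  }
  start_cam <- c(sim$path$x[[1L]] * world$calibration - world$view_px[[1L]] / 2,
                 sim$path$y[[1L]] * world$calibration - world$view_px[[2L]] / 2)
  tr <- track_stream(src, tracker_cfg, timestamps = attr(src, "timestamps"),
                     cam_start = round(start_cam), frame_callback = cb)
  centroids <- do.call(rbind, unname(cens$rows))
  centroids <- centroids[order(centroids$frame), , drop = FALSE]
  path <- reconstruct_global(centroids, tr$camera_log, world$calibration)
  out <- run_pipeline(path = path, config = config)
  out$truth <- attr(src, "truth")()
  out$camera_log <- tr$camera_log
  out$n_moves <- tr$n_moves
  out$sim <- sim
  out
}
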