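# Orchestration: experiment configuration, the seeded end-to-end runner and
# pose-track file I/O.

#' Default experiment configuration
#'
#' Nested list consumed by [run_experiment()]. The default "desk" profile
#' uses a 64 x 64 retinal grid and a 20 s walk, which runs in well under five
#' minutes on one CPU; the full-resolution profile of the analyses this
#' emulates (250 x 250 grid, minutes-long walks) is reached by raising
#' `grid$n` and `duration_s`.
#'
#' @param terrain_class terrain class for the run.
#' @param duration_s walk duration, seconds.
#' @param grid_n retinal grid side length.
#' @param seed master seed; deterministic sub-seeds are derived from it for
#'   every stochastic stage.
#' @return a named list with sections `terrain`, `gait`, `gaze`, `grid`,
#'   `analysis`, and `seed`.
#' @export
default_config <- function(terrain_class = "rocks", duration_s = 20,
                           grid_n = 64, seed = 1) {
  list(
    terrain = list(class = terrain_class, extent_m = 60, width_m = 20,
                   cell_size = 0.1, correlation_length = 0.3),
    gait = list(walking_speed = 1.3, eye_height = 1.6, step_frequency = 1.8,
                vertical_amplitude = 0.025, lateral_amplitude = 0.04,
                lateral_yaw_amplitude = 12),
    gaze = list(lookahead_mean = NULL, lookahead_sd = 8,
                fixation_duration_range = c(0.2, 0.3), gain = 1,
                off_path_sd = 10, off_path_max = 30,
                min_target_distance = 0.5),
    grid = list(n = grid_n, max_ecc = 45),
    analysis = list(duration_s = duration_s, probe_eccentricity = 20,
                    pooling = "pooled", flow_stride = 1,
                    write_terrain = FALSE),
    seed = seed
  )
}

#' Validate an experiment configuration
#'
#' Checks that all required sections and fields are present and in range;
#' errors name the offending section/field.
#'
#' @param config a configuration list (see [default_config()]).
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  required <- c("terrain", "gait", "gaze", "grid", "analysis", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop_retflow(sprintf("config is missing section(s): %s",
                         paste(missing, collapse = ", ")),
                 "retflow_bad_config")
  }
  if (is.null(config$terrain$class) ||
      !config$terrain$class %in% names(.terrain_classes)) {
    stop_retflow("config section 'terrain': unknown or missing class",
                 "retflow_bad_config")
  }
  if (is.null(config$grid$n) || config$grid$n < 2) {
    stop_retflow("config section 'grid': n must be at least 2",
                 "retflow_bad_config")
  }
  if (!is.null(config$gaze$gain) &&
      (config$gaze$gain < 0 || config$gaze$gain > 1)) {
    stop_retflow("config section 'gaze': gain must be in [0, 1]",
                 "retflow_bad_config")
  }
  if (is.null(config$analysis$duration_s) || config$analysis$duration_s <= 0) {
    stop_retflow("config section 'analysis': duration_s must be positive",
                 "retflow_bad_config")
  }
  invisible(config)
}

# Deterministic sub-seeds per stage, derived from the master seed.
.sub_seed <- function(seed, stage) {
  (as.integer(seed) * 1000L + stage) %% .Machine$integer.max
}

#' Run a full simulated experiment
#'
#' Terrain -> head trajectory -> gaze sequence -> segmentation -> retinal
#' flow -> pooled statistics, all driven by the master seed, with results
#' written as CSV files plus a JSON provenance record. Re-running with an
#' identical configuration reproduces every CSV byte-for-byte.
#'
#' @param config a [default_config()]-style list.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`terrain`, `track`,
#'   `kin`, `segments`, `flow`, `speed_map`, `direction`, `probe_hists`,
#'   `slip`, `stabilization`) and `files` (the paths written).
#' @export
run_experiment <- function(config, outdir) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  terrain <- do.call(make_terrain, c(
    list(terrain_class = config$terrain$class, seed = .sub_seed(seed, 1L)),
    config$terrain[setdiff(names(config$terrain), "class")]))
  gait <- do.call(gait_params, c(config$gait, list(seed = .sub_seed(seed, 2L))))
  gaze_args <- config$gaze
  if (is.null(gaze_args$lookahead_mean)) {
    gaze <- do.call(gaze_params_for_terrain,
                    c(list(terrain_class = config$terrain$class),
                      gaze_args[!vapply(gaze_args, is.null, TRUE)],
                      list(seed = .sub_seed(seed, 3L))))
  } else {
    gaze <- do.call(gaze_params, c(gaze_args, list(seed = .sub_seed(seed, 3L))))
  }
  head_track <- simulate_head_trajectory(gait, config$analysis$duration_s)
  track <- simulate_gaze_sequence(head_track, gaze, terrain)
  grid <- retinal_grid(config$grid$n, config$grid$max_ecc)
  kin <- eye_in_orbit_kinematics(track)
  segments <- segment_fixations(kin)
  flow <- flow_for_track(track, terrain, grid,
                         stride = config$analysis$flow_stride)
  smap <- pool_speed_map(flow, grid)
  dirs <- direction_summary(flow, grid)
  probes <- probe_set(grid, min(config$analysis$probe_eccentricity,
                                grid$max_ecc))
  phists <- probe_distributions(flow, probes)
  slip <- slip_analysis(track, segments_from_labels(track), terrain)
  stab <- stabilization_summary(kin, segments)

  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  write_pose_track(track, file.path(outdir, "track.csv"))
  files <- c(files, file.path(outdir, "track.csv"))
  wr(segments, "segments.csv")
  wr(data.frame(x = grid$gx, y = grid$gy,
                mean_speed = smap$mean_speed, count = smap$count,
                mean_direction = dirs$mean_direction), "speed_map.csv")
  wr(dirs$direction_hist, "direction_hist.csv")
  wr(do.call(rbind, lapply(names(phists), function(nm) {
    cbind(probe = nm, phists[[nm]])
  })), "probe_hists.csv")
  wr(slip$hist, "slip_hist.csv")
  wr(stab$speed_hist, "stabilization_speed_hist.csv")
  wr(stab$direction_hist, "stabilization_direction_hist.csv")
  if (isTRUE(config$analysis$write_terrain)) {
    write_terrain_ply(terrain, file.path(outdir, "terrain.ply"))
    files <- c(files, file.path(outdir, "terrain.ply"))
  }
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  prov <- list(
    package = "retflow",
    version = as.character(utils::packageVersion("retflow")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_frames = length(track$t),
    n_fixations = nrow(track$targets),
    n_flow_pairs = length(flow$fields),
    slip_median = slip$median,
    slip_mode = slip$mode
  )
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, cfg_path, file.path(outdir, "provenance.json"))

  invisible(list(terrain = terrain, track = track, kin = kin,
                 segments = segments, flow = flow, speed_map = smap,
                 direction = dirs, probe_hists = phists, slip = slip,
                 stabilization = stab, grid = grid, files = files))
}

#' Write / read an eye pose track as CSV
#'
#' Columns `t`, `px`, `py`, `pz`, `gx`, `gy`, `gz`, `label_kind`, `label_id`.
#' The reader validates monotone timestamps and resamples non-120 Hz input
#' onto the 120 Hz lattice via [resample_linear()] (with a warning), which is
#' the ingestion path for externally recorded pose data.
#'
#' @param track an `eye_pose_track`.
#' @param path CSV file path.
#' @return `write_pose_track`: `path` invisibly; `read_pose_track`: an
#'   `eye_pose_track`.
#' @export
write_pose_track <- function(track, path) {
  df <- data.frame(t = track$t,
                   px = track$position[, 1], py = track$position[, 2],
                   pz = track$position[, 3],
                   gx = track$gaze[, 1], gy = track$gaze[, 2],
                   gz = track$gaze[, 3],
                   label_kind = track$label_kind, label_id = track$label_id)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_track
#' @export
read_pose_track <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "px", "py", "pz", "gx", "gy", "gz")
  if (!all(need %in% names(df))) {
    stop_retflow(sprintf("pose CSV is missing column(s): %s",
                         paste(setdiff(need, names(df)), collapse = ", ")),
                 "retflow_bad_track")
  }
  if (any(diff(df$t) <= 0)) {
    stop_retflow("pose CSV timestamps are not strictly increasing",
                 "retflow_bad_track")
  }
  pos <- as.matrix(df[, c("px", "py", "pz")])
  gz <- as.matrix(df[, c("gx", "gy", "gz")])
  kind <- if ("label_kind" %in% names(df)) df$label_kind else
    rep("fixation", nrow(df))
  id <- if ("label_id" %in% names(df)) df$label_id else rep(1L, nrow(df))
  dt <- diff(df$t)
  if (any(abs(dt - 1 / .retflow_sample_rate) > 1e-6)) {
    warning(sprintf("input is not sampled at %d Hz; resampling linearly",
                    .retflow_sample_rate), call. = FALSE)
    rp <- resample_linear(pos, t_in = df$t)
    rg <- resample_linear(gz, t_in = df$t)
    nearest <- vapply(rp$t, function(tt) which.min(abs(df$t - tt)), 1L)
    pos <- rp$y
    gz <- .normalize_rows(rg$y)
    kind <- kind[nearest]
    id <- id[nearest]
    tvec <- rp$t
  } else {
    gz <- .normalize_rows(gz)
    tvec <- df$t
  }
  structure(list(t = tvec, position = pos, gaze = gz,
                 label_kind = kind, label_id = id,
                 targets = NULL, yaw = NULL),
            class = "eye_pose_track")
}
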