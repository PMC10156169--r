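# Synthetic locomotion: gait-driven eye trajectories and saccade-and-fixate
# gaze sequences with a controllable stabilization gain.

#' Gait parameters
#'
#' Defaults describe ordinary adult walking: 1.3 m/s forward speed, 1.6 m eye
#' height, 1.8 Hz step frequency, vertical head oscillation (2 x step
#' frequency) of 2.5 cm amplitude, lateral sway (1 x step frequency) of 4 cm,
#' and a body-yaw oscillation of +-12 deg that steers where fixation targets
#' are placed (walkers look where the body points). The sample rate is fixed
#' at the 120 Hz eye-tracker rate.
#'
#' @param walking_speed m/s.
#' @param eye_height m.
#' @param step_frequency Hz.
#' @param vertical_amplitude m (vertical sinusoid at 2 x step frequency).
#' @param lateral_amplitude m (lateral sinusoid at 1 x step frequency).
#' @param lateral_yaw_amplitude deg (body-yaw sinusoid at 1 x step frequency).
#' @param seed integer.
#' @return object of class `gait_params`.
#' @export
gait_params <- function(walking_speed = 1.3, eye_height = 1.6,
                        step_frequency = 1.8, vertical_amplitude = 0.025,
                        lateral_amplitude = 0.04, lateral_yaw_amplitude = 12,
                        seed = 1) {
  stopifnot(walking_speed > 0, eye_height > 0, step_frequency > 0,
            vertical_amplitude >= 0, lateral_amplitude >= 0,
            lateral_yaw_amplitude >= 0)
  structure(list(walking_speed = walking_speed, eye_height = eye_height,
                 step_frequency = step_frequency,
                 vertical_amplitude = vertical_amplitude,
                 lateral_amplitude = lateral_amplitude,
                 lateral_yaw_amplitude = lateral_yaw_amplitude,
                 sample_rate = .retflow_sample_rate, seed = seed),
            class = "gait_params")
}

#' Gaze-behavior parameters
#'
#' @param lookahead_mean mean vertical gaze angle (deg from the gravity
#'   vector; 0 = straight down, 90 = horizon) at fixation onset. Terrain
#'   profiles: rocky ~45 deg, flat/pavement ~85 deg (see
#'   [gaze_params_for_terrain()]).
#' @param lookahead_sd SD of the onset vertical gaze angle, deg.
#' @param fixation_duration_range fixation durations are drawn uniformly from
#'   this range, seconds (default 0.2-0.3 s).
#' @param gain stabilization gain `g` in `[0, 1]`: each frame the eye performs
#'   `g` times the incremental rotation that perfect world-fixed gaze would
#'   require. `g = 1` holds the gaze point exactly; `g < 1` accrues retinal
#'   slip at rate `(1 - g) * omega`.
#' @param off_path_mean mean lateral (off-path) target angle, deg; positive =
#'   rightward of the body direction (for emulating deliberate looks off the
#'   path).
#' @param off_path_sd SD of the lateral target angle, deg.
#' @param off_path_max clamp on the lateral target angle, deg.
#' @param min_target_distance m; a fixation ends early once the walker gets
#'   this close (horizontally) to its target.
#' @param seed integer.
#' @return object of class `gaze_params`.
#' @export
gaze_params <- function(lookahead_mean = 45, lookahead_sd = 8,
                        fixation_duration_range = c(0.2, 0.3), gain = 1,
                        off_path_mean = 0, off_path_sd = 10, off_path_max = 30,
                        min_target_distance = 0.5, seed = 1) {
  stopifnot(gain >= 0, gain <= 1, length(fixation_duration_range) == 2,
            all(fixation_duration_range > 0),
            diff(fixation_duration_range) >= 0,
            lookahead_sd >= 0, off_path_sd >= 0)
  structure(list(lookahead_mean = lookahead_mean, lookahead_sd = lookahead_sd,
                 fixation_duration_range = fixation_duration_range,
                 gain = gain, off_path_mean = off_path_mean,
                 off_path_sd = off_path_sd, off_path_max = off_path_max,
                 min_target_distance = min_target_distance, seed = seed),
            class = "gaze_params")
}

#' Terrain-typical gaze parameter profiles
#'
#' Look-ahead means per terrain class: walkers fixate 2-3 steps ahead
#' (~45 deg) on rocks and near the horizon (~85 deg) on pavement, with the
#' intermediate classes in between.
#'
#' @param terrain_class one of the five terrain classes.
#' @param ... overrides passed to [gaze_params()].
#' @return a `gaze_params` object.
#' @export
gaze_params_for_terrain <- function(terrain_class, ...) {
  means <- c(pavement = 87, flat = 85, medium = 65, bark = 70, rocks = 45)
  terrain_class <- match.arg(terrain_class, names(means))
  args <- list(...)
  if (is.null(args$lookahead_mean)) args$lookahead_mean <- unname(means[terrain_class])
  do.call(gaze_params, args)
}

#' Simulate a gait-driven head (eye-socket) trajectory
#'
#' Constant forward translation at `walking_speed` along `+x`, a vertical
#' sinusoid at twice the step frequency, a lateral sinusoid at the step
#' frequency, and a body-yaw sinusoid at the step frequency. Velocities are
#' analytic derivatives. The trajectory is deterministic given the
#' parameters.
#'
#' @param gait a [gait_params()] object.
#' @param duration_s track length, seconds (at least two gait cycles).
#' @return object of class `head_track`: list with `t` (s), `position` and
#'   `velocity` (N x 3, m and m/s), `yaw` (deg, body yaw about the vertical)
#'   and `gait`.
#' @export
#' @examples
#' h <- simulate_head_trajectory(gait_params(), 5)
#' range(h$position[, 3]) # eye_height +- vertical_amplitude
simulate_head_trajectory <- function(gait, duration_s) {
  stopifnot(inherits(gait, "gait_params"))
  if (duration_s < 2 / gait$step_frequency) {
    stop_retflow("duration must cover at least two gait cycles",
                 "retflow_bad_duration")
  }
  fs <- gait$sample_rate
  t <- seq(0, duration_s, by = 1 / fs)
  wf <- 2 * pi * gait$step_frequency
  pos <- cbind(gait$walking_speed * t,
               gait$lateral_amplitude * sin(wf * t),
               gait$eye_height + gait$vertical_amplitude * sin(2 * wf * t))
  vel <- cbind(rep(gait$walking_speed, length(t)),
               gait$lateral_amplitude * wf * cos(wf * t),
               gait$vertical_amplitude * 2 * wf * cos(2 * wf * t))
  yaw <- gait$lateral_yaw_amplitude * sin(wf * t)
  structure(list(t = t, position = pos, velocity = vel, yaw = yaw,
                 gait = gait), class = "head_track")
}

#' Sample a fixation target on the terrain surface
#'
#' Draws an onset vertical gaze angle (truncated to 5-95 deg) and a lateral
#' off-path angle, and casts the resulting ray from the eye onto the terrain.
#' Rays that miss the (finite) terrain are redrawn, up to `max_tries`.
#'
#' @param position eye position, world 3-vector.
#' @param heading_deg horizontal direction the walker is facing, deg
#'   (0 = `+x`, counterclockwise from above).
#' @param gaze a [gaze_params()] object.
#' @param terrain a [make_terrain()] object.
#' @param max_tries resample budget before erroring.
#' @return list with `target` (world 3-vector on the surface), `alpha_v`
#'   (onset vertical gaze angle, deg) and `beta` (lateral offset, deg).
#'   Uses the R RNG stream (seed it at the call site for reproducibility).
#' @export
select_fixation_target <- function(position, heading_deg, gaze, terrain,
                                   max_tries = 100) {
  for (k in seq_len(max_tries)) {
    alpha_v <- rnorm(1, gaze$lookahead_mean, gaze$lookahead_sd)
    if (alpha_v <= 5 || alpha_v >= 95) next
    beta <- max(-gaze$off_path_max,
                min(gaze$off_path_max,
                    rnorm(1, gaze$off_path_mean, gaze$off_path_sd)))
    az <- deg2rad(heading_deg + beta)
    h <- c(cos(az), sin(az), 0)
    d <- sin(deg2rad(alpha_v)) * h + cos(deg2rad(alpha_v)) * c(0, 0, -1)
    hit <- raycast_heightfield(as.numeric(position), matrix(d, 1, 3),
                               terrain$heights, terrain$x0, terrain$y0,
                               terrain$cell_size, terrain$cell_size / 2,
                               1e-9, 200)
    if (is.finite(hit)) {
      target <- position + hit * d
      if ((target[1] - position[1]) * cos(deg2rad(heading_deg)) +
          (target[2] - position[2]) * sin(deg2rad(heading_deg)) > 0) {
        return(list(target = target, alpha_v = alpha_v, beta = beta))
      }
    }
  }
  stop_retflow(sprintf("no fixation target found in %d tries (terrain too small or gaze too flat)",
                       max_tries), "retflow_target_failure")
}

# Saccade main sequence: duration (s) for an amplitude (deg). Standard
# oculomotor constants; peak velocities for the typical 5-15 deg locomotor
# saccades then land mostly below ~150 deg/s at the 120 Hz sampling.
.saccade_duration <- function(amplitude_deg) (21 + 2.2 * amplitude_deg) / 1000

#' Simulate a saccade-and-fixate gaze sequence over a head trajectory
#'
#' Alternates fixations (durations uniform in the configured range, ended
#' early if the target comes within `min_target_distance` of the walker) and
#' main-sequence saccades (duration 21 ms + 2.2 ms/deg, raised-cosine speed
#' profile) to new terrain targets. During a fixation the eye performs, each
#' frame, `gain` times the incremental rotation that exact world-fixed gaze
#' would require, so `gain = 1` keeps the gaze point stationary in the world
#' and `gain < 1` lets it slip at rate `(1 - gain) * omega`.
#'
#' @param head a [simulate_head_trajectory()] track.
#' @param gaze a [gaze_params()] object (its `seed` drives all target and
#'   duration draws).
#' @param terrain a [make_terrain()] object.
#' @return object of class `eye_pose_track`: list with `t`, `position`
#'   (N x 3), `gaze` (N x 3 unit), `label_kind` (`"fixation"`/`"saccade"`),
#'   `label_id` (integer, per segment), `targets` (one row per fixation id:
#'   world target and onset angles), `yaw` (copied from the head track) and
#'   the parameter objects.
#' @export
simulate_gaze_sequence <- function(head, gaze, terrain) {
  stopifnot(inherits(head, "head_track"), inherits(gaze, "gaze_params"))
  with_seed(gaze$seed, .simulate_gaze_sequence(head, gaze, terrain))
}

.simulate_gaze_sequence <- function(head, gaze, terrain) {
  pos <- head$position
  N <- nrow(pos)
  fs <- head$gait$sample_rate
  g <- gaze$gain
  gz <- matrix(NA_real_, N, 3)
  kind <- character(N)
  id <- integer(N)
  targets <- list()
  fix_id <- 0L
  sac_id <- 0L

  draw_dur_frames <- function() {
    max(1L, round(runif(1, gaze$fixation_duration_range[1],
                        gaze$fixation_duration_range[2]) * fs))
  }
  unit_to <- function(target, p) {
    d <- target - p
    d / sqrt(sum(d^2))
  }

  i <- 1L
  sel <- select_fixation_target(pos[i, ], head$yaw[i], gaze, terrain)
  target <- sel$target
  fix_id <- fix_id + 1L
  targets[[fix_id]] <- c(target, sel$alpha_v, sel$beta)
  gz[i, ] <- unit_to(target, pos[i, ])
  kind[i] <- "fixation"; id[i] <- fix_id
  frames_left <- draw_dur_frames() - 1L

  while (i < N) {
    i <- i + 1L
    too_close <- sqrt(sum((target[1:2] - pos[i, 1:2])^2)) < gaze$min_target_distance
    if (frames_left > 0L && !too_close) {
      # fixation frame: gain-scaled incremental stabilizing rotation
      ideal_prev <- unit_to(target, pos[i - 1L, ])
      ideal_cur <- unit_to(target, pos[i, ])
      if (g == 1) {
        gz[i, ] <- ideal_cur
      } else {
        rot <- .rotation_between(ideal_prev, ideal_cur)
        gz[i, ] <- drop(.rotate_about(gz[i - 1L, ], rot$axis,
                                      g * rot$angle_deg))
      }
      kind[i] <- "fixation"; id[i] <- fix_id
      frames_left <- frames_left - 1L
    } else {
      # saccade to a new target
      sel <- select_fixation_target(pos[i, ], head$yaw[i], gaze, terrain)
      target <- sel$target
      start_dir <- gz[i - 1L, ]
      amp <- angular_between(start_dir, unit_to(target, pos[i - 1L, ]))
      nf <- max(1L, round(.saccade_duration(amp) * fs))
      nf <- min(nf, N - i + 1L)
      sac_id <- sac_id + 1L
      for (k in seq_len(nf)) {
        tau <- k / nf
        s <- (1 - cos(pi * tau)) / 2
        j <- i + k - 1L
        gz[j, ] <- .slerp(start_dir, unit_to(target, pos[j, ]), s)
        kind[j] <- "saccade"; id[j] <- sac_id
      }
      i <- i + nf - 1L
      fix_id <- fix_id + 1L
      targets[[fix_id]] <- c(target, sel$alpha_v, sel$beta)
      frames_left <- draw_dur_frames()
    }
  }
  tg <- do.call(rbind, targets)
  colnames(tg) <- c("tx", "ty", "tz", "alpha_v_drawn", "beta_drawn")
  structure(list(t = head$t, position = pos, gaze = gz,
                 label_kind = kind, label_id = id,
                 targets = as.data.frame(tg), yaw = head$yaw,
                 gait = head$gait, gaze_params = gaze),
            class = "eye_pose_track")
}

#' @export
print.eye_pose_track <- function(x, ...) {
  nf <- sum(x$label_kind == "fixation")
  cat(sprintf("eye pose track: %d frames at %g Hz (%.1f s), %d fixation / %d saccade frames, %d fixations\n",
              length(x$t), .retflow_sample_rate, max(x$t),
              nf, sum(x$label_kind == "saccade"),
              length(unique(x$label_id[x$label_kind == "fixation"]))))
  invisible(x)
}

#' Vertical and horizontal gaze angles
#'
#' The vertical gaze angle `alpha_v` is the angle between gaze and the
#' gravity (down) vector: 0 = straight down, 90 = horizon. The horizontal
#' gaze angle `alpha_h` is the signed angle between gaze and the head
#' velocity direction, both projected into the horizontal plane, positive
#' clockwise when viewed from above.
#'
#' @param gaze N x 3 matrix (or 3-vector) of unit gaze directions.
#' @param head_velocity N x 3 matrix (or 3-vector) of head velocities, m/s.
#' @param gravity unit 3-vector, default `c(0, 0, -1)`.
#' @return data.frame with columns `alpha_v` (deg, `[0, 180]`) and `alpha_h`
#'   (deg, `(-180, 180]`). `alpha_h` is `NA` (with a warning) for frames
#'   whose horizontal head speed is below 1e-6 m/s.
#' @export
#' @examples
#' gaze_angles(c(0, 0, -1), c(1, 0, 0))  # alpha_v = 0
gaze_angles <- function(gaze, head_velocity, gravity = c(0, 0, -1)) {
  gaze <- .rows3(gaze)
  hv <- .rows3(head_velocity)
  if (nrow(hv) == 1 && nrow(gaze) > 1) hv <- hv[rep(1, nrow(gaze)), , drop = FALSE]
  down <- matrix(gravity / sqrt(sum(gravity^2)), nrow(gaze), 3, byrow = TRUE)
  alpha_v <- angular_between(gaze, down)
  hspeed <- sqrt(hv[, 1]^2 + hv[, 2]^2)
  undef <- hspeed <= 1e-6
  if (any(undef)) {
    warning("horizontal gaze angle undefined where head velocity is vertical/zero; returning NA",
            call. = FALSE)
  }
  # CCW (mathematical) angle from velocity to gaze in the horizontal plane,
  # then negated: clockwise-from-above positive.
  ccw <- atan2(hv[, 1] * gaze[, 2] - hv[, 2] * gaze[, 1],
               hv[, 1] * gaze[, 1] + hv[, 2] * gaze[, 2])
  alpha_h <- -rad2deg(ccw)
  alpha_h[alpha_h <= -180] <- alpha_h[alpha_h <= -180] + 360
  alpha_h[undef] <- NA_real_
  data.frame(alpha_v = alpha_v, alpha_h = alpha_h)
}
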