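# Eye-in-orbit kinematics, fixation/saccade segmentation and stabilizing
# movement summaries.

#' Segmentation thresholds
#'
#' Fixation frames are those whose eye-in-orbit angular speed is below
#' `velocity_threshold` AND whose speed change is below
#' `acceleration_threshold` (both conditions must hold). The acceleration is
#' the instantaneous first difference of the frame-pair speeds. Its unit is
#' configurable: `"deg_per_s_per_frame"` (default) thresholds the raw
#' per-frame speed change at 120 Hz, which is the only reading of a 5-unit
#' acceleration threshold consistent with smooth gait-driven stabilization
#' (whose literal acceleration is of order 100 deg/s^2); `"deg_per_s2"`
#' thresholds the difference multiplied by the frame rate.
#'
#' @param velocity_threshold deg/s (default 65).
#' @param acceleration_threshold default 5, in `acceleration_unit`.
#' @param acceleration_unit `"deg_per_s_per_frame"` or `"deg_per_s2"`.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(velocity_threshold = 65,
                                acceleration_threshold = 5,
                                acceleration_unit = c("deg_per_s_per_frame",
                                                      "deg_per_s2")) {
  stopifnot(velocity_threshold > 0, acceleration_threshold > 0)
  structure(list(velocity_threshold = velocity_threshold,
                 acceleration_threshold = acceleration_threshold,
                 acceleration_unit = match.arg(acceleration_unit)),
            class = "segmentation_params")
}

#' Eye-in-orbit kinematics of a gaze track
#'
#' Computes, per frame, the angular speed (deg/s) and speed change of the eye
#' relative to the head, and the movement direction of each frame pair in the
#' retinocentric convention (90 deg = up, 270 deg = down). The head frame is
#' gravity-levelled and, by default, aligned with the mean (path) travel
#' direction; `heading = "velocity"` aligns it with the instantaneous
#' horizontal head velocity instead, and `heading = "yaw"` uses the body-yaw
#' channel carried by the simulator. Frame `i` carries the speed of the
#' movement from frame `i` to `i + 1` (the last frame repeats its
#' predecessor); the speed change at frame `i` is `speed[i] - speed[i - 1]`.
#'
#' @param track an `eye_pose_track` (or any list with `gaze`, `position`, `t`).
#' @param heading `"path"`, `"velocity"` or `"yaw"`.
#' @return object of class `eye_kinematics`: list with `speed` (deg/s, length
#'   N), `accel_per_frame` (deg/s per frame), `accel` (deg/s^2), `direction`
#'   (deg, length N; `NA` on the last frame and where the eye did not move)
#'   and `n`.
#' @export
eye_in_orbit_kinematics <- function(track, heading = c("path", "velocity", "yaw")) {
  heading <- match.arg(heading)
  gz <- track$gaze
  N <- nrow(gz)
  stopifnot(N >= 3)
  yaw_deg <- switch(heading,
    path = {
      disp <- track$position[N, 1:2] - track$position[1, 1:2]
      rep(rad2deg(atan2(disp[2], disp[1])), N)
    },
    velocity = {
      v <- apply(track$position, 2, function(p) c(diff(p), NA)) * .retflow_sample_rate
      y <- rad2deg(atan2(v[, 2], v[, 1]))
      y[N] <- y[N - 1]
      y
    },
    yaw = {
      if (is.null(track$yaw)) stop_retflow("track carries no yaw channel", "retflow_bad_track")
      track$yaw
    })
  # eye-in-head gaze: undo the head yaw about the vertical
  ca <- cos(deg2rad(-yaw_deg)); sa <- sin(deg2rad(-yaw_deg))
  eh <- cbind(ca * gz[, 1] - sa * gz[, 2],
              sa * gz[, 1] + ca * gz[, 2],
              gz[, 3])
  pair_speed <- angular_between(eh[-N, , drop = FALSE],
                                eh[-1, , drop = FALSE]) * .retflow_sample_rate
  speed <- c(pair_speed, pair_speed[N - 1])
  accel_pf <- c(0, diff(speed))
  # movement direction of each frame pair, in the first frame's eye basis
  ef <- eye_frames(eh[-N, , drop = FALSE])
  v2 <- eh[-1, , drop = FALSE]
  dx <- rowSums(v2 * ef$X)
  dy <- rowSums(v2 * ef$Y)
  direction <- rad2deg(atan2(dy, dx)) %% 360
  direction[pair_speed < 1e-9] <- NA_real_
  structure(list(speed = speed, accel_per_frame = accel_pf,
                 accel = accel_pf * .retflow_sample_rate,
                 direction = c(direction, NA_real_), n = N),
            class = "eye_kinematics")
}

#' Segment a track into fixations and saccades
#'
#' A frame is a fixation frame iff its speed is below the velocity threshold
#' AND its speed change is below the acceleration threshold; runs of
#' same-kind frames merge into segments that tile the track without gaps.
#'
#' @param kin an [eye_in_orbit_kinematics()] result.
#' @param params a [segmentation_params()] object.
#' @return data.frame with columns `start`, `end` (frame indices, half-open
#'   `[start, end)` so `end` is one past the segment), `kind`
#'   (`"fixation"`/`"saccade"`) and `n_frames`.
#' @export
segment_fixations <- function(kin, params = segmentation_params()) {
  acc <- switch(params$acceleration_unit,
                deg_per_s_per_frame = kin$accel_per_frame,
                deg_per_s2 = kin$accel)
  is_fix <- kin$speed < params$velocity_threshold &
    abs(acc) < params$acceleration_threshold
  r <- rle(is_fix)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end + 1L,
             kind = ifelse(r$values, "fixation", "saccade"),
             n_frames = r$lengths)
}

#' World gaze points at fixation onsets
#'
#' Casts the onset-frame gaze ray of each fixation segment onto the terrain.
#'
#' @param segments a [segment_fixations()] data.frame.
#' @param track the corresponding pose track.
#' @param terrain a [make_terrain()] object.
#' @return `segments` with added columns `onset_x`, `onset_y`, `onset_z`
#'   (`NA` for saccade segments and for onset rays that miss the terrain).
#' @export
add_onset_gaze_points <- function(segments, track, terrain) {
  out <- cbind(segments, onset_x = NA_real_, onset_y = NA_real_,
               onset_z = NA_real_)
  fx <- which(segments$kind == "fixation")
  for (k in fx) {
    i <- segments$start[k]
    hit <- raycast_heightfield(as.numeric(track$position[i, ]),
                               matrix(track$gaze[i, ], 1, 3),
                               terrain$heights, terrain$x0, terrain$y0,
                               terrain$cell_size, terrain$cell_size / 2,
                               1e-9, 200)
    if (is.finite(hit)) {
      out[k, c("onset_x", "onset_y", "onset_z")] <-
        track$position[i, ] + hit * track$gaze[i, ]
    }
  }
  out
}

#' Summaries of stabilizing eye movements
#'
#' Speed histogram and 24-bin (15 deg) polar direction histogram of the
#' eye-in-orbit rotations on fixation frames, each normalized to sum to 1.
#' Direction bins are centered on 0, 15, 30, ... deg so that straight down
#' (270 deg) falls at a bin center.
#'
#' @param kin an [eye_in_orbit_kinematics()] result.
#' @param segments a [segment_fixations()] data.frame.
#' @param speed_breaks histogram breaks for the speed distribution, deg/s.
#' @return list with `speed_hist` and `direction_hist` (data.frames with bin
#'   edges/centers and normalized density), `n_frames`.
#' @export
stabilization_summary <- function(kin, segments,
                                  speed_breaks = seq(0, 70, by = 1)) {
  fix <- segments[segments$kind == "fixation", , drop = FALSE]
  if (nrow(fix) == 0) {
    stop_retflow("no fixation segments to summarize", "retflow_empty_segmentation")
  }
  idx <- unlist(mapply(function(s, e) s:(e - 1L), fix$start, fix$end,
                       SIMPLIFY = FALSE))
  idx <- idx[idx < kin$n] # pair-based measures undefined on the last frame
  sp <- kin$speed[idx]
  sp <- pmin(sp, max(speed_breaks)) # clamp into the top bin
  sc <- tabulate(findInterval(sp, speed_breaks, rightmost.closed = TRUE),
                 nbins = length(speed_breaks) - 1)
  dr <- kin$direction[idx]
  dr <- dr[!is.na(dr)]
  centers <- seq(0, 345, by = 15)
  b <- floor(((dr + 7.5) %% 360) / 15) + 1L
  dc <- tabulate(b, nbins = 24)
  list(
    speed_hist = data.frame(bin_left = head(speed_breaks, -1),
                            bin_right = tail(speed_breaks, -1),
                            density = sc / sum(sc)),
    direction_hist = data.frame(center = centers, density = dc / sum(dc)),
    n_frames = length(idx)
  )
}

#' Linear resampling onto the 120 Hz lattice
#'
#' Upsamples a uniformly sampled signal (e.g. 100 Hz motion-capture data) to
#' the 120 Hz eye-tracker rate by linear interpolation. Output timestamps are
#' `t[1] + k/120` spanning the input range; endpoints are preserved when they
#' fall on the lattice.
#'
#' @param y numeric vector or matrix (columns resampled independently).
#' @param rate_in input sample rate, Hz.
#' @param t_in optional input timestamps (overrides `rate_in`); must be
#'   uniformly spaced.
#' @return list with `t` (output timestamps) and `y`.
#' @export
resample_linear <- function(y, rate_in = 100, t_in = NULL) {
  ym <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  n <- nrow(ym)
  if (n < 2) stop_retflow("need at least 2 samples to resample", "retflow_bad_signal")
  if (is.null(t_in)) t_in <- (seq_len(n) - 1) / rate_in
  dt <- diff(t_in)
  if (any(abs(dt - dt[1]) > 1e-9)) {
    stop_retflow("input spacing is not uniform", "retflow_bad_signal")
  }
  t_out <- seq(t_in[1], t_in[n] + 1e-12, by = 1 / .retflow_sample_rate)
  out <- apply(ym, 2, function(col) approx(t_in, col, xout = t_out)$y)
  list(t = t_out, y = if (is.matrix(y)) out else drop(out))
}
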