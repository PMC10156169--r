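# The retinal flow engine: frame-pair speed/direction fields from depth +
# pose change, a closed-form rigid-scene oracle, and uniform-slip injection.

.new_flow_field <- function(speed, direction, valid, n, frame_index = NA) {
  structure(list(speed = speed, direction = direction, valid = valid,
                 n = n, frame_index = frame_index), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("flow field: %d x %d, %d valid cells, speed median %.3g deg/s (max %.3g)\n",
              x$n, x$n, sum(ok),
              if (any(ok)) median(x$speed[ok]) else NA,
              if (any(ok)) max(x$speed[ok]) else NA))
  invisible(x)
}

#' Retinal flow field for one frame pair
#'
#' For every valid grid cell, the 3D point `Q` seen along the cell's ray at
#' frame `t` (position + depth x ray direction in world) is re-projected from
#' the frame `t+1` pose. The retinal speed is the angle between the cell's
#' direction (in frame t's eye basis) and the re-projected direction (in
#' frame t+1's basis), divided by `dt`; the direction is the angle of the
#' displacement between the two directions' retinal chart coordinates
#' (90 deg = up, 270 deg = down). With perfect gaze stabilization the
#' fixated point re-projects onto the gaze axis in both frames, so the
#' foveal speed is zero.
#'
#' @param depth a [cast_depth()] map rendered at the frame-`t` pose on `grid`.
#' @param pos_t,pos_t1 eye positions, world 3-vectors.
#' @param frame_t,frame_t1 [build_eye_frame()] bases of the two frames.
#' @param grid the [retinal_grid()] the depth map was rendered on.
#' @param dt frame-pair interval, s (default 1/120).
#' @return a `flow_field`: list with `speed` (deg/s), `direction` (deg,
#'   `NA` where the cell did not move), `valid` (grid-valid AND depth hit AND
#'   re-projection in front of the eye), all length n^2, plus `n`.
#' @export
compute_flow_field <- function(depth, pos_t, frame_t, pos_t1, frame_t1, grid,
                               dt = 1 / .retflow_sample_rate) {
  if (length(depth$depth) != grid$n^2) {
    stop_retflow("depth map and grid shapes disagree", "retflow_shape_mismatch")
  }
  ncell <- grid$n^2
  speed <- rep(NA_real_, ncell)
  direction <- rep(NA_real_, ncell)
  valid <- rep(FALSE, ncell)
  ok <- grid$valid & is.finite(depth$depth)
  if (!any(ok)) return(.new_flow_field(speed, direction, valid, grid$n))
  M0 <- .frame_matrix(frame_t)
  M1 <- .frame_matrix(frame_t1)
  v1 <- grid$dirs[ok, , drop = FALSE]
  w <- v1 %*% M0                      # rays in world coordinates
  Q <- w * depth$depth[ok]
  Q[, 1] <- Q[, 1] + pos_t[1]; Q[, 2] <- Q[, 2] + pos_t[2]
  Q[, 3] <- Q[, 3] + pos_t[3]
  d1 <- Q
  d1[, 1] <- d1[, 1] - pos_t1[1]; d1[, 2] <- d1[, 2] - pos_t1[2]
  d1[, 3] <- d1[, 3] - pos_t1[3]
  v2w <- .normalize_rows(d1)
  v2 <- v2w %*% t(M1)                 # frame t+1 eye coordinates
  front <- v2[, 3] > 1e-12
  ang <- angular_between(v1, v2)
  g2 <- direction_to_grid(v2, strict = FALSE)
  dx <- g2$x - grid$gx[ok]
  dy <- g2$y - grid$gy[ok]
  dir <- rad2deg(atan2(dy, dx)) %% 360
  dir[ang < 1e-12] <- NA_real_
  idx <- which(ok)
  speed[idx] <- ang / dt
  direction[idx] <- dir
  valid[idx] <- front
  speed[idx[!front]] <- NA_real_
  direction[idx[!front]] <- NA_real_
  .new_flow_field(speed, direction, valid, grid$n)
}

#' Closed-form motion field over a ground plane
#'
#' The instantaneous rigid-scene motion field for an eye translating at `tvel`
#' and rotating at `omega` above a horizontal plane: for a scene point at
#' distance `Z` along the unit ray `d` (eye coordinates), the image-point
#' angular velocity is `-(T - (T.d)d)/Z - omega x d`. Serves as the
#' independent oracle for [compute_flow_field()]; it involves no frame-pair
#' discretization and no ray casting.
#'
#' @param plane_height plane elevation, m.
#' @param eye_position world 3-vector (above the plane).
#' @param eye_frame a [build_eye_frame()] basis.
#' @param tvel translational velocity, world 3-vector, m/s.
#' @param omega angular velocity of the eye, world 3-vector, rad/s.
#' @param grid a [retinal_grid()].
#' @return a `flow_field` (speed deg/s, direction deg); cells whose rays do
#'   not meet the plane are invalid.
#' @export
planar_motion_oracle <- function(plane_height, eye_position, eye_frame,
                                 tvel, omega, grid) {
  ncell <- grid$n^2
  speed <- rep(NA_real_, ncell)
  direction <- rep(NA_real_, ncell)
  valid <- rep(FALSE, ncell)
  M <- .frame_matrix(eye_frame)
  w <- grid$dirs %*% M
  Z <- (eye_position[3] - plane_height) / (-w[, 3])
  ok <- grid$valid & w[, 3] < 0 & Z > 0
  if (!any(ok)) return(.new_flow_field(speed, direction, valid, grid$n))
  # Evaluate the motion-field equation with world-coordinate vectors: the
  # retinocentric basis (Y = X x Z, chosen so 90 deg = up) is left-handed, so
  # cross products must not be formed from eye-frame component triples.
  wk <- w[ok, , drop = FALSE]
  TdotD <- drop(wk %*% tvel)
  Tperp <- matrix(tvel, nrow(wk), 3, byrow = TRUE) - wk * TdotD
  Om <- matrix(omega, nrow(wk), 3, byrow = TRUE)
  ddot <- -Tperp / Z[ok] - .cross3(Om, wk)
  sp <- rad2deg(sqrt(rowSums(ddot^2)))
  # direction in the retinal chart: displace the ray infinitesimally along
  # ddot, then convert both directions to eye-frame components
  eps <- 1e-8
  d <- grid$dirs[ok, , drop = FALSE]
  d2 <- .normalize_rows(wk + eps * ddot) %*% t(M)
  g1 <- direction_to_grid(d, strict = FALSE)
  g2 <- direction_to_grid(d2, strict = FALSE)
  dir <- rad2deg(atan2(g2$y - g1$y, g2$x - g1$x)) %% 360
  dir[sp < 1e-12] <- NA_real_
  idx <- which(ok)
  speed[idx] <- sp
  direction[idx] <- dir
  valid[idx] <- TRUE
  .new_flow_field(speed, direction, valid, grid$n)
}

#' Add a uniform retinal slip to a flow field
#'
#' Adds a constant velocity vector (rate + direction in the retinal chart) to
#' every valid cell and recomputes speeds and directions; emulates the motion
#' added by imperfect gaze stabilization, which appears as a uniform drift of
#' the whole field.
#'
#' @param flow a `flow_field`.
#' @param slip_rate deg/s (>= 0).
#' @param slip_direction deg (270 = downward slip).
#' @return the modified `flow_field`.
#' @export
#' @examples
#' # a zero field plus 3.2 deg/s of downward slip moves at 3.2 deg/s everywhere
add_uniform_slip <- function(flow, slip_rate, slip_direction = 270) {
  stopifnot(slip_rate >= 0)
  if (slip_rate == 0) return(flow)
  ok <- flow$valid
  dr <- deg2rad(ifelse(is.na(flow$direction[ok]), 0, flow$direction[ok]))
  u <- flow$speed[ok] * cos(dr) + slip_rate * cos(deg2rad(slip_direction))
  v <- flow$speed[ok] * sin(dr) + slip_rate * sin(deg2rad(slip_direction))
  sp <- sqrt(u^2 + v^2)
  di <- rad2deg(atan2(v, u)) %% 360
  di[sp < 1e-12] <- NA_real_
  flow$speed[ok] <- sp
  flow$direction[ok] <- di
  flow
}

#' Compare the frame-pair flow engine with the closed-form oracle
#'
#' Draws stabilized fixation frame pairs from a track over flat (zero-height)
#' terrain, computes the frame-pair flow field, and evaluates
#' [planar_motion_oracle()] at the mid-frame pose with finite-difference
#' velocities (translation from the position difference, rotation from the
#' axis-angle of the eye-basis change). Because the frame-pair estimate is the
#' average flow along each tracked point's retinal path, the oracle is
#' evaluated at the mid-path retinal location of every cell (the comparison is
#' then second-order accurate in the frame interval instead of first-order).
#'
#' @param track an `eye_pose_track` simulated with `gain = 1`.
#' @param terrain the flat terrain the track was simulated over (roughness
#'   amplitude must be 0, so the plane `z = 0` is the exact scene).
#' @param grid a [retinal_grid()].
#' @param n_pairs number of fixation frame pairs to compare.
#' @param seed seed for the pair draw.
#' @return list with `max_speed_err` (deg/s), `max_direction_err` (deg;
#'   over cells with speed > 1 deg/s) and `per_pair` (data.frame).
#' @export
compare_flow_to_oracle <- function(track, terrain, grid, n_pairs = 50,
                                   seed = 1) {
  if (terrain$roughness_amplitude != 0) {
    stop_retflow("oracle comparison requires flat (zero-amplitude) terrain",
                 "retflow_bad_terrain")
  }
  dt <- 1 / .retflow_sample_rate
  N <- nrow(track$gaze)
  eligible <- which(track$label_kind[-N] == "fixation" &
                      track$label_kind[-1] == "fixation" &
                      track$label_id[-N] == track$label_id[-1])
  sel <- with_seed(seed, sample(eligible, min(n_pairs, length(eligible))))
  ef <- eye_frames(track$gaze)
  sp_err <- dir_err <- numeric(length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    f0 <- list(X = ef$X[i, ], Y = ef$Y[i, ], Z = ef$Z[i, ])
    f1 <- list(X = ef$X[i + 1, ], Y = ef$Y[i + 1, ], Z = ef$Z[i + 1, ])
    dm <- cast_depth(terrain, track$position[i, ], f0, grid)
    fl <- compute_flow_field(dm, track$position[i, ], f0,
                             track$position[i + 1, ], f1, grid, dt = dt)
    B0 <- cbind(f0$X, f0$Y, f0$Z)
    B1 <- cbind(f1$X, f1$Y, f1$Z)
    aa <- .rotmat_axis_angle(B1 %*% t(B0))
    omega <- aa$axis * deg2rad(aa$angle_deg) / dt
    Bh <- .rotate_about(t(B0), aa$axis, aa$angle_deg / 2)
    fh <- list(X = Bh[1, ], Y = Bh[2, ], Z = Bh[3, ])
    tvel <- (track$position[i + 1, ] - track$position[i, ]) / dt
    pm <- (track$position[i, ] + track$position[i + 1, ]) / 2
    ok <- fl$valid & !is.na(fl$direction)
    disp <- fl$speed * dt
    mx <- grid$gx + ifelse(ok, disp * cos(deg2rad(fl$direction)) / 2, 0)
    my <- grid$gy + ifelse(ok, disp * sin(deg2rad(fl$direction)) / 2, 0)
    pg <- list(n = grid$n, max_ecc = grid$max_ecc, gx = mx, gy = my,
               dirs = grid_to_direction(mx, my),
               valid = ok & sqrt(mx^2 + my^2) <= 89)
    or <- planar_motion_oracle(0, pm, fh, tvel, omega, pg)
    cmp <- ok & or$valid
    sp_err[k] <- max(abs(fl$speed[cmp] - or$speed[cmp]))
    fast <- cmp & fl$speed > 1 & !is.na(or$direction)
    dd <- abs(fl$direction[fast] - or$direction[fast])
    dd <- pmin(dd, 360 - dd)
    dir_err[k] <- if (any(fast)) max(dd) else 0
  }
  list(max_speed_err = max(sp_err), max_direction_err = max(dir_err),
       per_pair = data.frame(frame = sel, speed_err = sp_err,
                             direction_err = dir_err))
}

#' Retinal flow for a whole pose track
#'
#' Renders a depth map at every selected frame and computes the flow field of
#' each consecutive frame pair that stays within one segment (both frames
#' share a label). This is the workhorse that turns a simulated (or imported)
#' pose track over a terrain into the sample of flow fields all pooled
#' statistics are built from.
#'
#' @param track an `eye_pose_track`.
#' @param terrain a [make_terrain()] object.
#' @param grid a [retinal_grid()].
#' @param kinds which segment kinds to compute flow for (default
#'   `"fixation"`; the motion generated by saccades is analysed separately).
#' @param stride keep every `stride`-th eligible frame pair (1 = all).
#' @return object of class `flow_set`: list with `fields` (list of
#'   `flow_field`s) and `meta` (data.frame: `frame`, `kind`, `id`,
#'   onset gaze angles `alpha_v`, `alpha_h` of the segment the pair belongs
#'   to), plus `grid_n`.
#' @export
flow_for_track <- function(track, terrain, grid,
                           kinds = "fixation", stride = 1L) {
  N <- nrow(track$gaze)
  ef <- eye_frames(track$gaze)
  same <- track$label_kind[-N] == track$label_kind[-1] &
    track$label_id[-N] == track$label_id[-1]
  sel <- which(same & track$label_kind[-N] %in% kinds)
  sel <- sel[seq(1, length(sel), by = stride)]
  # per-segment onset gaze angles (horizontal angle vs the mean path heading)
  onset_av <- rep(NA_real_, N); onset_ah <- rep(NA_real_, N)
  seg_key <- paste(track$label_kind, track$label_id)
  onset_idx <- which(!duplicated(seg_key))
  disp <- track$position[N, 1:2] - track$position[1, 1:2]
  path_vel <- c(disp, 0)
  ga <- gaze_angles(track$gaze[onset_idx, , drop = FALSE],
                    matrix(path_vel, length(onset_idx), 3, byrow = TRUE))
  onset_av[onset_idx] <- ga$alpha_v
  onset_ah[onset_idx] <- ga$alpha_h
  seg_onset <- onset_idx[match(seg_key, seg_key[onset_idx])]
  fields <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    f0 <- list(X = ef$X[i, ], Y = ef$Y[i, ], Z = ef$Z[i, ])
    f1 <- list(X = ef$X[i + 1, ], Y = ef$Y[i + 1, ], Z = ef$Z[i + 1, ])
    dm <- cast_depth(terrain, track$position[i, ], f0, grid)
    fl <- compute_flow_field(dm, track$position[i, ], f0,
                             track$position[i + 1, ], f1, grid)
    fl$frame_index <- i
    fields[[k]] <- fl
  }
  meta <- data.frame(frame = sel,
                     kind = track$label_kind[sel],
                     id = track$label_id[sel],
                     alpha_v = onset_av[seg_onset[sel]],
                     alpha_h = onset_ah[seg_onset[sel]])
  structure(list(fields = fields, meta = meta, grid_n = grid$n),
            class = "flow_set")
}

#' @export
print.flow_set <- function(x, ...) {
  cat(sprintf("flow set: %d frame-pair fields on a %d x %d grid (%s)\n",
              length(x$fields), x$grid_n, x$grid_n,
              paste(sprintf("%s: %d", names(table(x$meta$kind)),
                            as.integer(table(x$meta$kind))), collapse = ", ")))
  invisible(x)
}

#' Subset a flow set
#'
#' @param x a `flow_set`.
#' @param i indices into the fields.
#' @param ... unused.
#' @return a `flow_set`.
#' @export
`[.flow_set` <- function(x, i, ...) {
  structure(list(fields = x$fields[i], meta = x$meta[i, , drop = FALSE],
                 grid_n = x$grid_n), class = "flow_set")
}
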