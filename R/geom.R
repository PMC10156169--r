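# Coordinate frames, the retinocentric grid and angular arithmetic.
#
# All directions are unit 3-vectors. The retinal chart is azimuthal
# equidistant: a grid point (x, y) in degrees lies at eccentricity
# phi = sqrt(x^2 + y^2) from the gaze direction, at polar angle
# theta = atan2(y, x) around it.

.cross3 <- function(u, v) {
  # row-wise cross product of m x 3 matrices
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

.rows3 <- function(v) {
  if (is.matrix(v)) v else matrix(v, ncol = 3)
}

.normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

#' Angle between unit vectors, in degrees
#'
#' Numerically stable angular distance computed as
#' `atan2(|u x v|, u . v)`, which (unlike `acos(u . v)`) does not lose
#' precision for nearly parallel vectors.
#'
#' @param u,v unit 3-vectors, or m x 3 matrices of unit row vectors.
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angular_between(c(1, 0, 0), c(0, 1, 0)) # 90
angular_between <- function(u, v) {
  u <- .rows3(u); v <- .rows3(v)
  cr <- .cross3(u, v)
  rad2deg(atan2(sqrt(rowSums(cr^2)), rowSums(u * v)))
}

#' Build the retinocentric eye basis from a gaze direction
#'
#' The basis is `Z` = gaze, `X` = normalize(Z x up) (horizontal, perpendicular
#' to gaze and gravity), `Y` = X x Z ("up-ish", so that retinal polar angle
#' 90 deg is the upper visual field and 270 deg the lower). The basis assumes
#' zero ocular torsion: `X` always lies in the plane perpendicular to gravity.
#'
#' @param gaze unit 3-vector, gaze direction in world coordinates.
#' @param gravity unit 3-vector, default `c(0, 0, -1)`.
#' @return an object of class `eye_frame`: list with unit vectors `X`, `Y`, `Z`.
#'   Errors with condition class `retflow_degenerate_gaze` when gaze is within
#'   0.06 deg of +-gravity (the cross product vanishes); callers tracking a
#'   gaze stream should then reuse the previous frame's `X` (see
#'   [eye_frames()], which implements that fallback).
#' @export
#' @examples
#' f <- build_eye_frame(c(1, 0, 0))
#' f$Y  # straight up for horizontal gaze
build_eye_frame <- function(gaze, gravity = c(0, 0, -1)) {
  stopifnot(length(gaze) == 3, length(gravity) == 3)
  gaze <- gaze / sqrt(sum(gaze^2))
  up <- -gravity / sqrt(sum(gravity^2))
  cr <- c(gaze[2] * up[3] - gaze[3] * up[2],
          gaze[3] * up[1] - gaze[1] * up[3],
          gaze[1] * up[2] - gaze[2] * up[1])
  n <- sqrt(sum(cr^2))
  if (n < sin(deg2rad(0.06))) {
    stop_retflow("gaze is within 0.06 deg of the gravity axis; eye basis undefined",
                 "retflow_degenerate_gaze")
  }
  X <- cr / n
  Y <- c(X[2] * gaze[3] - X[3] * gaze[2],
         X[3] * gaze[1] - X[1] * gaze[3],
         X[1] * gaze[2] - X[2] * gaze[1])
  structure(list(X = X, Y = Y, Z = gaze), class = "eye_frame")
}

#' @export
print.eye_frame <- function(x, ...) {
  cat("eye frame (rows X, Y, Z, world coordinates):\n")
  print(round(rbind(X = x$X, Y = x$Y, Z = x$Z), 6))
  invisible(x)
}

#' Eye bases for a whole gaze track
#'
#' Vectorized version of [build_eye_frame()] for the default gravity
#' `(0, 0, -1)`. Frames whose gaze is degenerate (within 0.06 deg of the
#' vertical) reuse the previous frame's `X` axis, the documented fallback for
#' streaming data; an error is raised if the first frame is degenerate.
#'
#' @param gaze N x 3 matrix of unit gaze directions.
#' @return list with N x 3 matrices `X`, `Y`, `Z`.
#' @export
eye_frames <- function(gaze) {
  gaze <- .rows3(gaze)
  h <- sqrt(gaze[, 1]^2 + gaze[, 2]^2)
  bad <- h < sin(deg2rad(0.06))
  # Z x up with up = (0,0,1) is (Zy, -Zx, 0)
  X <- cbind(gaze[, 2] / h, -gaze[, 1] / h, 0)
  if (any(bad)) {
    if (bad[1]) {
      stop_retflow("first frame gaze is degenerate (parallel to gravity)",
                   "retflow_degenerate_gaze")
    }
    idx <- which(bad)
    for (i in idx) X[i, ] <- X[i - 1L, ]
  }
  Y <- .cross3(X, gaze)
  list(X = X, Y = Y, Z = gaze)
}

# 3x3 matrix with rows X, Y, Z: v_world = v_eye %*% M, v_eye = v_world %*% t(M)
.frame_matrix <- function(frame, i = NULL) {
  if (is.null(i)) rbind(frame$X, frame$Y, frame$Z)
  else rbind(frame$X[i, ], frame$Y[i, ], frame$Z[i, ])
}

#' Map retinal grid coordinates to eye-frame directions
#'
#' `(x, y)` are degrees of the azimuthal-equidistant retinal chart; the
#' returned unit vector makes angle `phi = sqrt(x^2 + y^2)` with the gaze
#' (`Z`) axis, at polar angle `theta = atan2(y, x)` in the X-Y plane. The
#' grid center maps to `Z`.
#'
#' @param x,y numeric vectors of equal length, degrees. `phi` must not
#'   exceed 90.
#' @return m x 3 matrix of unit vectors in eye-frame coordinates.
#' @export
#' @examples
#' grid_to_direction(0, 0)   # the gaze axis (0, 0, 1)
#' grid_to_direction(0, 45)  # 45 deg above gaze in the Y-Z plane
grid_to_direction <- function(x, y) {
  stopifnot(length(x) == length(y))
  phi <- sqrt(x^2 + y^2)
  if (any(phi > 90 + 1e-12)) {
    stop_retflow("eccentricity above 90 deg is outside the forward hemisphere chart",
                 "retflow_bad_eccentricity")
  }
  theta <- atan2(y, x)
  sp <- sin(deg2rad(phi))
  cbind(sp * cos(theta), sp * sin(theta), cos(deg2rad(phi)))
}

#' Map eye-frame directions to retinal grid coordinates
#'
#' Inverse of [grid_to_direction()] for front-hemisphere directions.
#'
#' @param v unit 3-vector or m x 3 matrix, eye-frame coordinates.
#' @param strict if `TRUE` (default), directions behind the eye
#'   (`v . Z <= 0`) raise an error with class `retflow_behind_eye`; if
#'   `FALSE` they yield `NA` rows.
#' @return data.frame with columns `x`, `y`, `theta` (degrees, in
#'   `[0, 360)`), `phi` (degrees, >= 0).
#' @export
direction_to_grid <- function(v, strict = TRUE) {
  v <- .rows3(v)
  behind <- v[, 3] <= 0
  if (any(behind)) {
    if (strict) {
      stop_retflow("direction lies behind the eye (rear hemisphere)",
                   "retflow_behind_eye")
    }
  }
  hyp <- sqrt(v[, 1]^2 + v[, 2]^2)
  phi <- rad2deg(atan2(hyp, v[, 3]))
  s <- ifelse(hyp > 0, phi / hyp, 0)
  x <- v[, 1] * s
  y <- v[, 2] * s
  theta <- rad2deg(atan2(y, x)) %% 360
  theta[phi == 0] <- 0
  out <- data.frame(x = x, y = y, theta = theta, phi = phi)
  if (any(behind)) out[behind, ] <- NA_real_
  out
}

#' Linear-eccentricity retinal sampling grid
#'
#' An `n` x `n` lattice over the square `[-max_ecc, max_ecc]^2` of the retinal
#' chart. Cells whose eccentricity exceeds `max_ecc` (the square's corners)
#' are kept in the arrays but masked invalid and excluded from all statistics,
#' so the effective sampling region is the disc of eccentricity 0 to
#' `max_ecc`. The default 250 x 250 grid carries 62,500 speed/direction
#' samples per frame.
#'
#' Vectors indexing grid cells are in column-major order of an `n` x `n`
#' matrix whose `[i, j]` element is the cell at `x = xs[i]`, `y = xs[j]`
#' (so `matrix(value, n, n)` is directly usable with `graphics::image`).
#'
#' @param n grid side length (default 250).
#' @param max_ecc maximum eccentricity in degrees (default 45; must be below
#'   63 so that even the square's corners stay in the forward hemisphere).
#' @return object of class `retinal_grid`: list with `n`, `max_ecc`,
#'   `spacing` (deg between adjacent cells, `2 * max_ecc / (n - 1)`), `xs`
#'   (axis values), `gx`, `gy`, `theta`, `phi` (length n^2), `dirs` (n^2 x 3
#'   eye-frame unit vectors) and `valid` (logical, `phi <= max_ecc`).
#' @export
#' @examples
#' g <- retinal_grid(n = 65, max_ecc = 45)
#' sum(g$valid) / g$n^2  # ~ pi/4: the disc within the square
retinal_grid <- function(n = 250, max_ecc = 45) {
  stopifnot(n >= 2, max_ecc > 0, max_ecc * sqrt(2) < 90)
  xs <- seq(-max_ecc, max_ecc, length.out = n)
  gx <- rep(xs, times = n)
  gy <- rep(xs, each = n)
  phi <- sqrt(gx^2 + gy^2)
  theta <- rad2deg(atan2(gy, gx)) %% 360
  structure(list(
    n = as.integer(n), max_ecc = max_ecc,
    spacing = 2 * max_ecc / (n - 1),
    xs = xs, gx = gx, gy = gy, theta = theta, phi = phi,
    dirs = grid_to_direction(gx, gy),
    valid = phi <= max_ecc + 1e-12
  ), class = "retinal_grid")
}

#' @export
print.retinal_grid <- function(x, ...) {
  cat(sprintf("retinal grid: %d x %d (%d cells, %d within %g deg eccentricity), spacing %.4g deg\n",
              x$n, x$n, x$n^2, sum(x$valid), x$max_ecc, x$spacing))
  invisible(x)
}

# Rodrigues rotation of row vectors about a unit axis by an angle in degrees.
.rotate_about <- function(v, axis, angle_deg) {
  v <- .rows3(v)
  a <- deg2rad(angle_deg)
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(axis, nrow(v), 3, byrow = TRUE)
  v * cos(a) + .cross3(k, v) * sin(a) + k * (rowSums(k * v)) * (1 - cos(a))
}

# Spherical interpolation from unit vector u toward w by fraction s of the arc.
.slerp <- function(u, w, s) {
  ang <- angular_between(u, w)
  if (ang < 1e-12) return(w)
  axis <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
  na <- sqrt(sum(axis^2))
  if (na < 1e-15) return(if (s >= 1) w else u) # antipodal or identical
  drop(.rotate_about(u, axis / na, s * ang))
}

# Axis-angle of the rotation taking unit vector u to unit vector w
# (minimal great-circle rotation). Returns list(axis, angle_deg).
.rotation_between <- function(u, w) {
  axis <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
  na <- sqrt(sum(axis^2))
  ang <- angular_between(u, w)
  if (na < 1e-15) list(axis = c(1, 0, 0), angle_deg = 0)
  else list(axis = axis / na, angle_deg = ang)
}

# Axis-angle of a 3x3 rotation matrix (world frame). Returns list(axis, angle_deg).
.rotmat_axis_angle <- function(R) {
  tr <- sum(diag(R))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(v^2))
  ang <- atan2(s, tr - 1)
  if (s < 1e-15) return(list(axis = c(1, 0, 0), angle_deg = 0))
  list(axis = v / s, angle_deg = rad2deg(ang))
}
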