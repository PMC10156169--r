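# Parametric terrain heightfields and ray-cast depth rendering.
#
# Terrain is a 2.5D heightfield on a regular x-y lattice: walkable ground, for
# which first-hit ray marching is exact and fast. Roughness is band-limited
# Gaussian noise (white noise low-passed at the correlation length, rescaled
# to the class RMS amplitude), emulating the qualitative roughness ladder
# pavement < flat < medium < bark < rocks.

.terrain_classes <- c(pavement = 0, flat = 0.005, medium = 0.02,
                      bark = 0.03, rocks = 0.08)

#' Generate a parametric terrain heightfield
#'
#' @param terrain_class one of `"pavement"`, `"flat"`, `"medium"`, `"bark"`,
#'   `"rocks"`. Class sets the default RMS roughness amplitude (0, 0.005,
#'   0.02, 0.03, 0.08 m); these amplitudes are calibration knobs chosen to
#'   span a plausible roughness ladder, not measured values.
#' @param extent_m lattice length along the travel (`x`) axis, meters
#'   (>= 20).
#' @param width_m lattice width along `y`, meters.
#' @param x0 `x` coordinate of the lattice origin (default -2, so the walker
#'   starting at the world origin has ground behind it).
#' @param cell_size lattice spacing, m; must be at most `correlation_length/3`.
#' @param correlation_length roughness correlation length, m (Gaussian
#'   low-pass standard deviation).
#' @param roughness_amplitude override the class RMS amplitude, m.
#' @param seed integer; the field is reproducible for a fixed seed.
#' @return object of class `terrain`: list with `heights` (nx x ny matrix, m),
#'   `x0`, `y0`, `cell_size`, `terrain_class`, `roughness_amplitude`,
#'   `correlation_length`, `seed`.
#' @export
#' @examples
#' tr <- make_terrain("rocks", extent_m = 20, width_m = 6, seed = 1)
#' sd(as.vector(tr$heights)) # ~ 0.08
make_terrain <- function(terrain_class, extent_m = 60, width_m = 20,
                         x0 = -2, cell_size = 0.1, correlation_length = 0.3,
                         roughness_amplitude = NULL, seed = 1) {
  terrain_class <- match.arg(terrain_class, names(.terrain_classes))
  if (extent_m < 20) {
    stop_retflow("terrain extent along the travel axis must be at least 20 m",
                 "retflow_bad_terrain")
  }
  if (cell_size > correlation_length / 3 + 1e-12) {
    stop_retflow("cell_size must be at most correlation_length / 3",
                 "retflow_bad_terrain")
  }
  amp <- if (is.null(roughness_amplitude)) {
    unname(.terrain_classes[terrain_class])
  } else roughness_amplitude
  nx <- floor(extent_m / cell_size) + 1L
  ny <- floor(width_m / cell_size) + 1L
  y0 <- -width_m / 2
  if (amp == 0) {
    heights <- matrix(0, nx, ny)
  } else {
    heights <- with_seed(seed, {
      noise <- matrix(rnorm(nx * ny), nx, ny)
      # Gaussian low-pass (periodic, via FFT): band-limits the spectrum at
      # spatial scale = correlation_length.
      fx <- c(0:floor(nx / 2), -((nx - floor(nx / 2) - 1):1)) / (nx * cell_size)
      fy <- c(0:floor(ny / 2), -((ny - floor(ny / 2) - 1):1)) / (ny * cell_size)
      H <- exp(-2 * pi^2 * correlation_length^2 *
                 outer(fx^2, fy^2, `+`))
      sm <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / (nx * ny)
      sm <- sm - mean(sm)
      sm * (amp / sqrt(mean(sm^2)))
    })
  }
  structure(list(heights = heights, x0 = x0, y0 = y0, cell_size = cell_size,
                 terrain_class = terrain_class, roughness_amplitude = amp,
                 correlation_length = correlation_length, seed = seed),
            class = "terrain")
}

#' @export
print.terrain <- function(x, ...) {
  cat(sprintf("terrain '%s': %d x %d lattice, cell %.3g m, RMS amplitude %.3g m (seed %s)\n",
              x$terrain_class, nrow(x$heights), ncol(x$heights),
              x$cell_size, x$roughness_amplitude, x$seed))
  invisible(x)
}

#' Terrain surface elevation at arbitrary points
#'
#' Bilinear interpolation of the heightfield; `NA` outside the lattice.
#'
#' @param terrain a [make_terrain()] object.
#' @param x,y numeric vectors, world coordinates (m).
#' @return elevations, m.
#' @export
terrain_height <- function(terrain, x, y) {
  h <- terrain$heights
  fx <- (x - terrain$x0) / terrain$cell_size
  fy <- (y - terrain$y0) / terrain$cell_size
  nx <- nrow(h); ny <- ncol(h)
  out <- rep(NA_real_, length(x))
  ok <- fx >= 0 & fy >= 0 & fx <= nx - 1 & fy <= ny - 1
  i <- pmin(floor(fx[ok]), nx - 2) + 1L
  j <- pmin(floor(fy[ok]), ny - 2) + 1L
  tx <- fx[ok] - (i - 1L); ty <- fy[ok] - (j - 1L)
  out[ok] <- h[cbind(i, j)] * (1 - tx) * (1 - ty) +
    h[cbind(i + 1L, j)] * tx * (1 - ty) +
    h[cbind(i, j + 1L)] * (1 - tx) * ty +
    h[cbind(i + 1L, j + 1L)] * tx * ty
  out
}

#' Ray-cast a depth map from an eye pose
#'
#' Casts one ray per retinal grid cell (along the grid direction expressed in
#' world coordinates through the eye basis) and returns the distance to the
#' first terrain intersection. Marching step is `cell_size / 2` with bisection
#' refinement to 1e-9 m, so on a flat plane the result matches the analytic
#' ray-plane intersection to well below 1e-6 m. Rays that never meet the
#' terrain (above the horizon, or leaving the lattice) are flagged as misses.
#'
#' @param terrain a [make_terrain()] object.
#' @param eye_position world 3-vector; must be strictly above the surface
#'   (else an error of class `retflow_eye_underground`).
#' @param eye_frame an [build_eye_frame()] basis.
#' @param grid a [retinal_grid()].
#' @param tmax maximum ray length, m.
#' @return object of class `depth_map`: list with `depth` (length n^2; m;
#'   `Inf` where missed, `NA` where the grid cell is invalid), `miss`
#'   (logical) and `n`.
#' @export
cast_depth <- function(terrain, eye_position, eye_frame, grid, tmax = 200) {
  hz <- terrain_height(terrain, eye_position[1], eye_position[2])
  if (!is.na(hz) && eye_position[3] <= hz) {
    stop_retflow("eye position is at or below the terrain surface",
                 "retflow_eye_underground")
  }
  M <- .frame_matrix(eye_frame)
  dirs <- grid$dirs %*% M
  dirs[!grid$valid, ] <- NA_real_
  depth <- raycast_heightfield(as.numeric(eye_position), dirs,
                               terrain$heights, terrain$x0, terrain$y0,
                               terrain$cell_size, terrain$cell_size / 2,
                               1e-9, tmax)
  structure(list(depth = depth, miss = is.infinite(depth), n = grid$n),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  hit <- is.finite(x$depth)
  cat(sprintf("depth map: %d x %d, %d hits (median %.3g m), %d misses\n",
              x$n, x$n, sum(hit),
              if (any(hit)) median(x$depth[hit]) else NA, sum(x$miss, na.rm = TRUE)))
  invisible(x)
}

#' Export a terrain as an ASCII PLY triangle mesh
#'
#' Triangulates the heightfield lattice (two triangles per cell) and writes a
#' plain-text PLY file.
#'
#' @param terrain a [make_terrain()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_terrain_ply <- function(terrain, path) {
  h <- terrain$heights
  nx <- nrow(h); ny <- ncol(h)
  xs <- terrain$x0 + (seq_len(nx) - 1) * terrain$cell_size
  ys <- terrain$y0 + (seq_len(ny) - 1) * terrain$cell_size
  verts <- cbind(rep(xs, times = ny), rep(ys, each = nx), as.vector(h))
  idx <- function(i, j) (j - 1L) * nx + (i - 1L) # 0-based vertex index
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  faces <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                 cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(verts[, 1], verts[, 2], verts[, 3]), con)
  writeLines(paste(3, faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}

#' Write / read a terrain as a CSV lattice
#'
#' Long-format CSV with columns `x`, `y`, `height`; the reader reconstructs
#' the regular lattice and the terrain object (class and seed metadata are
#' stored in a `# retflow-terrain` comment line).
#'
#' @param terrain a [make_terrain()] object.
#' @param path file path.
#' @return `write_terrain_csv`: `path`, invisibly. `read_terrain_csv`: a
#'   `terrain` object.
#' @export
write_terrain_csv <- function(terrain, path) {
  h <- terrain$heights
  nx <- nrow(h); ny <- ncol(h)
  df <- data.frame(
    x = terrain$x0 + (rep(seq_len(nx), times = ny) - 1) * terrain$cell_size,
    y = terrain$y0 + (rep(seq_len(ny), each = nx) - 1) * terrain$cell_size,
    height = as.vector(h))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# retflow-terrain class=%s amplitude=%.17g corr=%.17g seed=%d",
                     terrain$terrain_class, terrain$roughness_amplitude,
                     terrain$correlation_length, as.integer(terrain$seed)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_terrain_csv
#' @export
read_terrain_csv <- function(path) {
  meta <- readLines(path, n = 1)
  df <- read.csv(path, comment.char = "#")
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  cell <- xs[2] - xs[1]
  h <- matrix(NA_real_, length(xs), length(ys))
  h[cbind(match(df$x, xs), match(df$y, ys))] <- df$height
  cls <- sub(".*class=(\\S+).*", "\\1", meta)
  amp <- as.numeric(sub(".*amplitude=(\\S+).*", "\\1", meta))
  corr <- as.numeric(sub(".*corr=(\\S+).*", "\\1", meta))
  seed <- as.integer(sub(".*seed=(\\S+).*", "\\1", meta))
  structure(list(heights = h, x0 = xs[1], y0 = ys[1], cell_size = cell,
                 terrain_class = cls, roughness_amplitude = amp,
                 correlation_length = corr, seed = seed),
            class = "terrain")
}
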