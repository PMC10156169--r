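# Pooled statistics over sets of flow fields: speed maps, probe histograms,
# direction summaries, gaze-angle conditioning, terrain-matched comparison,
# retinal slip and saccade contribution, gaze-angle histograms.

.fields_of <- function(x) if (inherits(x, "flow_set")) x$fields else x

#' Log-spaced retinal speed histogram bins
#'
#' 60 log-spaced bins spanning 0.1-300 deg/s, the working range of
#' locomotor retinal speeds. Samples outside the range are clamped into the
#' edge bins so normalized histograms always sum to 1.
#'
#' @param n_bins number of bins.
#' @param lo,hi range, deg/s.
#' @return vector of bin edges (length `n_bins + 1`).
#' @export
speed_bins <- function(n_bins = 60, lo = 0.1, hi = 300) {
  exp(seq(log(lo), log(hi), length.out = n_bins + 1))
}

.hist_norm <- function(values, edges) {
  v <- pmin(pmax(values, edges[1]), edges[length(edges)])
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  data.frame(bin_left = head(edges, -1), bin_right = tail(edges, -1),
             density = if (sum(counts) > 0) counts / sum(counts) else counts)
}

#' Pool flow fields into a mean-speed map
#'
#' Cell-wise mean retinal speed over all valid samples. Two combination
#' modes: `"pooled"` treats every frame pair of every input as one sample;
#' `"averaged"` (for a list of flow sets, one per subject/run) averages the
#' per-subject maps cell-wise.
#'
#' @param x a `flow_set` (or list of `flow_field`s), or for
#'   `mode = "averaged"` a list of such sets.
#' @param grid the [retinal_grid()] the fields live on.
#' @param mode `"pooled"` or `"averaged"`.
#' @return object of class `speed_map`: list with `mean_speed` and `count`
#'   (length n^2; `NA`/0 where no valid samples), `n`, `grid`.
#' @export
pool_speed_map <- function(x, grid, mode = c("pooled", "averaged")) {
  mode <- match.arg(mode)
  if (mode == "averaged") {
    maps <- lapply(x, pool_speed_map, grid = grid, mode = "pooled")
    ms <- sapply(maps, `[[`, "mean_speed")
    cnt <- sapply(maps, `[[`, "count")
    mean_speed <- rowMeans(ms)   # NA where any subject lacks coverage
    return(structure(list(mean_speed = mean_speed, count = rowSums(cnt),
                          n = grid$n, grid = grid), class = "speed_map"))
  }
  fields <- .fields_of(x)
  if (length(fields) == 0) stop_retflow("no flow fields to pool", "retflow_empty_input")
  ncell <- grid$n^2
  s <- numeric(ncell); cnt <- numeric(ncell)
  for (f in fields) {
    ok <- f$valid & !is.na(f$speed)
    s[ok] <- s[ok] + f$speed[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  mean_speed <- ifelse(cnt > 0, s / cnt, NA_real_)
  structure(list(mean_speed = mean_speed, count = cnt, n = grid$n,
                 grid = grid), class = "speed_map")
}

#' @export
print.speed_map <- function(x, ...) {
  ok <- !is.na(x$mean_speed)
  cat(sprintf("speed map: %d x %d, %d covered cells, mean %.3g deg/s (max %.3g)\n",
              x$n, x$n, sum(ok), mean(x$mean_speed[ok]), max(x$mean_speed[ok])))
  invisible(x)
}

#' @export
plot.speed_map <- function(x, levels = pretty(range(x$mean_speed, na.rm = TRUE), 8),
                           main = "mean retinal speed (deg/s)", ...) {
  m <- matrix(x$mean_speed, x$n, x$n)
  graphics::image(x$grid$xs, x$grid$xs, m, asp = 1,
                  xlab = "x (deg)", ylab = "y (deg)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(x$grid$xs, x$grid$xs, m, levels = levels, add = TRUE,
                    col = "white", lwd = 0.5)
  invisible(x)
}

#' Mean-speed profile along the vertical meridian
#'
#' Helper for upper/lower visual-field comparisons: the mean-speed map
#' sampled along the grid column nearest `x = 0`, split by sign of `y`
#' (positive = upper field).
#'
#' @param map a [pool_speed_map()] result.
#' @return data.frame with `ecc` (signed, deg; negative = lower field),
#'   `speed` (deg/s) and `count`.
#' @export
meridian_profile <- function(map) {
  g <- map$grid
  i0 <- which.min(abs(g$xs))          # column nearest x = 0
  idx <- i0 + (seq_len(g$n) - 1L) * g$n
  data.frame(ecc = g$xs, speed = map$mean_speed[idx], count = map$count[idx])
}

#' Peak mean speeds of the lower and upper vertical meridian
#'
#' Maximum of the meridian mean-speed profile in each half-field, restricted
#' to cells sampled in at least `min_coverage` of the pooled frame pairs: a
#' cell that only receives samples under rare geometry (e.g. the upper far
#' periphery, which is only below the horizon on the nearest-gaze frames)
#' carries a conditional mean that is not comparable with the rest of the
#' map, so majority-covered cells define the profile.
#'
#' @param map a [pool_speed_map()] result.
#' @param n_fields number of frame pairs pooled into the map.
#' @param min_coverage minimum fraction of frames a cell must be valid in.
#' @return list with `lower`, `upper` (deg/s), `lower_ecc`, `upper_ecc`
#'   (deg) and `ratio` (lower/upper).
#' @export
meridian_peaks <- function(map, n_fields, min_coverage = 0.5) {
  mp <- meridian_profile(map)
  okl <- mp$ecc < 0 & mp$count >= min_coverage * n_fields & !is.na(mp$speed)
  oku <- mp$ecc > 0 & mp$count >= min_coverage * n_fields & !is.na(mp$speed)
  if (!any(okl) || !any(oku)) {
    stop_retflow("a half-meridian has no sufficiently covered cells",
                 "retflow_empty_input")
  }
  lower <- max(mp$speed[okl]); upper <- max(mp$speed[oku])
  list(lower = lower, upper = upper,
       lower_ecc = abs(mp$ecc[okl][which.max(mp$speed[okl])]),
       upper_ecc = mp$ecc[oku][which.max(mp$speed[oku])],
       ratio = lower / upper)
}

#' Probe locations in the visual field
#'
#' The fovea plus four cardinal points at `eccentricity` degrees, snapped to
#' the nearest grid cells.
#'
#' @param grid a [retinal_grid()].
#' @param eccentricity deg (default 20; must be within the grid).
#' @return object of class `probe_set`: data.frame with `name`, nominal
#'   `x`, `y` and the linear `cell` index.
#' @export
probe_set <- function(grid, eccentricity = 20) {
  if (eccentricity > grid$max_ecc) {
    stop_retflow("probe eccentricity outside the grid", "retflow_bad_probe")
  }
  px <- c(0, eccentricity, -eccentricity, 0, 0)
  py <- c(0, 0, 0, eccentricity, -eccentricity)
  cell <- mapply(function(x, y) {
    which.min((grid$gx - x)^2 + (grid$gy - y)^2)
  }, px, py)
  structure(data.frame(name = c("fovea", "right", "left", "upper", "lower"),
                       x = px, y = py, cell = cell),
            class = c("probe_set", "data.frame"))
}

#' Retinal speed distributions at probe locations
#'
#' Normalized speed histograms (log-spaced bins) of the flow samples at each
#' probe cell across all frame pairs.
#'
#' @param x a `flow_set` or list of `flow_field`s.
#' @param probes a [probe_set()].
#' @param edges histogram bin edges, deg/s (default [speed_bins()]).
#' @return named list (one per probe) of histogram data.frames
#'   (`bin_left`, `bin_right`, `density`; each sums to 1).
#' @export
probe_distributions <- function(x, probes, edges = speed_bins()) {
  fields <- .fields_of(x)
  out <- lapply(seq_len(nrow(probes)), function(p) {
    cell <- probes$cell[p]
    vals <- unlist(lapply(fields, function(f) {
      if (f$valid[cell] && !is.na(f$speed[cell])) f$speed[cell] else NULL
    }))
    .hist_norm(vals, edges)
  })
  setNames(out, probes$name)
}

#' Mean flow directions and their polar-angle histogram
#'
#' Per-cell circular mean of the flow direction across frame pairs, and a
#' normalized histogram of those mean directions over all covered cells
#' (36 bins of 10 deg, centered on 0, 10, ..., 350 so that 90 and 270 are
#' bin centers).
#'
#' @param x a `flow_set` or list of `flow_field`s.
#' @param grid the [retinal_grid()].
#' @return list with `mean_direction` (deg, length n^2), `resultant`
#'   (mean resultant length), `count`, and `direction_hist` (data.frame
#'   `center`, `density`).
#' @export
direction_summary <- function(x, grid) {
  fields <- .fields_of(x)
  ncell <- grid$n^2
  cs <- numeric(ncell); sn <- numeric(ncell); cnt <- numeric(ncell)
  for (f in fields) {
    ok <- f$valid & !is.na(f$direction)
    r <- deg2rad(f$direction[ok])
    cs[ok] <- cs[ok] + cos(r)
    sn[ok] <- sn[ok] + sin(r)
    cnt[ok] <- cnt[ok] + 1
  }
  mean_dir <- ifelse(cnt > 0, rad2deg(atan2(sn, cs)) %% 360, NA_real_)
  resultant <- ifelse(cnt > 0, sqrt(cs^2 + sn^2) / cnt, NA_real_)
  covered <- cnt > 0 & grid$valid
  centers <- seq(0, 350, by = 10)
  b <- floor(((mean_dir[covered] + 5) %% 360) / 10) + 1L
  dc <- tabulate(b, nbins = 36)
  list(mean_direction = mean_dir, resultant = resultant, count = cnt,
       direction_hist = data.frame(center = centers,
                                   density = dc / sum(dc)))
}

#' Mean circulation (curl sign) of a flow set
#'
#' Mean tangential component of the per-cell mean flow vector, weighted over
#' covered cells; positive = counterclockwise circulation around the fovea.
#' Lateral gaze relative to the travel direction flips its sign.
#'
#' @param x a `flow_set`.
#' @param grid the [retinal_grid()].
#' @return scalar, deg/s.
#' @export
mean_circulation <- function(x, grid) {
  fields <- .fields_of(x)
  ncell <- grid$n^2
  u <- numeric(ncell); v <- numeric(ncell); cnt <- numeric(ncell)
  for (f in fields) {
    ok <- f$valid & !is.na(f$direction)
    r <- deg2rad(f$direction[ok])
    u[ok] <- u[ok] + f$speed[ok] * cos(r)
    v[ok] <- v[ok] + f$speed[ok] * sin(r)
    cnt[ok] <- cnt[ok] + 1
  }
  ok <- cnt > 0 & grid$valid & grid$phi > 1e-9
  tx <- -grid$gy[ok] / grid$phi[ok]   # CCW tangent of the chart
  ty <- grid$gx[ok] / grid$phi[ok]
  mean((u[ok] / cnt[ok]) * tx + (v[ok] / cnt[ok]) * ty)
}

#' Default gaze-angle conditioning bins
#'
#' Vertical bins 60-90 deg (far gaze) and 17-45 deg (near gaze); horizontal
#' bins -180..-28 deg (leftward) and +28..+180 deg (rightward).
#'
#' @return list with `vertical` and `horizontal` lists of `c(lo, hi)` bins.
#' @export
gaze_bins <- function() {
  list(vertical = list(far = c(60, 90), near = c(17, 45)),
       horizontal = list(left = c(-180, -28), right = c(28, 180)))
}

#' Condition flow statistics on gaze angle
#'
#' Assigns frame pairs to gaze-angle bins by the onset gaze angle of the
#' fixation they belong to, and computes a pooled speed map and direction
#' summary per bin. Empty bins are dropped with a warning.
#'
#' @param x a `flow_set` (its `meta` carries the onset angles).
#' @param grid the [retinal_grid()].
#' @param axis `"vertical"` (uses `alpha_v`) or `"horizontal"` (`alpha_h`).
#' @param bins list of `c(lo, hi)` bins (default the standard
#'   [gaze_bins()]).
#' @return named list per bin: `speed_map`, `direction`, `n_pairs`.
#' @export
condition_on_gaze <- function(x, grid, axis = c("vertical", "horizontal"),
                              bins = NULL) {
  axis <- match.arg(axis)
  if (is.null(bins)) bins <- gaze_bins()[[axis]]
  ang <- if (axis == "vertical") x$meta$alpha_v else x$meta$alpha_h
  out <- list()
  for (nm in names(bins)) {
    b <- bins[[nm]]
    sel <- which(!is.na(ang) & ang >= b[1] & ang <= b[2])
    if (length(sel) == 0) {
      warning(sprintf("gaze bin '%s' [%g, %g] is empty; omitted", nm, b[1], b[2]),
              call. = FALSE)
      next
    }
    sub <- x[sel]
    out[[nm]] <- list(speed_map = pool_speed_map(sub, grid),
                      direction = direction_summary(sub, grid),
                      n_pairs = length(sel), bin = b)
  }
  out
}

#' Terrain comparison on gaze-matched subsamples
#'
#' Matches the two data sets on vertical gaze angle (1-deg bins; each bin
#' subsampled without replacement to the smaller count) so that the remaining
#' difference between terrains reflects 3D structure, not gaze behavior.
#'
#' @param x_a,x_b `flow_set`s for the two terrains.
#' @param grid the [retinal_grid()].
#' @param probes optional [probe_set()] for probe histograms.
#' @param seed integer; the subsample is reproducible and invariant to input
#'   frame order.
#' @return list with per-terrain `speed_map`, `probe_hists`, `direction`,
#'   `alpha_hist` (the matched 1-deg histograms, identical by construction)
#'   and `n_pairs`.
#' @export
terrain_matched_comparison <- function(x_a, x_b, grid, probes = NULL,
                                       seed = 1) {
  bin_a <- floor(x_a$meta$alpha_v)
  bin_b <- floor(x_b$meta$alpha_v)
  common <- intersect(unique(bin_a), unique(bin_b))
  if (length(common) == 0) {
    stop_retflow("no overlapping vertical gaze angle support", "retflow_no_overlap")
  }
  pick <- function(bin_vec, other_counts, ord) {
    sel <- integer(0)
    for (b in common) {
      idx <- which(bin_vec == b)
      k <- min(length(idx), other_counts[as.character(b)])
      # order-invariant: rank candidate frames deterministically before sampling
      idx <- idx[order(ord[idx])]
      sel <- c(sel, idx[sample.int(length(idx), k)])
    }
    sort(sel)
  }
  cnt_a <- table(bin_a); cnt_b <- table(bin_b)
  res <- with_seed(seed, {
    sa <- pick(bin_a, cnt_b, x_a$meta$frame)
    sb <- pick(bin_b, cnt_a, x_b$meta$frame)
    list(sa = sa, sb = sb)
  })
  make_side <- function(x, sel) {
    sub <- x[sel]
    list(speed_map = pool_speed_map(sub, grid),
         probe_hists = if (!is.null(probes)) probe_distributions(sub, probes),
         direction = direction_summary(sub, grid),
         alpha_hist = table(factor(floor(sub$meta$alpha_v), levels = common)),
         n_pairs = length(sel))
  }
  list(a = make_side(x_a, res$sa), b = make_side(x_b, res$sb))
}

#' Retinal slip during fixations
#'
#' For every fixation of at least two frames, the world gaze point at the
#' fixation onset is ray-cast onto the terrain and tracked: the deviation at
#' each later frame is the angle between the current gaze direction and the
#' direction from the current eye position to that onset point (the first
#' frame, which defines the location, is excluded). Per-fixation medians are
#' pooled into a normalized histogram with 0.05-deg bins; the mode is the
#' center of the fullest bin.
#'
#' @param track an `eye_pose_track`.
#' @param segments a [segment_fixations()] data.frame (or the track's own
#'   labels via [segments_from_labels()]).
#' @param terrain a [make_terrain()] object.
#' @param bin_width histogram bin width, deg.
#' @return list with `per_fixation` (data.frame: `start` = onset frame of the
#'   segment, `median_dev`, `terminal_dev`, `duration_s`, `n_frames`;
#'   fixations whose onset ray misses the terrain are dropped), `hist`,
#'   `mode`, `median`.
#' @export
slip_analysis <- function(track, segments, terrain, bin_width = 0.05) {
  fix <- segments[segments$kind == "fixation" & segments$n_frames >= 2, ,
                  drop = FALSE]
  med <- term <- dur <- nfr <- st <- numeric(0)
  for (k in seq_len(nrow(fix))) {
    i0 <- fix$start[k]
    last <- min(fix$end[k] - 1L, nrow(track$gaze))
    hit <- raycast_heightfield(as.numeric(track$position[i0, ]),
                               matrix(track$gaze[i0, ], 1, 3),
                               terrain$heights, terrain$x0, terrain$y0,
                               terrain$cell_size, terrain$cell_size / 2,
                               1e-9, 200)
    if (!is.finite(hit)) next
    P0 <- track$position[i0, ] + hit * track$gaze[i0, ]
    js <- (i0 + 1L):last
    to_p0 <- .normalize_rows(matrix(P0, length(js), 3, byrow = TRUE) -
                               track$position[js, , drop = FALSE])
    dev <- angular_between(track$gaze[js, , drop = FALSE], to_p0)
    med <- c(med, median(dev))
    term <- c(term, dev[length(dev)])
    dur <- c(dur, (last - i0 + 1L) / .retflow_sample_rate)
    nfr <- c(nfr, last - i0 + 1L)
    st <- c(st, i0)
  }
  if (length(med) == 0) stop_retflow("no usable fixations", "retflow_empty_input")
  edges <- seq(0, max(max(med), bin_width) + bin_width, by = bin_width)
  h <- .hist_norm(med, edges)
  mode_center <- (h$bin_left[which.max(h$density)] +
                    h$bin_right[which.max(h$density)]) / 2
  list(per_fixation = data.frame(start = st, median_dev = med,
                                 terminal_dev = term, duration_s = dur,
                                 n_frames = nfr),
       hist = h, mode = mode_center, median = median(med))
}

#' Segments from simulator ground-truth labels
#'
#' Converts the per-frame labels carried by a simulated track into the same
#' segment table [segment_fixations()] produces, for detector validation and
#' for analyses that want the idealized segmentation.
#'
#' @param track an `eye_pose_track`.
#' @return data.frame with `start`, `end` (half-open), `kind`, `n_frames`.
#' @export
segments_from_labels <- function(track) {
  key <- paste(track$label_kind, track$label_id)
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end + 1L,
             kind = track$label_kind[start], n_frames = r$lengths)
}

#' Saccade contribution to retinal speed distributions
#'
#' Probe speed histograms for fixation frames only, saccade frames only, and
#' the two combined (pooling all samples weights the conditions by their
#' frame counts). Also summarizes the saccades themselves: the distribution
#' of eye angular speeds on saccade frames and a 2D histogram of per-saccade
#' horizontal/vertical amplitude components in the retinal chart.
#'
#' @param x a `flow_set` computed with `kinds = c("fixation", "saccade")`.
#' @param probes a [probe_set()].
#' @param kin optional [eye_in_orbit_kinematics()] for the saccade speed
#'   distribution.
#' @param track optional `eye_pose_track` for the saccade component
#'   histogram.
#' @param edges speed histogram edges.
#' @return list with `fixation`, `saccade`, `combined` probe histogram sets,
#'   and (when inputs are given) `saccade_speed_hist` and
#'   `saccade_components` (data.frame `dx`, `dy`, deg).
#' @export
saccade_contribution <- function(x, probes, kin = NULL, track = NULL,
                                 edges = speed_bins()) {
  is_sac <- x$meta$kind == "saccade"
  if (!any(is_sac)) stop_retflow("no saccade frames in the flow set",
                                 "retflow_empty_input")
  out <- list(fixation = probe_distributions(x[!is_sac], probes, edges),
              saccade = probe_distributions(x[is_sac], probes, edges),
              combined = probe_distributions(x, probes, edges))
  if (!is.null(kin) && !is.null(track)) {
    segs <- segments_from_labels(track)
    sac <- segs[segs$kind == "saccade", , drop = FALSE]
    idx <- unlist(mapply(function(s, e) s:(e - 1L), sac$start, sac$end,
                         SIMPLIFY = FALSE))
    idx <- idx[idx < kin$n]
    out$saccade_speed_hist <- .hist_norm(kin$speed[idx],
                                         seq(0, 800, by = 10))
    comp <- t(vapply(seq_len(nrow(sac)), function(k) {
      i0 <- sac$start[k]; i1 <- min(sac$end[k], nrow(track$gaze))
      f <- build_eye_frame(track$gaze[i0, ])
      v2 <- track$gaze[i1, ]
      g <- direction_to_grid(c(sum(v2 * f$X), sum(v2 * f$Y), sum(v2 * f$Z)),
                             strict = FALSE)
      c(g$x, g$y)
    }, numeric(2)))
    out$saccade_components <- data.frame(dx = comp[, 1], dy = comp[, 2])
  }
  out
}

#' Vertical gaze-angle histograms by terrain class
#'
#' Normalized histograms (3-deg bins over 0-180 deg) of the vertical gaze
#' angle on fixation frames, one per run, then mean +- SEM across runs within
#' each terrain class.
#'
#' @param tracks_by_class named list (terrain class -> list of
#'   `eye_pose_track`s).
#' @return named list per class: data.frame with `center`, `mean`, `sem`,
#'   plus attribute `n_runs`.
#' @export
gaze_angle_histograms <- function(tracks_by_class) {
  edges <- seq(0, 180, by = 3)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  lapply(tracks_by_class, function(runs) {
    dens <- sapply(runs, function(tr) {
      fixes <- tr$label_kind == "fixation"
      av <- angular_between(tr$gaze[fixes, , drop = FALSE],
                            matrix(c(0, 0, -1), sum(fixes), 3, byrow = TRUE))
      .hist_norm(av, edges)$density
    })
    dens <- matrix(dens, nrow = length(centers))
    m <- rowMeans(dens)
    sem <- if (ncol(dens) > 1) apply(dens, 1, sd) / sqrt(ncol(dens)) else
      rep(0, length(centers))
    structure(data.frame(center = centers, mean = m, sem = sem),
              n_runs = ncol(dens))
  })
}
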