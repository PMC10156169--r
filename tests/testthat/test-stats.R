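test_that("speed maps pool and average as documented", {
  g <- fx_grid49()
  fA <- constant_field(g, 10, 270)
  fB <- constant_field(g, 20, 270)

  m1 <- pool_speed_map(list(fA), g)
  expect_equal(m1$mean_speed[g$valid], rep(10, sum(g$valid)))
  expect_error(pool_speed_map(list(), g), class = "retflow_empty_input")

  # averaged mode: (A + B) / 2 cellwise
  mavg <- pool_speed_map(list(list(fA), list(fB)), g, mode = "averaged")
  expect_equal(mavg$mean_speed[g$valid], rep(15, sum(g$valid)))

  # pooled mode weights by sample counts
  mpool <- pool_speed_map(list(fA, fB, fB), g)
  expect_equal(mpool$mean_speed[g$valid], rep(50 / 3, sum(g$valid)))
})

test_that("probe histograms are normalized and concentrate where they should", {
  g <- fx_grid49()
  pr <- probe_set(g, 20)
  expect_identical(pr$name, c("fovea", "right", "left", "upper", "lower"))
  expect_error(probe_set(g, 50), class = "retflow_bad_probe")

  # delta field: every probe histogram occupies a single bin
  fd <- constant_field(g, 10, 270)
  ph <- probe_distributions(list(fd, fd), pr)
  for (h in ph) {
    expect_equal(sum(h$density), 1, tolerance = 1e-12)
    expect_equal(sum(h$density > 0), 1)
    occupied <- which(h$density > 0)
    expect_true(h$bin_left[occupied] <= 10 && h$bin_right[occupied] >= 10)
  }

  # stabilized walk: foveal mass below 1 deg/s
  fl <- fx_flow45()
  ph <- probe_distributions(fl, probe_set(fx_grid49(), 20))
  fov <- ph$fovea
  expect_gt(sum(fov$density[fov$bin_right <= 1]), 0.99)
  expect_equal(sum(fov$density), 1, tolerance = 1e-12)
})

test_that("direction summaries expose the expansion pattern of ground-plane flow", {
  g <- fx_grid49()
  # pure expansion: mean direction at each cell is its radial direction,
  # and the polar histogram is near-uniform
  exp_field <- constant_field(g, 5, 0)
  exp_field$direction <- ifelse(g$valid, g$theta, NA)
  ds <- direction_summary(list(exp_field), g)
  cov <- g$valid & g$phi > 1e-9
  expect_lt(max(circ_diff(ds$mean_direction[cov], g$theta[cov])), 1e-9)
  expect_equal(sum(ds$direction_hist$density), 1, tolerance = 1e-12)
  expect_lt(max(ds$direction_hist$density), 3 / 36)

  # simulated forward walk: histogram peaks at the vertical bins
  fl <- fx_flow45()
  dh <- direction_summary(fl, g)$direction_hist
  expect_equal(sum(dh$density), 1, tolerance = 1e-12)
  top <- dh$center[order(-dh$density)][1:4]
  expect_true(any(circ_diff(top, 90) <= 10))
  expect_true(any(circ_diff(top, 270) <= 10))
})

test_that("lateral gaze flips the circulation of the mean field", {
  pav <- fx_pavement()
  g <- fx_grid49()
  h <- simulate_head_trajectory(gait_params(lateral_yaw_amplitude = 0), 6)
  circ <- vapply(c(-25, 25), function(m) {
    tk <- simulate_gaze_sequence(
      h, gaze_params(lookahead_mean = 60, lookahead_sd = 3,
                     off_path_mean = m, off_path_sd = 2, seed = 13), pav)
    mean_circulation(flow_for_track(tk, pav, g, stride = 8), g)
  }, numeric(1))
  expect_lt(circ[1] * circ[2], 0)
  expect_gt(circ[1], 0)   # leftward gaze: counterclockwise rotation
})

test_that("gaze-angle conditioning assigns frames by fixation-onset angle", {
  fl <- fx_flow45()           # all onsets near 45 deg
  g <- fx_grid49()
  expect_warning(byv <- condition_on_gaze(fl, g, "vertical"),
                 "empty")
  expect_null(byv$far)
  expect_equal(byv$near$n_pairs,
               sum(fl$meta$alpha_v >= 17 & fl$meta$alpha_v <= 45))

  # custom bins around the actual onsets split the data
  byv2 <- condition_on_gaze(fl, g, "vertical",
                            bins = list(lo = c(0, 45), hi = c(45, 90)))
  expect_equal(byv2$lo$n_pairs + byv2$hi$n_pairs, length(fl$fields))
})

test_that("vertical-field asymmetry grows toward far gaze and reverses near the feet", {
  pav <- fx_pavement()
  g <- fx_grid49()
  h <- simulate_head_trajectory(gait_params(), 6)
  ring_ratio <- function(av) {
    tk <- simulate_gaze_sequence(
      h, gaze_params(lookahead_mean = av, lookahead_sd = 1, off_path_sd = 1,
                     seed = 17), pav)
    fl <- flow_for_track(tk, pav, g, stride = 6)
    m <- pool_speed_map(fl, g)
    nf <- length(fl$fields)
    lo <- g$phi >= 25 & g$phi <= 35 & g$gy < 0 & m$count >= 0.5 * nf
    up <- g$phi >= 25 & g$phi <= 35 & g$gy > 0 & m$count >= 0.5 * nf
    mean(m$mean_speed[lo]) / mean(m$mean_speed[up])
  }
  r30 <- ring_ratio(30); r60 <- ring_ratio(60); r75 <- ring_ratio(75)
  # ground-plane geometry: lower-vs-upper contrast scales with -cos(2 alpha_v)
  expect_lt(r30, 1)       # near gaze: the upper field is faster
  expect_gt(r60, 1.2)     # far gaze: the lower field dominates
  expect_gt(r75, r60)
})

test_that("the lower-meridian speed profile is monotone at 45-deg gaze", {
  fl <- fx_flow45()
  g <- fx_grid49()
  m <- pool_speed_map(fl, g)
  mp <- meridian_profile(m)
  low <- mp[mp$ecc <= 0 & mp$ecc >= -40 & mp$count > 0.5 * length(fl$fields), ]
  low <- low[order(-low$ecc), ]   # fovea outward
  expect_gt(nrow(low), 20)
  expect_true(all(diff(low$speed) > -0.35)) # non-decreasing up to sampling noise
  pk <- meridian_peaks(m, length(fl$fields))
  expect_gt(pk$lower, pk$upper * 0.8)
  expect_true(pk$lower_ecc > 30)
})

test_that("terrain comparison matches gaze histograms and ignores frame order", {
  g <- fx_grid49()
  fl <- fx_flow45()
  cmp <- terrain_matched_comparison(fl, fl, g, seed = 5)
  expect_identical(as.vector(cmp$a$alpha_hist), as.vector(cmp$b$alpha_hist))
  expect_equal(cmp$a$speed_map$mean_speed, cmp$b$speed_map$mean_speed)

  # shuffling the input frame order leaves the subsample invariant
  set.seed(99)
  perm <- sample(length(fl$fields))
  fl_shuf <- fl[perm]
  cmp2 <- terrain_matched_comparison(fl_shuf, fl, g, seed = 5)
  expect_equal(cmp2$a$speed_map$mean_speed, cmp$a$speed_map$mean_speed)
  expect_equal(cmp2$a$speed_map$count, cmp$a$speed_map$count)

  bad <- fl
  bad$meta$alpha_v <- bad$meta$alpha_v + 500
  expect_error(terrain_matched_comparison(fl, bad, g),
               class = "retflow_no_overlap")
})

test_that("slip analysis: histogram mode/median arithmetic and the g = 1 limit", {
  # mode is the fullest 0.05-deg bin's center, median the sample median
  h <- retflow:::.hist_norm(c(0.2, 0.2, 0.9), seq(0, 0.95, by = 0.05))
  ctr <- (h$bin_left + h$bin_right) / 2
  expect_equal(ctr[which.max(h$density)], 0.225)
  expect_equal(median(c(0.2, 0.2, 0.9)), 0.2)

  tk <- fx_walk45()
  sl <- slip_analysis(tk, segments_from_labels(tk), fx_pavement())
  expect_lt(sl$median, 0.01)
  expect_lt(sl$mode, 0.03)
  expect_true(all(sl$per_fixation$median_dev < 1e-6))
  expect_equal(sum(sl$hist$density), 1, tolerance = 1e-12)
})

test_that("saccades contribute a separate high-speed lobe", {
  pav <- fx_pavement()
  g <- retinal_grid(33, 45)
  h <- simulate_head_trajectory(gait_params(), 6)
  tk <- simulate_gaze_sequence(h, gaze_params(lookahead_mean = 45,
                                              lookahead_sd = 6, seed = 23), pav)
  fl <- flow_for_track(tk, pav, g, kinds = c("fixation", "saccade"),
                       stride = 3)
  pr <- probe_set(g, 20)
  sc <- saccade_contribution(fl, pr, kin = eye_in_orbit_kinematics(tk),
                             track = tk)
  med_of <- function(h) {
    cdf <- cumsum(h$density)
    h$bin_left[which(cdf >= 0.5)[1]]
  }
  expect_gt(med_of(sc$saccade$fovea), 50 * med_of(sc$fixation$fovea))
  for (nm in names(sc$fixation)) {
    expect_equal(sum(sc$combined[[nm]]$density), 1, tolerance = 1e-12)
  }
  # combined = frame-count-weighted union of the two conditions
  n_f <- sum(fl$meta$kind == "fixation")
  n_s <- sum(fl$meta$kind == "saccade")
  recomb <- (n_f * sc$fixation$lower$density + n_s * sc$saccade$lower$density) /
    (n_f + n_s)
  expect_equal(sc$combined$lower$density, recomb, tolerance = 1e-9)

  expect_error(saccade_contribution(fl[fl$meta$kind == "fixation"], pr),
               class = "retflow_empty_input")

  # small locomotor saccades keep modal speeds below 150 deg/s
  tks <- simulate_gaze_sequence(
    h, gaze_params(lookahead_mean = 80, lookahead_sd = 2, off_path_sd = 2,
                   seed = 29), pav)
  kin <- eye_in_orbit_kinematics(tks)
  scs <- saccade_contribution(
    flow_for_track(tks, pav, g, kinds = c("fixation", "saccade"), stride = 10),
    pr, kin = kin, track = tks)
  sh <- scs$saccade_speed_hist
  modal <- sh$bin_left[which.max(sh$density)]
  expect_lt(modal, 150)
})

test_that("gaze-angle histograms reflect the terrain look-ahead profiles", {
  pav <- fx_pavement()
  rocks <- fx_rocks()
  h <- simulate_head_trajectory(gait_params(), 6)
  mk <- function(terrain, class, seeds) {
    lapply(seeds, function(s) {
      simulate_gaze_sequence(h, gaze_params_for_terrain(class, seed = s), terrain)
    })
  }
  gh <- gaze_angle_histograms(list(rocks = mk(rocks, "rocks", 1:2),
                                   pavement = mk(pav, "pavement", 1)))
  for (cl in names(gh)) {
    expect_equal(sum(gh[[cl]]$mean), 1, tolerance = 1e-12)
  }
  med_of_hist <- function(h) h$center[which(cumsum(h$mean) >= 0.5)[1]]
  expect_gt(med_of_hist(gh$rocks), 40)
  expect_lt(med_of_hist(gh$rocks), 50)
  expect_gt(med_of_hist(gh$pavement), 70)
  expect_true(all(gh$pavement$sem == 0))    # single run: no spread
  expect_true(any(gh$rocks$sem > 0))
})
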