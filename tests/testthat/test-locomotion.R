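test_that("head trajectory honors the gait parameters", {
  # zero amplitudes: straight line at constant speed and height
  g0 <- gait_params(vertical_amplitude = 0, lateral_amplitude = 0,
                    lateral_yaw_amplitude = 0)
  h0 <- simulate_head_trajectory(g0, 5)
  expect_true(all(h0$position[, 2] == 0))
  expect_true(all(h0$position[, 3] == 1.6))
  expect_equal(diff(range(diff(h0$position[, 1]))), 0, tolerance = 1e-12)

  gd <- gait_params()
  # 10 s = 18 full gait cycles: exact means
  h <- simulate_head_trajectory(gd, 10)
  dur <- h$t[length(h$t)] - h$t[1]
  expect_equal((h$position[nrow(h$position), 1] - h$position[1, 1]) / dur,
               gd$walking_speed, tolerance = 1e-9)
  expect_equal(diff(range(h$position[, 3])), 2 * gd$vertical_amplitude,
               tolerance = 1e-6)
  expect_equal(mean(h$position[1:1200, 3]), gd$eye_height, tolerance = 1e-3)

  # lateral sway repeats at the step period
  lat <- h$position[, 2]
  ac <- acf(lat, lag.max = 100, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac), round(120 / gd$step_frequency), tolerance = 1)

  expect_error(simulate_head_trajectory(gd, 0.5), class = "retflow_bad_duration")
})

test_that("fixation targets land on the terrain at the sampled gaze angle", {
  pav <- fx_pavement()
  # deterministic geometry: alpha_v = 45, no lateral offset, eye at 1.6 m
  gp <- gaze_params(lookahead_mean = 45, lookahead_sd = 0, off_path_sd = 0)
  set.seed(1)
  sel <- select_fixation_target(c(2, 0, 1.6), 0, gp, pav)
  expect_equal(sel$target, c(2 + 1.6, 0, 0), tolerance = 1e-6)

  # generator self-consistency: onset angles track the class distribution
  rocks <- fx_rocks()
  gpr <- gaze_params(lookahead_mean = 45, lookahead_sd = 8)
  set.seed(2)
  draws <- replicate(500, select_fixation_target(c(5, 0, 1.6), 0, gpr,
                                                 rocks)$alpha_v)
  expect_gt(mean(draws), 43)
  expect_lt(mean(draws), 47)

  # near-horizon look on a short plane has to fail eventually
  tiny <- make_terrain("pavement", extent_m = 20, width_m = 4)
  gph <- gaze_params(lookahead_mean = 90, lookahead_sd = 1e-6)
  set.seed(3)
  expect_error(select_fixation_target(c(0, 0, 1.6), 0, gph, tiny,
                                      max_tries = 20),
               class = "retflow_target_failure")
})

test_that("gaze sequence alternates saccades and fixations and holds targets at g = 1", {
  tk <- fx_walk45()
  expect_true(all(tk$label_kind %in% c("fixation", "saccade")))
  expect_equal(max(abs(rowSums(tk$gaze^2) - 1)), 0, tolerance = 1e-9)

  # with g = 1, gaze points at the fixation target on every fixation frame
  fix <- which(tk$label_kind == "fixation")
  tg <- as.matrix(tk$targets[tk$label_id[fix], 1:3])
  to_t <- tg - tk$position[fix, ]
  to_t <- to_t / sqrt(rowSums(to_t^2))
  expect_lt(max(angular_between(tk$gaze[fix, ], to_t)), 1e-6)

  # fixation durations within the configured range (interior fixations)
  segs <- segments_from_labels(tk)
  fdur <- segs$n_frames[segs$kind == "fixation"]
  fdur <- fdur[-c(1, length(fdur))]
  expect_true(all(fdur <= 0.3 * 120 + 1))
  # some end early when the walker overtakes the target; most reach full length
  expect_gt(mean(fdur >= 0.2 * 120 - 1), 0.5)
})

test_that("saccade rate matches the duration budget across seeds", {
  pav <- fx_pavement()
  h <- simulate_head_trajectory(gait_params(), 10)
  for (s in 1:5) {
    tk <- simulate_gaze_sequence(h, gaze_params(lookahead_mean = 50,
                                                lookahead_sd = 5, seed = s), pav)
    segs <- segments_from_labels(tk)
    n_sac <- sum(segs$kind == "saccade")
    mean_fix <- mean(segs$n_frames[segs$kind == "fixation"]) / 120
    mean_sac <- mean(segs$n_frames[segs$kind == "saccade"]) / 120
    predicted <- 10 / (mean_fix + mean_sac)
    expect_gt(n_sac, 0.9 * predicted - 1)
    expect_lt(n_sac, 1.1 * predicted + 1)
  }
})

test_that("zero gait amplitudes with g = 1 give pure downward in-orbit rotation", {
  pav <- fx_pavement()
  g0 <- gait_params(vertical_amplitude = 0, lateral_amplitude = 0,
                    lateral_yaw_amplitude = 0)
  h0 <- simulate_head_trajectory(g0, 6)
  tk <- simulate_gaze_sequence(h0, gaze_params(lookahead_mean = 45,
                                               lookahead_sd = 2,
                                               off_path_sd = 0, seed = 9), pav)
  kin <- eye_in_orbit_kinematics(tk)
  fix <- which(tk$label_kind == "fixation" & seq_along(tk$label_kind) < kin$n)
  fix <- fix[tk$label_kind[fix + 1] == "fixation"]
  expect_true(all(circ_diff(kin$direction[fix], 270) < 1e-6))
  expect_true(all(kin$speed[fix] > 0))
})

test_that("stabilization gain below one accrues the predicted slip", {
  pav <- fx_pavement()
  h <- simulate_head_trajectory(gait_params(), 8)
  tk <- simulate_gaze_sequence(h, gaze_params(lookahead_mean = 45,
                                              lookahead_sd = 3, gain = 0.9,
                                              seed = 4), pav)
  segs <- segments_from_labels(tk)
  sl <- slip_analysis(tk, segs, pav)
  # terminal drift ~ (1-g) * omega * T with omega ~ 20-30 deg/s, T ~ 0.25 s
  expect_gt(median(sl$per_fixation$terminal_dev), 0.2)
  expect_lt(median(sl$per_fixation$terminal_dev), 1.2)
  # medians over the ramp sit near half the terminal drift
  rat <- sl$per_fixation$median_dev / sl$per_fixation$terminal_dev
  expect_gt(median(rat), 0.3)
  expect_lt(median(rat), 0.7)
})

test_that("gaze angles follow the stated conventions", {
  expect_equal(gaze_angles(c(0, 0, -1), c(1, 0, 0))$alpha_v, 0)
  ga <- gaze_angles(c(1, 0, 0), c(1, 0, 0))
  expect_equal(ga$alpha_v, 90)
  expect_equal(ga$alpha_h, 0)

  # 30 deg to the right of heading, viewed from above, is +30
  g30r <- c(cos(-pi / 6), sin(-pi / 6), 0)
  expect_equal(gaze_angles(g30r, c(1, 0, 0))$alpha_h, 30, tolerance = 1e-9)
  g30l <- c(cos(pi / 6), sin(pi / 6), 0)
  expect_equal(gaze_angles(g30l, c(1, 0, 0))$alpha_h, -30, tolerance = 1e-9)

  expect_warning(ga0 <- gaze_angles(c(1, 0, 0), c(0, 0, -1)))
  expect_true(is.na(ga0$alpha_h))
  expect_equal(ga0$alpha_v, 90)
})
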