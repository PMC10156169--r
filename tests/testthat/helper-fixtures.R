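# Shared fixtures, built lazily and cached for the session so expensive
# simulations are run once across test files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, build(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

fx_pavement <- function() fixture("pavement", function() {
  make_terrain("pavement", extent_m = 40, width_m = 16, seed = 1)
})

fx_rocks <- function() fixture("rocks", function() {
  make_terrain("rocks", extent_m = 40, width_m = 16, seed = 2)
})

fx_grid49 <- function() fixture("grid49", function() retinal_grid(49, 45))

# 8 s pavement walk, gaze ~45 deg, perfect stabilization
fx_walk45 <- function() fixture("walk45", function() {
  h <- simulate_head_trajectory(gait_params(), 8)
  simulate_gaze_sequence(h, gaze_params(lookahead_mean = 45, lookahead_sd = 4,
                                        off_path_sd = 4, seed = 3),
                         fx_pavement())
})

fx_flow45 <- function() fixture("flow45", function() {
  flow_for_track(fx_walk45(), fx_pavement(), fx_grid49(), stride = 6)
})

# hand-built flow field with constant speed/direction on a grid
constant_field <- function(grid, speed, direction) {
  n2 <- grid$n^2
  structure(list(speed = ifelse(grid$valid, speed, NA_real_),
                 direction = ifelse(grid$valid, direction, NA_real_),
                 valid = grid$valid, n = grid$n, frame_index = NA),
            class = "flow_field")
}

# angular distance between direction angles, degrees
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
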