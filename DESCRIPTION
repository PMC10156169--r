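Package: retflow
Title: Retinal Motion Statistics from Simulated Natural Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the retinal optic-flow input experienced by a walker
    who stabilizes gaze on the ground: parametric terrain heightfields,
    gait-driven eye trajectories, saccade-and-fixate gaze sequences with
    controllable stabilization gain, ray-cast depth rendering on a
    linear-eccentricity retinal grid, a frame-pair retinal flow engine with a
    closed-form rigid-scene oracle, and the pooled speed/direction statistics
    of that flow (speed maps, probe histograms, gaze-angle conditioning,
    terrain-matched comparisons, retinal slip and saccade analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
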