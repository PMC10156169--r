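# retflow

Retinal motion statistics from simulated natural locomotion.

## What this is for

When a person walks over natural ground, gaze is held on a world-fixed spot a
few steps ahead between saccades, and the eye counter-rotates in the orbit
(largely via the vestibulo-ocular reflex) while the body translates and bobs
through the gait cycle. The motion pattern that actually lands on the retina —
low speeds at the fovea, speeds rising with eccentricity, a lower-field bias
under far gaze, vertically dominated directions, gaze-angle-dependent
circulation — is the joint product of ground-plane geometry, gaze behavior,
stabilization quality and gait. `retflow` is for researchers in visual
neuroscience and oculomotor control who want to generate those retinal flow
signals synthetically, under controlled conditions, and compute their summary
statistics.

## The model

The eye at position `p` with retinocentric basis `X, Y, Z` (`Z` = gaze,
`X` = normalize(`Z` × up), `Y` = `X` × `Z`; torsion-free) samples the visual
field on an azimuthal-equidistant grid: `n` × `n` cells (default 250 × 250 =
62,500 samples/frame) with `theta = atan2(y, x)`, `phi = sqrt(x² + y²)`,
eccentricity 0-45°. Per frame, the distance to the terrain along every grid
ray gives a depth map; per frame pair, the 3D point seen at `t` is
re-projected from the pose at `t + 1/120 s`, giving a retinal speed
(angle between the two directions ÷ dt, deg/s) and a direction
(`atan2(Δy, Δx)` in the chart; 90° = up, 270° = down) at every cell.

The walker is synthetic: a heightfield terrain in one of five roughness
classes (pavement → rocks), a sinusoidal gait (1.3 m/s, 1.6 m eye height,
1.8 Hz steps, 2.5 cm bounce, 4 cm sway, ±12° body yaw), and
saccade-and-fixate gaze: fixations of 200-300 ms at terrain-typical vertical
gaze angles (rocks ≈ 45°, pavement near the horizon), main-sequence saccades,
and a stabilization gain `g ∈ [0, 1]` — each frame the eye performs `g` times
the rotation exact world-fixed gaze would require, so `g = 1` pins the gaze
point and `g < 1` accrues retinal slip at rate `(1 − g)·ω`.

The frame-pair engine is validated against the closed-form rigid-scene motion
field `−(T − (T·d)d)/Z − Ω × d` over a plane (agreement ≈ 0.01 deg/s), and
against the geometry's exact predictions: with gaze at vertical angle
`alpha_v`, the meridian speed is `(v/h)|cos²(alpha_v − e) − cos²(alpha_v)|`,
so the lower/upper asymmetry scales with `−cos(2·alpha_v)` — strong for far
gaze, zero at 45°, reversed below.

## Worked example

```r
library(retflow)

terrain <- make_terrain("rocks", seed = 1)
head    <- simulate_head_trajectory(gait_params(), duration_s = 10)
track   <- simulate_gaze_sequence(head,
                                  gaze_params_for_terrain("rocks", seed = 2),
                                  terrain)
track
#> eye pose track: 1201 frames at 120 Hz (10.0 s), 910 fixation / 291 saccade
#> frames, 32 fixations

grid <- retinal_grid(n = 64, max_ecc = 45)
flow <- flow_for_track(track, terrain, grid, stride = 4)
map  <- pool_speed_map(flow, grid)
map
#> speed map: 64 x 64, 3096 covered cells, mean 20 deg/s (max 39.5)
plot(map)   # mean-speed image with iso-speed contours

meridian_peaks(map, length(flow$fields))
#> lower-field peak 32.4 deg/s at 44 deg ecc; upper 38.8; ratio 0.83

slip_analysis(track, segments_from_labels(track), terrain)$median
#> 3.4e-10   # perfect stabilization: the gaze point never slips

segs <- segment_fixations(eye_in_orbit_kinematics(track))
table(segs$kind)
#> fixation  saccade
#>       32       31
```

Reading the numbers: with gaze parked ~45° down (rocky-terrain habit), mean
retinal speed is ~20 deg/s over the 45°-eccentricity disc and peaks at
~32 deg/s toward the feet; at this near-gaze angle the upper field is
comparably fast (ratio ≈ 0.8) — the familiar lower-field dominance (ratio ≈
2-3) emerges when far-gaze terrains are pooled in, which is what
`scripts/acceptance.R` demonstrates. With gain 1 the fixated point stays on
the fovea to numerical precision, and the velocity/acceleration detector
recovers the simulator's own 31 saccades.

A full seeded pipeline with CSV outputs and a provenance record:

```r
res <- run_experiment(default_config("rocks", duration_s = 20, grid_n = 64),
                      "results/rocks-run")
```

The methods vignette (`vignettes/retinal-motion-statistics.Rmd`) documents
the model, conventions, parameter choices and limitations.

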