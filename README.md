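# ScopeTrack

Markerless, feature-based 2D tracking of a rigid surgical situs from a
surgical microscope's RGB image stream.

## The problem

Microscope-mounted robotic assistance (for example a laser for cochleostomy)
must stay registered to the patient while both the microscope and the patient
move. The standard of care uses fiducial markers rigidly attached to the
patient, which costs preparation time, adds invasiveness, and needs a free
line of sight. Because the drilled temporal bone moves (nearly) rigidly and a
magnified video stream already exists, the relative motion between microscope
and situs can instead be estimated from the images alone.

ScopeTrack implements that estimator, the evaluation protocol around it, and
a synthetic bone-scene simulator that supplies image sequences with exact
ground-truth motion, so the whole pipeline can be developed and benchmarked
without a microscope, phantom, or robot.

## The method

For each pair of consecutive frames F_i, F_{i+1}:

1. **Reflection masking.** Specular lamp reflections are bright and nearly
   colorless. With I the HSV value channel, S the saturation channel, and
   I_max, S_max the frame maxima, a pixel is kept for feature detection iff

       I < τ1·I_max  ∨  S > τ2·S_max        (defaults τ1 = 0.8, τ2 = 0.2)

   The complement — bright AND unsaturated — is excluded as a reflection
   artifact.
2. **Feature detection.** Oriented FAST corners with rotated 256-bit BRIEF
   descriptors (ORB-style), at most k per frame (k = 2000 referenced to
   1080p, rescaled by pixel count), detected only on valid mask pixels.
3. **Matching.** Brute-force Hamming nearest neighbours with mutual
   cross-check.
4. **Robust model estimation.** Seeded RANSAC fits the 6-parameter planar
   affine transform

       T = | a00 a01 b0 |
           | a10 a11 b1 |
           |  0   0   1 |

   by exact minimal samples (3 matches), keeps the largest consensus under a
   3 px reprojection threshold, and refits by least squares on the inliers.
   T_i maps pixel coordinates in F_i to coordinates in F_{i+1}.
5. **Pose cascading.** Step transforms are accumulated,
   x_n = (T_{n-1} ··· T_0) · (0, 0, 1)ᵀ, giving the tracked trajectory.
   Failed steps (too few matches or inliers) hold the position and are
   flagged. Optionally, every K frames the tracker re-registers against a
   stored keyframe and replaces the cumulative transform, bounding drift.

Evaluation follows the reference-robot protocol: piecewise-linear reference
trajectories (a cross through (0,0),(0,10),(0,−10),(0,0),(10,0),(−10,0),(0,0)
mm and a 26-waypoint spiral of four turns growing to radius 5 mm) traversed
at a constant 2 mm/s, the per-pair translation error E = Δx_tracked −
Δx_reference, and the mean absolute error distance μ = (1/n) Σ ‖E_n‖.

## Worked example

Simulate the cross trajectory over a synthetic bone scene (512×512 px,
4 px/mm, moving specular highlights, sensor noise), track it, and evaluate:

```r
library(ScopeTrack)
spec <- sceneSpec(seed = 1)
ref  <- linearReference()
sim  <- renderSequence(spec, ref, times = seq(0, referenceDuration(ref), 1))
run  <- trackSequence(sim$frames, trackerConfig(ransac_seed = 1, mm_per_pixel = 1/4))
run
#> TrackingRun  41 frames, 0 fallbacks, mean inlier ratio 0.980
#>   final position (0.061, -0.007) px
frameErrors(trackingRecords(run), ref)
#> ErrorSummary  n = 40 pairs  mu = 0.0096 mm  std = 0.0048 mm
```

The 80 mm out-and-back cross closes to within 0.06 px of the origin, and the
mean frame-to-frame error distance is ~10 μm at the simulated scale
(0.25 mm/px). `trackingRecords(run)` holds the full per-frame table (step
transform parameters, cascaded position in px and mm, feature/match/inlier
counts, status).

The same workflows are available from a shell:

```sh
scopetrack=$(Rscript -e 'cat(system.file("scripts", "scopetrack", package = "ScopeTrack"))')
$scopetrack simulate --out sim --trajectory linear --seed 1
$scopetrack track    --frames sim/frames --out tracked.csv --seed 1 --mm-per-pixel 0.25
$scopetrack evaluate --measured tracked.csv --truth sim/truth.csv --out eval --plots
```

## Layout

- `R/` — implementation: frame/config/trajectory IO, reflection mask,
  feature pipeline, RANSAC affine estimation and pose cascading, tracker
  orchestration, evaluation protocol, synthetic scene generator, CLI.
- `tests/testthat/` — unit, property and acceptance tests.
- `vignettes/tracking-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical conventions, limitations.
- `inst/scripts/scopetrack` — the shell entry point.
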