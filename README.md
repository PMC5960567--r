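# noarsa

Intensity-based nonoverlapping-area (NOA) 2D-3D registration for
model-based radiostereometric analysis (MBRSA).

## What it does, and for whom

Radiostereometric analysis measures sub-millimetre migration of a joint
prosthesis relative to bone from a calibrated stereo pair of radiographs.
The model-based variant avoids implant-attached tantalum markers: the
implant pose is recovered by registering a surface model of the prosthesis
into the two views. `noarsa` is for researchers in orthopaedic imaging and
medical image analysis who need an open, fully scriptable implementation of
the intensity-based NOA formulation of that registration — including its
distinctive ability to exclude user-selected unreliable image regions
("drop-outs", e.g. a ball head occluded by a metal acetabular cup) from the
metric.

Given the radiographs (binary segmentations or enhanced grayscale), a
triangle mesh of the implant (STL/PLY/OBJ, mm), a DLT calibration for each
view and a coarse initial pose, the package minimizes

    PD(p, x, y) = DR(x, y) - DRR(p, x, y)
    NOA(p)      = sum over x, y of PD(p, x, y)^2      ->  min over p

where `DR` is the real radiograph, `DRR(p)` the binary silhouette of the
mesh rendered at pose `p = (rx, ry, rz, tx, ty, tz)` (degrees / mm), and
the sum stacks both views over fixed regions of interest. Because the
binary objective is piecewise constant, Jacobians come from central
differences `(DRR(p + eps) - DRR(p - eps)) / 2 eps`, and the optimization
runs five Levenberg-Marquardt stages with `eps = 10, 1, 0.1, 0.01, 0.001`
(mm or degrees), coarse to fine. For binary segmentations the residual NOA
is reported in its relative form `NOA / (NOA + C)` (`C` = overlapping
pixels), a directly interpretable quality indicator in percent.

The package also ships the supporting geometry (DLT calibration from cage
beads, triangulation, rigid marker fitting), radiograph I/O and enhancement,
a software silhouette rasterizer (C++ inner loop), a synthetic phantom
generator (asymmetric femoral-stem mesh, biplanar 36-bead calibration cage,
stereo silhouette radiographs at selectable pixel spacing, drop-out
scenarios), and an in silico evaluation harness.

## Worked example

Everything below is generated — no data files needed. We build a synthetic
scene at 0.5 mm detector pixel spacing, perturb the true pose by up to
±5 mm / ±5° per axis, and register back:

```r
library(noarsa)

scene <- phantom_scene(seed = 1, pixel_spacing = 0.5)
views <- list(
  list(dr = simulate_radiograph(scene, "ap",  "binary"),
       camera = scene$cameras$ap,  mask = NULL),
  list(dr = simulate_radiograph(scene, "lat", "binary"),
       camera = scene$cameras$lat, mask = NULL))

start <- sample_initial_poses(scene$ground_truth_pose, bound = 5,
                              n = 1, seed = 42)[[1]]
fit <- noa_register(views, scene$mesh, start, margin_px = 32)
fit
#> <noa_registration> binary mode, converged
#> <pose6> r = (-0.001552, -0.02522, -0.0008474) deg, t = (5.903e-05, -0.002567, 0.002169) mm
#>   rotation center (6.516, -15.5, 1.735) mm
#>   NOA 2 (relative 0.008229%), 61 iterations over 5 stages (13.11 s)

pose_error(fit$pose, scene$ground_truth_pose)
#>           rx           ry           rz           tx           ty           tz
#> 1.551528e-03 2.521839e-02 8.473730e-04 5.903145e-05 2.567257e-03 2.168618e-03
```

The ground-truth pose is the zero pose, so the recovered parameters are the
errors: from a perturbation of several millimetres and degrees, the pose
comes back to within ~0.025° (the hard proximodistal rotation) and a few
micrometres of the truth, with 2 of roughly 24,000 silhouette pixels left
unexplained (relative NOA 0.008%). At the finest 0.143 mm spacing the
registration typically drives the NOA to exactly zero. `tidy(fit)` and `glance(fit)` give broom-style
summaries, `autoplot(fit)` the per-stage residual decrease.

The full in silico evaluation (three pixel spacings, 20 seeded trials each)
is one call:

```r
results <- run_insilico_experiment(insilico_config(trials = 20, seed = 1))
summarize_insilico(results)   # per-cell mean/SD errors, iterations, NOA (%)
autoplot(results)             # error distributions vs pixel spacing
```

A thin command-line front end covers the same operations
(`calibrate`, `register`, `simulate`, `evaluate`, `triangulate`):

```sh
Rscript inst/cli/noarsa.R simulate --seed 1 --spacing 0.5 -o scene/
Rscript inst/cli/noarsa.R register --mesh scene/mesh.stl \
  --ap scene/ap.png --lat scene/lat.png --calib scene/calibration.json \
  --init scene/truth_pose.json --binary -o result.json
```

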