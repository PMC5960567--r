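---
title: "Intensity-based nonoverlapping-area registration for model-based RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-based nonoverlapping-area registration for model-based RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noarsa)
```

## The measurement problem

Radiostereometric analysis (RSA) measures sub-millimetre migration of a joint
replacement relative to the surrounding bone from a calibrated stereo pair of
radiographs. Model-based RSA (MBRSA) avoids marking the implant with tantalum
beads: the implant pose is instead recovered by 2D-3D registration of a
surface model of the prosthesis into the two views. `noarsa` implements an
intensity-based formulation of this registration built on the
*nonoverlapping area* (NOA): the set of pixels on which the real and the
reconstructed implant segmentations disagree.

## The model

Each view is described by a 3x4 homogeneous projection (an 11-parameter
direct linear transformation, DLT) solved from the bead correspondences of a
calibration cage. Given a candidate pose $p = (r_x, r_y, r_z, t_x, t_y, t_z)$
— rotations in degrees, translations in millimetres, applied about a fixed
rotation center — a binary silhouette DRR (digitally reconstructed
radiograph) of the mesh is rasterized through each camera. The objective
stacks per-pixel differences over both views:

$$\mathrm{PD}(p, x, y) = \mathrm{DR}(x, y) - \mathrm{DRR}(p, x, y),
\qquad \mathrm{NOA}(p) = \sum_{x,y} \mathrm{PD}(p, x, y)^2,$$

minimized as a nonlinear least-squares problem over the six degrees of
freedom. For binary segmentations the sum of squares *is* the count of
disagreeing pixels; the relative form
$\mathrm{NOA}/(\mathrm{NOA} + C)$, with $C$ the count of pixels lit in both
images, normalizes away resolution and perspective scaling and is reported in
percent. For grayscale (nonsegmented) radiographs the same least-squares
machinery applies with real-valued residuals; the relative form is then
undefined and not reported.

Because the silhouette is binary, the objective is piecewise constant in the
pose: derivatives must come from finite differences at a spacing coarse
enough to flip pixels. The Jacobian has one row per unmasked region-of-
interest pixel (both views stacked, AP first, row-major) and one column per
degree of freedom, each column obtained from exactly two renders at
$p \pm \varepsilon e_d$. Registration runs five Levenberg-Marquardt stages
with $\varepsilon = 10, 1, 0.1, 0.01, 0.001$ (millimetres or degrees — the
reason angles are kept in degrees, so one schedule covers both), each stage
warm-starting from the previous: the coarse stages provide capture range, the
fine stages accuracy.

A note on the residual-derivative sign: since
$\mathrm{PD} = \mathrm{DR} - \mathrm{DRR}$, the central difference of the DRR
enters the Jacobian negated. The sign is a global factor on the Jacobian and
leaves the damped least-squares step unchanged; it is kept as an explicit
constant in the code.

## Numerical choices

* **Rasterization.** A software edge-function rasterizer (C++ inner loop):
  a pixel is lit iff its center lies inside at least one projected triangle,
  with pixel centers exactly on an edge counted inside. The silhouette is
  the union over triangles, so there is no depth buffer and back faces are
  not culled; the inclusive rule makes the union seam-free and the result
  deterministic. Edge functions are evaluated directly per pixel rather than
  incrementally so the inclusive rule stays exact. No antialiasing: the
  metric is defined on binary pixels.
* **Region of interest.** Computed once per view from the DR segmentation as
  the bounding box enlarged by a margin, then held fixed, so the objective
  does not change mid-optimization. The margin must exceed the largest
  expected initial-pose silhouette displacement; the experiment harness uses
  16 mm (converted to pixels per spacing), which covers the worst-case
  ~14 mm displacement of the validated ±5 mm / ±5° capture range at the
  ~1.1 detector magnification used here.
* **Levenberg-Marquardt.** Damping $\lambda I$ with
  $\lambda_0 = 10^{-3}\,\mathrm{tr}(J^\top J)/6$. A step is accepted only if
  the residual sum of squares strictly decreases; on an increase $\lambda$
  is multiplied by 10, after an acceptance divided by 10. Trial steps that
  leave the residual *exactly unchanged* get special treatment, because on a
  piecewise-constant objective they are common and informative: a vanishing
  equal-residual step means no pixel flipped, so $\lambda$ is divided by 10
  to lengthen the next trial; a finite equal-residual step is walked (the
  pose moves without resetting $\lambda$), at most five consecutive times,
  which lets the fine stages traverse flats of the staircase landscape and
  crawl along the coupled rotation-translation valley of the proximodistal
  axis instead of stalling one or two pixels short of the optimum. A stage ends on
  zero residual, a relative reduction below $10^{-6}$, failure to find any
  improving step among 25 damped trials, or 100 iterations. A step-norm
  cutoff is deliberately absent: on the staircase landscape, small accepted
  steps routinely precede larger valley moves, and ending a stage on step
  size froze registrations short of the optimum.
* **Rotation convention.** Fixed-axis X→Y→Z (right-handed), rotation center
  at the mesh centroid by default: the centroid minimizes rotation-
  translation coupling in the optimizer, and per-axis error reporting is
  insensitive to the convention at sub-degree errors. Both choices are
  configurable.
* **Enhancement is preprocessing.** Histogram equalization (plain CDF
  mapping on 256 levels) and gamma adjustment are explicit `imaging` steps
  applied *before* registration; the registration consumes the enhanced
  image as its residual target. Equalization is rank-based, so on synthetic
  two-level images it spreads the homogeneous background over most of the
  output range — thresholds for segmenting such images are therefore applied
  to the enhanced image directly, and the synthetic generator's grayscale
  output is already "enhanced" by construction.
* **Degenerate inputs.** Calibration requires ≥6 non-coplanar beads;
  triangulation rejects (near-)parallel rays; rigid fitting requires ≥3
  non-collinear points and returns a proper rotation even for
  reflection-dominated correspondences; rendering rejects poses that put
  any vertex at non-positive depth; empty segmentations cannot define an
  ROI and are an error.

## The synthetic phantom

No implant geometry or radiographs ship with the package; everything is
generated. The stem generator emulates a cementless revision femoral stem:
a ~150 mm lofted surface of *superelliptical* (rounded-rectangular)
cross-sections — implants of this family have a rectangular tapered profile,
and the corners are precisely what makes the silhouette sensitive to
rotation about the long (proximodistal) axis — tapered distally, twisted by
18°, bowed laterally, plus an off-axis spherical ball head. The lateral bow,
twist and off-axis head leave no rotational symmetry: the silhouette differs
from its own half-turn by far more than 1% of the lit area, the property
that makes pose recovery from two views well-posed at all. A seed-controlled
low-order harmonic perturbation of the radius profiles makes different seeds
give distinct implants while keeping the surface smooth, so the shape
converges as the mesh is refined. The default resolution (48 points per
section, 56 sections, ~7600 triangles) follows the reference practice of
registering against a high-resolution model: coarser meshes make the
discrete NOA landscape visibly bumpier and measurably hurt convergence of
the proximodistal rotation.

The stereo rig places two pinhole cameras with principal rays intersecting
at the scene origin, 90° apart (the anterior-posterior / lateral setup),
source-to-origin 1000 mm and source-to-detector 1100 mm (magnification 1.1),
with a ~300 mm field of view — geometry comparable to a clinical biplanar
calibration cage. The cage carries 36 beads on two parallel planes with
exact projections, so DLT calibration from the cage recovers each camera to
numerical precision (a self-consistency the tests pin at RMS < 1e-8 px).

Simulated radiographs are exact silhouettes (binary mode) or two-level
images with foreground ~N(0.95, σ) and background ~N(0.2, σ) clipped to
[0, 1] (grayscale mode), honoring the radiopacity assumption that the
implant is the brightest object. Initial poses perturb each degree of
freedom independently by Uniform(−b, +b). Drop-out scenarios place a
circular mask over the projected ball head sized (by bisection) to cover a
requested fraction of the lit area, optionally burning a bright occluder
disk — an acetabular-cup stand-in — into grayscale radiographs, offset so it
corrupts the silhouette boundary.

What the generator does *not* emulate: X-ray attenuation physics, scatter,
beam hardening, anatomy or cement around the implant, detector blur, or
calibration error (cameras are exact). Passing the in silico evaluation
therefore demonstrates the correctness and accuracy of the registration
machinery itself under the stated protocol — the same inverse-crime caveat
any same-renderer evaluation carries — not clinical performance on real
radiographs.

## The in silico evaluation

`run_insilico_experiment()` reproduces the evaluation protocol at desk
scale: for each pixel spacing (0.5, 0.35, 0.143 mm) it renders noise-free
binary stereo silhouettes at the ground-truth pose, draws 20 seeded initial
poses within ±5 mm / ±5° per axis (the study used 100), registers each with
the default five-stage schedule, and tabulates per-axis absolute errors,
iteration counts and residual relative NOA. The problem sizes are the
package's own choice of a desk-scale protocol: 20 trials per cell give
stable means for the sub-millidegree checks while the whole three-spacing
table computes in a few minutes on one core. The proximodistal (y) rotation
is consistently the least accurate axis — both views look roughly
perpendicular to it, so its silhouette signal comes only from the implant's
asymmetry — and accuracy improves monotonically with resolution, with mean
errors at 0.143 mm spacing in the sub-millidegree / sub-micrometre-ish
range typical of a noise-free same-renderer evaluation.

```{r, eval = FALSE}
results <- run_insilico_experiment(insilico_config(trials = 20, seed = 1))
summarize_insilico(results)
autoplot(results)
```

## Known limitations

* The binary objective is piecewise constant; all derivative information
  comes from finite differences, and convergence into the last few
  nonoverlapping pixels depends on the plateau rule described above. A few
  trials per cell may end with a handful of residual pixels rather than
  exactly zero.
* Capture range is bounded: beyond roughly ±5 mm / ±5° initial error the
  coarsest stage may converge to a wrong basin, and no multi-start or
  global search is attempted.
* Grayscale registration assumes the enhanced radiograph approximates a
  probabilistic segmentation (implant near the top of the intensity range);
  strongly textured backgrounds violate this and should be masked or
  segmented instead.
* Clipping is unsupported: every posed vertex must project in front of the
  camera (silhouettes may fall outside the raster, which is handled).
* The DLT model carries no lens/detector distortion terms, and bead
  detection in real images is out of scope — marker coordinates are inputs.
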