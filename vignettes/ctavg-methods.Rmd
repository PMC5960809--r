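---
title: "Average-brain CT templates and subtraction-based detection of small hemorrhages"
author: "ctavg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average-brain CT templates and subtraction-based detection of small hemorrhages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small intracranial hemorrhages (under 10 mm in diameter) are easy to miss
on non-contrast head CT, especially outside specialist settings, yet missing
them can allow secondary injury in traumatic brain injury (TBI) patients.
`ctavg` implements a deliberately simple detection principle: build an
"average brain" CT from a group of lesion-free control scans, deform that
average onto a patient's scan, and subtract. Healthy tissue largely cancels;
fresh blood, which is hyperdense (above roughly 60 Hounsfield units, versus
3–40 HU for brain parenchyma and CSF), survives subtraction as a bright
residual.

The package covers the whole chain: Hounsfield-unit volume handling and
preprocessing, a from-scratch deformable registration framework, template
construction, subtraction and candidate extraction, lesion-level scoring,
and a seeded synthetic-phantom generator that serves as the test substrate
in place of patient data.

## The registration framework

Registration maps points of the *fixed* image's physical space to the
*moving* image's space, maximising mutual information (MI) between the two
intensity distributions. The recipe, applied per stage:

* **Scale space.** Four levels of Gaussian smoothing with standard
  deviations 4, 2, 1 and 0.5 (in voxels; the grid is never downsampled, so
  level bookkeeping stays trivial). Levels run coarse to fine; trilinear
  interpolation on the first three levels, cubic B-spline interpolation
  (with prefiltered coefficients) on the final level.
* **Sampler.** 3000 random continuous coordinates drawn fresh over the
  fixed head mask at *every* iteration. An iteration is valid only if at
  least 150 points land inside both image domains; otherwise the stage
  aborts ("insufficient coordinate alignments").
* **Metric.** Mutual information from a 32×32 joint histogram built with
  cubic B-spline Parzen windows on both intensity axes, which makes the
  estimate differentiable. The intensity-to-bin mapping is frozen per stage
  from the min/max of the intensities sampled under the stage's initial
  transform (padded by 5%); samples outside the frozen range are clamped
  and carry no gradient. The analytic gradient chains the Parzen-window
  derivative with the moving image's spatial gradient and the transform
  Jacobian, and is verified against central finite differences in the test
  suite.
* **Transform stages.** Rigid (3 Euler angles + 3 translations, centred on
  the fixed head centroid, initialised by aligning head centres of mass),
  then affine (12 parameters, optimising the residual after the rigid
  map), then a cubic B-spline free-form deformation with 20 mm control-point
  spacing. The chain maps `x` to `A(R(x)) + u(x)`: global stages compose
  sequentially and the local displacement `u` is evaluated at the chain
  input point (the classical global + local FFD decomposition), so the
  control grid covers the fixed domain plus a margin and is identically
  zero when all coefficients are zero.
* **Optimizer.** Adaptive stochastic gradient descent with step size
  `a / (A + t_k)^alpha`. The adaptive time `t_k` moves by a sigmoid of the
  negated, normalised inner product of successive stochastic gradients:
  correlated gradients accelerate, anti-correlated ones decelerate.
  Iteration budgets are 1500 (rigid), 1500 (affine) and 2500 (B-spline);
  the budgets are read as per-stage totals and split evenly across the four
  pyramid levels.

### Numerical choices that are the package's own

Several constants are not fixed by the recipe above and were chosen once,
on the grounds given here:

* *ASGD gains.* `alpha = 0.602`, `A = 20`; sigmoid `fmin = -0.8`,
  `fmax = 1`, `omega = 0.2` on the gradient-correlation scale. The gain `a`
  is auto-calibrated per level so the first step moves about `delta` mm,
  with `delta` equal to one mean voxel at the coarsest level and halved at
  each finer level. Calibration uses the median norm of five probe
  gradients, so one unlucky stochastic draw cannot set an oversized step.
  Single steps are capped at `2 * delta` (a trust region), and the returned
  parameters average the final 25% of iterates, which damps the stochastic
  tail near an optimum. All of these are exposed in `optimizer_config()`.
* *Rotation/matrix parameter scaling.* Rotations and affine matrix entries
  are internally multiplied by the sampling-region radius so one internal
  unit moves a peripheral point by about 1 mm; this removes the unit
  mismatch between radians and millimetres inside one step size.
* *Interpolation.* The registration interpolator is the classical
  prefiltered cubic B-spline; its recursive prefilter uses exact
  mirror-boundary initialisation so voxel centres are reproduced to 1e-6
  even on short axes. Axial slice reconstruction (`resample_axial`) instead
  uses a Catmull–Rom cubic with anti-symmetric boundary extension, which
  reproduces linear intensity ramps exactly up to the volume border.
* *Out-of-domain policy.* Resampling fills out-of-domain voxels with
  -1000 HU (air), which is what a scanner reports outside the patient.
* *Self-information identity.* With cubic Parzen windows on both axes the
  textbook identity MI(X,X) = H(X) holds only approximately (the smoothed
  joint histogram has off-diagonal mass); it is exact under the package's
  zero-order histogram estimator, and the tests assert it there. The
  Parzen estimator is cross-checked against an independent brute-force
  reimplementation instead.

## Template construction

One control is designated the fixed image; every control (including the
fixed one itself, whose self-registration is not the exact identity) is
registered to it with the full rigid→affine→B-spline chain, resampled onto
the fixed grid with cubic interpolation, and averaged voxelwise without any
intensity normalisation or trimming. Per-control sampler seeds are derived
by hashing the control's identifier together with the master seed, so a
build is reproducible and invariant to the order of the control list. A
control whose registration fails is dropped with a warning; fewer than two
survivors abort the build.

The fixed image is an explicit argument; a cheap automatic mode (mean MI of
coarse affine-only alignments to all other controls) exists for the CLI but
is a deviation from an explicit clinical choice and is logged as such.

## Detection

The template is registered *onto* each subject (subject fixed, template
moving), resampled to the subject grid, and subtracted (subject minus
template, signed). Candidates are 26-connected components of voxels with

* difference above 25 HU (half the nominal contrast between blood at
  ~60-80 HU and parenchyma at ~35-40 HU), **and**
* subject attenuation above 60 HU (the physiological floor for fresh
  blood),

inside the head mask with the skull excluded (subject HU > 300, dilated by
one voxel — this suppresses the bright skull-edge rim that subtraction
otherwise produces). Components with sphere-equivalent diameter under 2 mm
are discarded. Hypodense differences are rendered in the overlays but never
become candidates, since hemorrhage is hyperdense. No ventricle
segmentation is attempted; periventricular pseudo-differences caused by
shape variability are a known limitation of the subtraction principle and
are controlled here only by the two thresholds above.

Scoring is greedy one-to-one centroid matching at 5 mm (half the largest
target lesion diameter); sensitivity is pooled over lesions, i.e.
TP / (TP + FN) across the whole cohort, matching the arithmetic that makes
65 of 67 lesions 97%.

## The synthetic cohort

No patient data ships with the package; a seeded generator produces head
phantoms with the statistical structure the method relies on:

* an ellipsoidal skull shell (~1000 HU, 7 mm thick) around a brain with a
  folded cortical gray ribbon (40 HU, thickness modulated around 4 mm),
  white matter (35 HU), deep gray nuclei and a falx (40 HU), and paired
  CSF ventricles (8 HU) — tissue values sit inside the physiological 3–40
  HU band, so the blood/brain threshold separation is honest;
* per-subject shape variation: a random affine jitter (±5% scale, ±5°
  rotation, ±5 mm translation) composed with a smooth random displacement
  field (Gaussian-filtered coarse noise, maximum amplitude drawn between 1
  and 3 mm), plus 3 HU Gaussian noise (typical brain-window CT noise);
* optional external clutter (a detached 40 HU "pillow" slab) to exercise
  preprocessing;
* lesions painted *after* the subject deformation, so ground-truth
  centroids are exact in the subject frame: spheres of 3-10 mm diameter
  with attenuation drawn from a truncated normal centred at 72 HU (sd 5,
  clipped to 60-80 HU — acute clotted blood is typically 70-80 HU, with
  60 HU the physiological floor), a smooth 1 mm raised-cosine edge feather
  (1 mm physical width regardless of grid resolution, i.e. one voxel at the
  1 mm reconstruction the method targets), and the voxel nearest the centre
  always carrying the full lesion HU. A `near_bone` flag allows lesions
  within 1-3 mm of the skull, the case hardest for the subtraction method.

The default cohort mirrors the study conditions: 30 controls and 9 lesioned
subjects carrying 12, 2, 11, 16, 3, 14, 2, 1 and 6 lesions (67 in total).

What the phantoms deliberately do **not** model: real cortical anatomy,
partial-volume skull edges, beam-hardening and streak artifacts, scanner
vendor differences, midline shift, and age-related atrophy. Passing the
synthetic benchmark therefore demonstrates that the pipeline's geometry,
metric, optimisation and thresholds work as designed under realistic
intensity statistics — not that the clinical sensitivity would be 97% on
real patients, where temporal-fossa variability and artifacts caused the
misses in practice.

## Problem sizes and reproducibility

The bundled evaluation (tests and `scripts/acceptance.R`) runs the full
cohort in half-resolution mode (2 mm isotropic grids, 60×80×80 voxels), the
generator's `fast` switch; full resolution (1 mm, 120×160×160) is the
default for interactive use. Registration accuracy benchmarks (rigid,
affine, B-spline recovery) use a contained 48×56×56 phantom at 2 mm. The
pipeline-determinism check runs a reduced cohort (3 controls, 2 lesioned
subjects) because reproducibility is a property of the seeding scheme, not
of the cohort size. All randomness flows from one master seed: per-stage
and per-subject seeds are derived by stable hashing, and the sampler runs
single-threaded through R's RNG, so a rerun with the same seed is
bit-identical.

```{r example}
library(ctavg)

out <- tempfile("ctavg_run_")
run <- run_pipeline(list(seed = 42, out_dir = out, fast = TRUE))
print(run$result)
```

## Known limitations

* One fixed image anchors the template, so its anatomy has more influence
  than the other controls; groupwise registration would remove that bias
  but is out of scope here.
* The candidate extractor is a fixed-threshold rule, not an observer model;
  the original reading of subtraction maps was radiological. The
  quantitative extractor makes sensitivity computable but its false-positive
  behaviour on real scans (skull base, tentorium, calcifications) is
  untested by construction.
* Oblique acquisitions are rejected rather than reoriented; inputs are
  expected as axis-aligned NIfTI with positive spacings.
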