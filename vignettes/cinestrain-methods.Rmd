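---
title: "Automated cine CMR analysis: models, parameters and validation"
author: "cinestrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cine CMR analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`cinestrain` analyzes a cine balanced-SSFP cardiac MR study — a stack of
short-axis 2D+time slices plus 2-chamber and 4-chamber long-axis views —
fully automatically, with no user interaction and no randomness, and
reports:

* left-ventricular cavity volumes over the cycle, end-diastolic and
  end-systolic volume (EDV/ESV) and ejection fraction
  (EF = (EDV − ESV)/EDV × 100);
* mean mid-wall Lagrangian circumferential strain of the mid-ventricular
  slice over the cycle, in the engineering convention (percent change of
  the mid-wall circumference against the first phase), plus its peak
  (most negative) value.

The processing stages, in order:

1. **Blood-pool localization.** The LV blood pool is detected per
   short-axis slice as a *moving, bright, round* connected component:
   the temporal standard deviation of each pixel forms a motion-saliency
   map, Otsu-thresholded; the temporal-maximum image is thresholded by
   Otsu within the high-motion region; components are scored by
   roundness (4π·area/perimeter²) × brightness × motion, and the
   cross-slice chain maximizing the summed score subject to adjacent
   centers lying within max(radius, 10 px) wins. Slices with no
   acceptable component get confidence 0; fewer than three confident
   slices aborts the automatic path (an `AlgorithmFailure`), mirroring
   the small fraction of clinical studies that require semi-automated
   fallback.
2. **Mitral-valve base plane.** On each long-axis view and phase, the
   bright moving cavity's basal rim is found along the LV long axis —
   the projection of the short-axis stack normal onto the view (the
   component's principal axis when that projection degenerates); the
   basal end is the extreme with the larger motion saliency, since the
   valve moves and the apex does not; the two rim corners are
   localized to sub-pixel precision at the half-way intensity level
   between the local inside and outside plateaus. A least-squares plane
   (total least squares via the smallest principal component) is fitted
   to the four anchors per phase, its normal oriented toward the apex.
3. **Inverse-consistent registration.** Dense displacement fields
   between cardiac phases are computed by maximizing windowed local
   cross-correlation with gradient descent; each step smooths the
   update (fluid-like) and the accumulated field (diffusion-like), and
   the inverse field is re-estimated by the fixed-point update
   inv(x) ← −fwd(x + inv(x)). Neighbor pairs are chained into two
   passes — one anchored at the first phase going forward, one reaching
   each phase backward through the cycle end — and the final per-phase
   field is the arithmetic average of the two passes' displacements,
   which makes the recovered motion cyclic.
4. **Gray-level region models.** Intensity means and spreads of blood,
   myocardium, background and the blood–myocardium partial-volume class
   are estimated from the localized regions, and each pixel gets an
   *edge possibility*: normalized gradient magnitude weighted by the
   likelihood that the two intensities flanking it along the gradient
   form an ordered (blood, myocardium) or (myocardium, background)
   pair.
5. **Contour recovery.** The edge-possibility map is resampled to polar
   space about the detected center; node cost is 1 − edge possibility.
   The endocardial and epicardial contours are minimum-cost closed
   paths (one radius per angle, bounded radial jumps). For each
   candidate seed phase the contours are propagated to every other
   phase through the deformation fields and re-scored; the family with
   the smallest summed cost is the final segmentation, with the
   epicardium clamped outside the endocardium.
6. **Volumes.** Simpson stacking: cavity volume is the sum over
   accepted slices of the endocardial polygon area times the slab
   spacing (thickness + gap), with each slice scaled by its in-slab
   fraction below the base plane,
   clamp(d/spacing + 0.5, 0, 1), d the signed distance of the slice
   center to the plane (positive apically).
7. **Strain.** The Green–Lagrange tensor
   E = (∇u + ∇uᵀ + ∇uᵀ∇u)/2 is computed from the phase-0-anchored
   displacement gradient in physical units, projected onto local
   radial/tangential directions, averaged over the phase-0 mid-wall
   centerline (material points fixed at the reference), and converted
   to engineering strain by strain% = (√(1 + 2·Ecc) − 1) × 100 — for a
   uniform contraction by factor λ this equals λ − 1 exactly, so a 20%
   radius reduction reads −20%.

## The synthetic phantom

`generatePhantom()` builds studies with analytic ground truth: a bright
circular blood pool (default 22 mm endocardial radius) inside a darker
annulus (10 mm wall), pixel spacing 2 mm, slices of 8 mm with a 2 mm gap,
raised-cosine contraction r(t) = r_ED·(1 − c·w(t)) with w(t) =
(1 − cos 2πt/T)/2 peaking at mid cycle, long-axis views whose basal edge
descends by a configurable distance, 1-px anti-aliased boundaries (a
genuine partial-volume class), and seeded Gaussian noise. Truth includes
the per-phase mid-wall engineering strain ((λ(t) − 1)·100), the clipped
cavity volume, the EF, the valve-anchor positions, and the dense radial
displacement field.

What it deliberately does **not** emulate: bSSFP banding, through-plane
motion in the short-axis slices, papillary muscles (available as an
optional flag, off by default), trabeculation, breathing drift, or
arrhythmic phase misregistration. Passing the phantom validation
therefore demonstrates the correctness of the geometry, registration,
graph-search and strain mathematics under the intensity ordering the
method assumes (blood > myocardium > background) — not clinical-grade
robustness to all real-data artifacts.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ccWindowPx` | 9 | px | local correlation window; smaller tracks finer motion, larger is more robust to noise |
| `stepSizePx` | 1.0 | px | maximum displacement update per iteration (demons-style normalization) |
| `updateSigmaPx` | 1.5 | px | fluid-like smoothing of each force update |
| `smoothingSigmaPx` | 0.75 | px | diffusion-like smoothing of the total field; kept small so textureless regions are not dragged |
| `nPyramidLevels` | 3 | — | capped so the coarsest level stays ≥ 16 px |
| `invertIterations` | 5 | — | fixed-point iterations of the inverse update |
| `nAngles`, `nRadii` | 96, 64 | — | polar grid; radial bins are refined to sub-pixel precision by parabolic interpolation of the cost profile |
| `smoothness` | 1 | bins/angle | maximum radial jump of the closed path |
| endo band | 0.3–1.3 × radius | — | endocardial radial search range |
| epi band | endo + 2 px to 2 × radius | — | epicardial range, constrained outside the endocardium |

The regularization balance is deliberate: a diffusion-dominant field
smoothing drags the static background along with the contracting
annulus, while the fluid-dominant default keeps force-free regions
static; a relative variance floor (10⁻⁴ of the strongest local
variance) zeroes the correlation force where a window has essentially
no contrast, which stabilizes flat blood pool and air.

## Numerical and design choices

* **Coordinates.** 0-based (row, col) pixel indices; world position =
  origin + row·spacing·rowDir + col·spacing·colDir (the DICOM patient
  coordinate contract). Slab spacing for volumetry is thickness + gap.
* **Phase alignment.** Cardiac time is normalized to [0, 1) per slice
  and resampled by nearest neighbor to the maximum phase count; no
  frames are invented. Short- and long-axis series are aligned by
  normalized cardiac time.
* **Closed path.** The polar graph is a DAG in the angle direction, so
  Dijkstra's shortest path reduces to one dynamic-programming sweep per
  candidate start radius; the optimum is exact (verified against
  exhaustive enumeration). Ties break toward the smaller mean radius,
  then the lexicographically smaller radius sequence.
* **Cyclicity.** Raw neighbor-pair chains do not close the loop in
  textureless regions — which is precisely why the two anchored passes
  are averaged. The reported cycle residual composes the per-phase
  increments derived from the final averaged family around the full
  cycle; the raw-chain closure is kept as a diagnostic attribute.
* **Valve-anchor smoothing.** The cyclic 3-phase moving median acts as
  an outlier rejector only: the raw anchor is kept when it agrees with
  the local median within 2 mm. Replacing the track wholesale by the
  median flattens the valve-plane excursion and biases EDV down and ESV
  up by 1–2 EF points. Anchors jumping more than 15 mm between phases
  are replaced by interpolation and flagged.
* **Base-plane clipping** uses the continuous linear in-slab fraction
  rather than exact plane–cylinder intersection; it is exact when the
  plane is parallel to the slices and continuous and monotone in the
  plane offset in general.
* **ED/ES** are the argmax/argmin of the automated volume curve.
* **Mid-slice selection** takes the middle of the contiguous accepted
  range, ties toward the base.
* **Strain convention.** The tensor is Green–Lagrange; reporting uses
  the engineering (Δcircumference/circumference) convention through the
  stretch relation √(1 + 2·Ecc) − 1, which reconciles the
  finite-deformation tensor with the familiar clinical percentages. The
  mean Ecc is converted (rather than converting per pixel and then
  averaging); the difference is second order and the alternative is a
  configuration switch. An Eulerian curve (accumulated incremental
  strains on the tracked centerline) is provided for comparison: it
  nearly equals the Lagrangian curve for small deformations and
  diverges for large ones (toward log-strain).
* **Degenerate inputs.** Constant image pairs register to a flagged
  zero field; a static series has identically zero saliency and fails
  localization; collinear valve anchors are an error; contour families
  violating epicardium ⊇ endocardium in more than 10% of samples raise
  `AlgorithmFailure`.
* **Determinism.** No stage uses random numbers; the only RNG in the
  package is the phantom's seeded noise generator. Identical input and
  configuration give bit-identical reports, which is what makes 100%
  test–retest reproducibility (R = 1.0) structural rather than
  statistical.

## Validation problem sizes

The test suite and the acceptance script validate on desk-scale
phantoms chosen to exercise every code path at interactive runtimes:
the reference study is 5 slices × 8 phases at 80×80 px (2 mm spacing,
20 mm endocardial radius, 10 mm wall, 20% contraction, noise σ = 3,
8 mm valve descent); the reproducibility experiment runs 20 series of
4 slices × 5 phases at 56×56 px with contractions 12.6–24% and a
lighter registration iteration budget; strain recovery sweeps
contractions of 10–25%. On these conditions the engine recovers peak
mid-wall strain within ~0.7 strain-points, EF within ~1.6 EF-points,
volumes within ~3–4%, with exact (bit-identical) reproducibility.

The Lagrangian–Eulerian comparison is evaluated on the phantom's
analytic deformation fields, isolating the strain mathematics from
registration error; the registration itself is validated separately
against the phantom's dense displacement truth.

## Known limitations

* 2D in-plane analysis only: no through-plane motion or 3D
  registration, no diffeomorphic guarantee (no velocity-field
  integration).
* Radial strain is computed internally but not validated or reported;
  no AHA segment breakdown (the mean mid-wall metric needs none); no LV
  mass.
* DICOM reading is not included in this build; studies are accepted as
  NIfTI volumes with a JSON geometry sidecar (the format the phantom
  writer produces). RV insertion points are not detected: the mean
  mid-wall strain over the full circumference never consumes the
  anteroseptal reference angle, and the rotationally symmetric phantom
  could not validate it.
* The blood-pool detector assumes bright-blood contrast; inverted
  contrast or severe shading would defeat the histogram models (the
  documented failure mode of the automatic path).
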