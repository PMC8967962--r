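---
title: "Slice-wise equivalent-ellipse GTV estimation and comparative assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise equivalent-ellipse GTV estimation and comparative assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etecim)
```

## The problem

Gross tumor volume (GTV) — the macroscopically visible tumor extent
delineated on imaging — is a treatment-planning quantity and a
prognostic determinant in radiotherapy of esophageal carcinoma. Given a
3-D binary segmentation mask (manual or automatic), the routine way to
report GTV is voxel summation: foreground count times voxel volume.
Because every boundary voxel is counted in full even where the lesion
only partly fills it, voxel summation is biased upward. This package
implements a geometric alternative: fit the *equivalent (inertia)
ellipse* of the lesion on every axial slice and integrate *truncated
elliptical cone* (frustum) volumes between adjacent slices. It also
provides the complete comparative-assessment toolbox used to judge
automatic segmentations against a manual reference, and synthetic
phantoms with known analytic geometry so every claim is testable
without clinical data.

## The model

### Equivalent ellipse from second moments

The foreground pixels of one axial slice are treated as $N$ unit point
masses at their voxel-center positions $(x_i, y_i)$ in mm. With central
(centroid-relative) second moments

$$A = \sum_i x_i^2,\qquad B = \sum_i y_i^2,\qquad H = \sum_i x_i y_i,$$

the inertia ellipse of the pixel system has half-axes

$$a = \sqrt{\tfrac{2}{N}\big[(A+B) + \sqrt{(A-B)^2 + 4H^2}\big]},\qquad
  b = \sqrt{\tfrac{2}{N}\big[(A+B) - \sqrt{(A-B)^2 + 4H^2}\big]},$$

and its long axis points along the principal eigen-direction,
$\varphi_1 = \tfrac{1}{2}\,\mathrm{atan2}(2H,\, A-B)$, reported in
degrees in $(-90, 90]$. The normalisation by $N$ makes the fit exact on
an ideal uniform ellipse: the coordinate variances of a uniform ellipse
are $a^2/4$ and $b^2/4$ along its principal axes, so the formulas
return the generating semi-axes identically. For a rasterized ellipse
the same property holds up to discretisation error; with a short
half-axis of at least 10 px both half-axes are recovered within 3% and
the orientation within 3° (and the fitted ellipse area $\pi a b$
matches the pixel area within 3%). Below ~5 px the point-mass
approximation degrades visibly — that is the documented validity
domain, not a tunable threshold.

Three derivation choices deserve a note:

* **Central moments.** Moments are taken relative to the slice
  centroid. Raw moments about the image origin would make the fit
  depend on where the lesion happens to sit in the scanner frame.
* **mm-space moments.** Moments are computed in physical coordinates,
  so anisotropic in-plane spacing is handled correctly and half-axes
  come out in mm directly.
* **Orientation convention.** The angle is computed from the principal
  eigen-direction in the y-up mm frame rather than from slope formulas
  of the form $(A-B \pm \sqrt{\cdot})/2H$, which divide by zero for
  axis-aligned foregrounds. The eigen-direction limit is continuous
  there; a perfect circle gets $\varphi_1 = 0$ by convention. The
  rotation-equivariance test pins this convention.

### Frustum integration

Adjacent fitted slices a distance $h$ (the axial spacing) apart bound a
truncated elliptical cone with volume

$$V_i = \frac{\pi h}{6}\Big[2\,(a_i b_i + a_{i+1} b_{i+1})
        + a_i b_{i+1} + b_i a_{i+1}\Big],$$

and the GTV estimate is $\sum_{i=m}^{n-1} V_i$ from the cranial slice
$m$ to the caudal slice $n$. Sanity limits: equal circular sections
give the classical circular frustum $(\pi h/3)(R^2+Rr+r^2)$; equal
ellipses give the cylinder $\pi a b h$; a section shrunk to a point
gives the cone $(\pi h/3)\,a b$. The integration runs between the
*outermost slice centers*, so on an $n$-slice cylinder it returns
$(n-1)\,\pi a b h$ while voxel summation returns $n$ slabs — the
$(n-1)/n$ ratio is a property of the estimator, documented rather than
"corrected", and is the precise sense in which voxel summation
overestimates convex stacked lesions.

Two policies cover inputs the summation formula does not address:

* **Single-slice lesions** ($m = n$): the sum is empty as written; a
  one-slice lesion is assigned $\pi a b h$ (one slice's worth of
  elliptical cylinder), consistent with the voxel baseline's treatment
  of a single slab.
* **Axial gaps**: a mask whose foreground skips intermediate slices is
  split into maximal contiguous runs, each integrated independently and
  summed, with a warning. No interpolation is invented across gaps.
  Degenerate fits inside a run (e.g. a single-pixel slice, $a=b=0$)
  stay in the frustum chain and contribute through the cone limit,
  keeping the estimator deterministic.

### RECIST-style diameters

From the fitted stack, the longest diameter is $\max_i 2a_i$ and the
shortest $\min_i 2b_i$ (ties to the lowest slice index), connecting the
volumetric estimate to the one-dimensional lesion measurement that
RECIST 1.1 bases response assessment on.

## Comparison metrics

For a predicted mask $P$ and reference $G$ on the same lattice, with
voxel counts $TP$, $FP$, $FN$:

* $\mathrm{DSC} = 2TP/(2TP+FP+FN)$ and
  $\mathrm{CI} = |A \cap B|/|A \cup B|$ (Jaccard), linked by the exact
  identity $\mathrm{DSC} = 2\,\mathrm{CI}/(1+\mathrm{CI})$;
* $\mathrm{DI}(A\text{ in }B) = |A \cap B|/|A|$ in both directions —
  $1-\mathrm{DI}(P\text{ in }G)$ is the fraction of the plan that would
  be unnecessarily irradiated, $1-\mathrm{DI}(G\text{ in }P)$ the
  fraction of tumor it would miss;
* Hausdorff distance (full max-of-max, not a percentile variant) and
  symmetrized mean surface distance over surface voxel centers in mm;
* the signed center-of-mass displacement (predicted minus reference)
  decomposed into left-right / anterior-posterior / cranial-caudal
  components, and its norm, the motion vector
  $\mathrm{MV} = \sqrt{LR^2+AP^2+CC^2}$.

The surface of a mask is defined as the foreground voxels with at
least one background face-neighbor (6-neighborhood, out-of-lattice =
background). This is deterministic, resolution-native and standard in
segmentation evaluation; no sub-voxel meshing is attempted, so reported
HD/MSD are voxel-center distances. Degenerate inputs (empty reference,
both masks empty) raise errors rather than silently contributing zeros
to cohort tables; an empty *prediction* yields a flagged report with
overlap 0 and undefined distances.

The canonical frame is fixed as lattice axis 1 = x (left-right), axis 2
= y (anterior-posterior), axis 3 = z (cranial-caudal), with voxel
centers at $(\text{index}-1)\times\text{spacing}$ mm. Files whose NIfTI
header carries a usable orientation are reoriented to RAS at load;
signed displacement conventions are therefore unambiguous.

## Cohort statistics

Over many pairs the package reproduces the standard assessment layer:
Pearson correlation with $R^2$ and a two-sided $p$ from the $t$
distribution on $n-2$ df; paired $t$-tests (predicted vs reference
GTV, and between the two DI directions); one-sample $t$-tests of the
signed LR/AP/CC displacements against 0; M ± SD and quartile
summaries (sample SD with the $n-1$ denominator; quartiles by linear
interpolation of order statistics, `quantile()` type 7 — a fixed,
documented convention rather than bit-compatibility with any
particular statistics product); and an OLS calibration line of
predicted on reference GTV, inverted algebraically to recover the
reference volume from a new prediction. All tests are two-sided.
Zero-variance inputs raise errors; in cohort reports such statistics
carry an explicit error note instead of a number.

## Synthetic phantoms

The generators emulate the geometry of axial CT acquisitions: default
spacing $(0.98, 0.98, 5)$ mm, lesions spanning 3–15 slices, per-slice
elliptical cross-sections with gradual taper, orientation drift and
centerline wander. Rasterization is by center inclusion (a voxel is
foreground iff its center lies inside the analytic solid), which is
unbiased to first order in the spacing; every phantom carries its exact
analytic geometry (volume, per-slice areas) in metadata so tests can
compare against closed forms. Prediction error is emulated by
`perturbMask()`: an integer-voxel translation, optional 6-neighborhood
dilation/erosion, and independent boundary flips. Flips act on both the
inner surface (foreground boundary voxels dropped) and the outer shell
(background face-neighbors added) so that perturbed cohorts exercise
false positives and false negatives — and hence both DI directions —
rather than only eroding. The default cohort error profile (in-plane
shifts up to 2 voxels, axial shift up to 1 slice, one
dilation/erosion step, flip rates up to 0.15) was chosen once as a
plausible stand-in for automatic-segmentation error at this slice
thickness.

What the phantoms deliberately do **not** model: image intensities and
noise, partial-volume effects at the delineation stage, inter-observer
variability, respiratory motion, and non-convex or branching lesions.
Passing tests therefore demonstrate the correctness of the estimators
and metrics as mathematical operations on masks — not the clinical
accuracy of any segmentation pipeline that produces the masks.

All generators draw from a private, explicitly seeded RNG stream and
restore the caller's RNG state; cohorts are byte-identical across
reruns with the same seed, and manifests store paths relative to
themselves so a cohort directory is relocatable.

## Numerical choices and edge cases

* The near-circular singularity ($(A-B)^2 + 4H^2 \to 0$) bypasses the
  angle computation and reports $\varphi_1 = 0$; the cutoff is
  $10^{-12}(A+B)$, far below discretisation noise.
* `frustumVolume()` rejects negative half-axes and non-positive $h$;
  it is monotone in every argument (a property test guards this).
* Surface-distance computation uses a blockwise vectorised
  nearest-point search; tests verify exact agreement (to $10^{-10}$ mm)
  with an all-pairs brute-force oracle.
* Multiple connected components within one slice are pooled into a
  single point-mass system (the formulation's "system of N mass
  points") with a warning, since per-component fitting would change
  the estimator.
* Problem sizes in the test suite and acceptance script — 164-patient
  synthetic cohorts on 96×96 in-plane lattices, 20-pair oracle
  comparisons, 200-seed calibration-recovery sweeps — were chosen so
  the full suite completes in a couple of minutes on one CPU while
  keeping every cohort-level statistic at the sample sizes the
  assessment layer is designed for.

## Known limitations

* DICOM / DICOM-RT structure sets are not parsed; masks are exchanged
  as NIfTI-1. 2-D slices read as single-slice volumes.
* The frustum integral does not extrapolate beyond the outermost slice
  centers, so it systematically loses the apical/basal caps of smooth
  lesions; on rasterized ellipsoids with at least 10 slices and 10 px
  in-plane half-axes the net error stays within 8%.
* Half-axis recovery degrades below ~10 px short half-axis — lesions a
  few pixels wide are better served by the voxel baseline, and the
  `degenerate` flag marks fits that should not be trusted.
* HD/MSD are voxel-center distances; sub-voxel surface positioning
  would require meshing, which is out of scope.
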