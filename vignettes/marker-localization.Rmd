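---
title: "Localizing two-sphere fiducial markers in MRI volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing two-sphere fiducial markers in MRI volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stereotactic neurosurgery and multi-modal image registration need landmark
points whose positions — and, for bone anchors, orientations — can be read
from MRI volumes automatically. A fiducial marker made of **two bright
spheres** (radius 3.5 mm) held by a dark cylindrical housing at a fixed
centre-to-centre distance of **11 mm** provides both: the two sphere
centroids give a position (their midpoint) and an axis direction (their
difference vector), in any spatial orientation, without X-ray imaging.

`sphereloc` implements four independent detectors for the sphere centroids,
the two-sphere *marker model* that pairs detections and discards solitary
false positives, a synthetic phantom generator with exact continuous ground
truth, and the evaluation metrics used to compare the detectors.

The pipeline is always the same three steps:

1. **Load / pre-process** — read the volume (NIfTI), resample to isotropic
   voxels when the detector needs it (`resample_isotropic()`, trilinear).
2. **Localize** — one of `detect_spheres_hough()`, `detect_spheres_kernel()`,
   `detect_spheres_cca()`, `detect_spheres_blob()`.
3. **Marker model** — `pair_spheres()`: greedy pairing of candidates whose
   mutual distance lies in the corridor 11 ± 1 mm, then `marker_pose()`.

The only parameters a user must supply are the sphere radius and the marker
spacing; everything else adapts to the voxel size or has defaults validated
on phantoms.

## The four detectors

### Bidirectional circular Hough transform (`hough`)

Spheres appear as circles in every slice direction. Slices perpendicular to
two orthogonal axes are processed independently with a gradient-limited 2D
circular Hough transform: a first-order derivative of Gaussian estimates edge
magnitude and direction; pixels above the 95th percentile of the nonzero
magnitudes vote along their gradient direction ± 0.35 rad, inward and
outward, for the radii `{r/s − 1, r/s, r/s + 1}` voxels (the physical radius
is known a priori, so the radius dimension of the parameter space collapses
into one 2D accumulator). Per-slice accumulators are stacked into 3D, each
stack normalized to [0, 1], and the two stacks blended by **elementwise
multiplication**: an object circular in only one slicing direction (a
cylinder, a tube) is attenuated, a sphere is reinforced. Peaks are local
maxima above `threshold_rel = 0.3` of the accumulator maximum, at least one
sphere diameter apart.

Because votes land on a discrete raster, the raw argmax is frequently one
voxel off the circle centre; the blended accumulator is therefore smoothed
with a 0.6-voxel Gaussian before peak picking (`acc_smooth_vox`). Without
this, the pair-spacing error of two snapped endpoints occasionally leaves the
±1 mm corridor and a true marker is lost at coarse voxel sizes — the same
post-pairing F1 degradation the Hough approach shows on real data.

### Spherical matched-kernel convolution (`kernel`)

The volume is normalized to mean 0, sd 1 (making detection invariant to
affine intensity rescaling), then convolved (valid region, Eq. form
`I*(i,j,k) = Σ F(u,v,w) I(i−u, j−v, k−w)`) with a two-valued kernel: inside
elements (centres within `radius_mm` of the kernel centre) get `kin = 1`,
outside elements get

\[ k_{out}(s_v) = -0.5 - \frac{1}{1 + e^{-c\,(1 - s_v)}}, \qquad c = 3, \]

a logistic in the voxel size with range (−1.5, −0.5) and value −1 at 1 mm.
Coarser voxels mix sphere and housing intensities at the border, so the
penalty on the surroundings is weakened as `s_v` grows. The kernel half-size
is `floor(radius_mm / spacing)` per axis (7×7×7 for a 3.5 mm sphere at 1 mm
isotropic voxels; cuboidal for anisotropic spacings). The response is
min–max rescaled to [0, 1] and peaks above `threshold_rel = 0.5` returned.

A note on the kernel geometry: restricting the inside ball to the half-size
extent (3.0 mm at 0.6 mm voxels) instead of the true 3.5 mm radius makes the
response flat under sub-voxel translation — the inner ball then fits strictly
inside the physical sphere, so the peak wanders about one voxel and the
median positioning error at 0.6 mm roughly doubles. The inside test therefore
uses the full physical radius.

### Connected-component analysis (`cca`)

Gaussian blur (σ = 1 mm, noise suppression) → unsharp mask (σ = one voxel,
gain 1; raises edge contrast and depresses the sphere surroundings) →
binarization at the **first threshold of the four-class Otsu method**
(exhaustive maximization of between-class variance; the first class is
background) → 6-connected component labelling → keep components with
equivalent radius within 35 % of `radius_mm` **and** roundness ≥ 0.6 →
candidate positions are the component centroids, which are intensity-grid
averages and therefore *sub-voxel accurate* (median positioning error on
noise-free phantoms ≈ 0.01–0.1 mm, far below the voxel-snapping detectors).

**Roundness and the surface-area estimator.** Roundness is the ratio of the
surface area of the equal-volume sphere to the measured component surface
area; 1 for a perfect sphere, smaller for elongated shapes. We measure the
surface by counting exposed voxel faces (weighted by their physical areas).
This estimator is *exact* for axis-aligned boxes — a digitized cube scores
`(36π)^{1/3}/6 ≈ 0.806`, the analytic value, at every resolution — and it
overestimates smooth curved surfaces by a known stable factor (≈ 1.5 for
spheres), so digitized spheres sit on a plateau of ≈ 0.64–0.74 across the
whole 0.6–1.6 mm range. An iso-surface triangulation of the binary mask was
evaluated as an alternative: it scores spheres higher (≈ 0.91) but scores a
1×1×12-voxel rod at ≈ 0.83 and a cube at ≈ 0.83, i.e. it cannot separate
thin elongated clutter from small digitized spheres by any threshold. Local
estimators fundamentally cannot tell a thin-rod face from a 45° plane from a
2×2×2 neighbourhood. Face counting keeps the classes far apart — rods ≈ 0.51,
boxes ≈ 0.81, spheres ≈ 0.67 — and the `roundness_min = 0.6` default sits in
the gap below the sphere plateau.

The trade-off is that roundness is a
*ranking score calibrated to this estimator*, not an absolute sphericity on
[0, 1]: digitized spheres do **not** approach 1 with increasing resolution
under face counting (they oscillate mildly with digitization parity within
the plateau). The filter behaviour, which is what the pipeline needs, is
stable.

**Why the pre-blur width is physical (1 mm) rather than voxel-relative.**
A half-voxel blur leaves the background noise peak wide relative to the
histogram bins, and the four-class Otsu then finds it profitable to split
that peak — marking roughly half of the background as foreground speckle,
which percolates in 3D (site threshold ≈ 0.31) and can bridge a sphere into
the background component through the housing gap. One millimetre of
smoothing collapses the noise class below bin resolution at every voxel size
in range while staying well below the 2.5 mm housing gap, so nearby spheres
still do not merge.

### Determinant-of-Hessian blob detection (`blob`)

Each slice (perpendicular to one axis; the 2D character is retained
deliberately) is smoothed to the scale-space representation `L` at a single
characteristic scale index `t` and the scale-normalized response
`t² (L_xx L_yy − L_xy²)` computed with central differences. The blob
radius–scale relation used is `t = (r/s)²/2` (i.e. `r = σ√2` in voxel units);
the alternative printed relation `r = 2t` would give σ ≈ 1.3 voxels for a
3.5 mm sphere at sub-millimetre voxels, far too small to respond to the blob,
and is dimensionally inconsistent with `t = σ²`, so it is treated as a
typographical casualty (`scale_index` can override). All positive local
maxima within a marker-radius neighbourhood become candidates — deliberately
permissive (hundreds to thousands on textured data). An in-plane border of
about σ voxels of the response is blanked: central differences are undefined
at the array boundary and replicate padding would fabricate maxima there.

Candidates are then described by the **normalized second-order central
moments** of the raw intensity in a marker-radius-sized cubic neighbourhood
(6 unique components of the symmetric 3×3 matrix; for a uniform solid sphere
of radius R the matrix tends to `(R²/5) I`, trace `3R²/5 = 7.35 mm²` at
R = 3.5). K-means classifies the descriptors **by their size** (the trace)
for k = 1..8; the knee of the inertia-vs-k curve (maximum distance to the
chord between its endpoints) selects k, and the cluster whose mean size is
closest to the analytic sphere trace is kept. Clustering on the size rather
than on the full 6-dimensional vectors is what separates the extremely tight
sphere cluster from anisotropic clutter of similar magnitude; in the 6-D
space the knee-selected k merges them. Residual false positives are removed
by the marker model downstream — and on noisy data many remain, which is the
known weakness of the slice-wise blob approach (structures that look
circular in a single slice direction).

## The marker model

`pair_spheres()` walks candidates in descending detection-score order and
pairs each with the remaining candidate whose distance is inside
`spacing ± tol` (defaults 11 ± 1 mm) and closest to the nominal spacing;
paired candidates leave the pool, leftovers are reported unpaired and count
as discarded false positives. The corridor does not vary with voxel size.
The marker position is the centroid midpoint; the direction is the unit
difference vector, defined only up to sign because the two spheres are
constructively identical (the CLI reports the representative whose
largest-magnitude component is positive).

Two consequences worth noting:

* Detectors that report voxel centres (hough, kernel, blob) carry a
  worst-case half-voxel-per-axis quantization, i.e. a positioning-error
  floor of `√3/2·s ≈ 0.86 s`. At `s` ≥ 1.2 mm the induced spacing error can
  leave the ±1 mm corridor, so the marker model can *lose* true markers at
  coarse resolutions — visible in `run_sweep()` output as F1 after the model
  dropping below F1 before it.
* A worst-case orientation error bound follows from displacing both sphere
  centroids by the positioning error orthogonally to the true axis in
  opposite senses: `atan(2·Ep / 11)` (`orientation_error_bound()`, single
  endpoint variant via `both_endpoints = FALSE`).

## The synthetic phantom

Real cadaver-head acquisitions are not distributable, so `generate_phantom()`
emulates their geometry: an 80 mm cube (default 0.6–1.6 mm isotropic voxels)
containing a bright ellipsoidal "head" (semi-axes 18, 20, 22 mm, intensity
0.5), and five markers placed at seeded-random positions on the head surface,
stood off 12.5 mm along the outward direction, each with a uniformly random
axis orientation — two spheres (radius 3.5 mm, intensity 1.0) exactly 11 mm
apart inside a dark spherical housing shell (thickness 2.5 mm). Spheres and
head are rendered with partial-volume blending (3³ subsampling of boundary
voxels), because binary voxelization would make sub-voxel centroid accuracy
artificially easy. Additive Gaussian noise (default sd 0.02 against a sphere
contrast of ≈ 1) models measurement noise; Rician noise is not modelled.
Ground-truth centres are continuous positions, never snapped to the grid, so
the quantization floor of voxel-snapping detectors is genuinely exercised.
Placement enforces ≥ 12.5 mm between spheres of different markers, keeping
greedy pairing unambiguous by construction.

The housing shell intensity defaults to the background intensity: the
housing material gives no MR signal, so in a realistic acquisition it is as
dark as air. This matters for the CCA detector: a housing rendered as its own
distinctly-valued population would form a separate histogram class, the
four-class Otsu would place its *first* threshold between background and
housing, and the binarization would merge every sphere with its housing —
a failure mode no real acquisition produces.

What phantom results do **not** show: robustness to anatomy-like texture,
bias fields, T1/T2 contrast differences (emulated only through intensity
parameters), Rician noise floors, or marker housings touching bright scalp
fat. Phantom recall of 1.0 is a necessary, not sufficient, condition.

## Evaluation

`match_to_ground_truth()` matches detections to true centres one-to-one,
greedily by ascending distance, within a 14 mm threshold (the published
value; it exceeds the 11 mm pair spacing, which the one-to-one
ascending-distance matching mitigates). `f1_score()` is
`tp / (tp + (fp+fn)/2)`, computed before (`f1_bm`) and after (`f1_am`) the
marker model by `evaluate_detections()`. Positioning error `Ep` is the
matched Euclidean distance; spacing error `Es = |d − 11|` is ground-truth
independent and only defined for complete markers. `detection_benchmark()`
ships the published cadaver-head counts (2 modalities × 6 voxel sizes × 4
methods); the F1-before-model column is reproducible from the counts, and
the largest published F1 gain from the marker model is 2.1×.

## Numerical and design choices

* **Problem sizes.** Tests and the acceptance script use 80 mm phantoms at
  0.6–1.6 mm voxels (≈ 0.13–2.4 M voxels), five markers each — the full
  study geometry per volume, sized so the whole suite runs in well under a
  minute per detector.
* **Local maxima** (`find_local_maxima()`): Euclidean mm neighbourhoods;
  plateau ties resolve to the smallest linear index; greedy suppression in
  decreasing-value order. Verified against an exhaustive scan.
* **Otsu**: exhaustive search over all threshold placements (≤ 4 classes,
  256 bins), implemented directly from the between-class-variance objective
  and cross-checked against an independent `combn` enumeration.
* **Resampling**: trilinear; the method is an implementation choice (no
  interpolation scheme is prescribed for intensity MRI at these scales).
* **Slice axes for the Hough stacks**: axes 1 and 2 by default, configurable
  (`axes`); which two of the three orthogonal stacks the original pipeline
  used is not documented.
* **Determinism**: every stochastic step (phantom placement, noise, k-means
  restarts) is seeded; identical inputs give bit-identical outputs.
* **Degenerate inputs**: constant volumes raise a degenerate-input error in
  `normalize_intensity()` (kernel method) and yield empty candidate lists in
  CCA (no foreground) and blob (no positive response); spheres rendered
  fully outside the grid warn and leave the volume unchanged.

## Known limitations

* The blob detector inherits the 2D slicing weakness: tube-like structures
  and noise maxima produce large false-positive counts on textured data
  (hundreds before the marker model), consistent with the published
  behaviour of the approach.
* Roundness values are estimator-calibrated rankings (see above), not
  absolute sphericities.
* Direction signs are reported up to the canonical representative; nothing
  in the marker design distinguishes the anchor-side sphere.
* The matching threshold default of 14 mm follows the published value even
  though it exceeds the pair spacing; pass `match_threshold` to tighten it.
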