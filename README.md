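# sphereloc

Automatic localization of spherical fiducial markers in 3D MRI volumes.

## The problem

Point-based registration and stereotactic planning need landmarks that can be
extracted from MRI automatically. A two-sphere fiducial marker — two bright
spheres of radius *r* = 3.5 mm held 11 mm apart by a dark housing screwed onto
a cranial bone anchor — encodes both a **position** (the midpoint of the two
sphere centroids) and a **direction** (the unit vector between them), in any
orientation and without additional X-ray imaging.

`sphereloc` implements and compares four detectors for the sphere centroids:

| method  | idea |
|---------|------|
| `hough` | bidirectional slice-wise circular Hough transform; two orthogonal slice stacks vote for circle centres, per-stack 3D accumulators are blended by multiplication so only objects circular in *both* directions (spheres) survive |
| `kernel`| valid-region 3D convolution with a two-valued spherical kernel: inside weight k<sub>in</sub> = 1, outside weight k<sub>out</sub>(s<sub>v</sub>) = −0.5 − 1/(1+e<sup>−3(1−s<sub>v</sub>)</sup>) ∈ (−1.5, −0.5), on the intensity-normalized (μ = 0, σ = 1) volume |
| `cca`   | Gaussian blur → unsharp mask → four-class Otsu (first cut = background) → 6-connected component labelling → radius + roundness filter → sub-voxel centroids |
| `blob`  | slice-wise determinant-of-Hessian t²(L<sub>xx</sub>L<sub>yy</sub> − L<sub>xy</sub>²) at the single scale t = (r/s)²/2, then second-order moment descriptors clustered by k-means (knee-selected k) against the analytic solid-sphere trace 3r²/5 |

All four feed the **marker model**: greedy pairing of candidates whose mutual
distance lies within 11 ± 1 mm; solitary candidates are discarded as false
positives, and each pair yields the marker pose. Evaluation follows the
standard metrics: F1 = tp/(tp + (fp+fn)/2) before/after the marker model,
positioning error E<sub>p</sub> (distance to ground truth), spacing error
E<sub>s</sub> = |d − 11| and the voxel-grid resolution limit √3/2·s ≈ 0.86·s.

A seeded synthetic phantom generator (`generate_phantom()`) renders a
head-shaped volume with five markers in random orientation, partial-volume
sphere edges, additive noise and exact (continuous, never grid-snapped)
ground truth, for validation across voxel sizes 0.6–1.6 mm.

## Worked example

```r
library(sphereloc)

ph  <- generate_phantom(phantom_spec(voxel_size = 1.0, noise_sd = 0.02, seed = 7))
res <- run_pipeline(ph$volume, pipeline_config("cca", verbose = TRUE))
#> [cca] 10 candidates -> 5 markers (0 unpaired)
round(res$markers[, c("px", "py", "pz", "dx", "dy", "dz", "spacing_mm")], 2)
#>      px    py    pz    dx    dy    dz spacing_mm
#> 1 63.89 42.98 59.75  0.45 -0.84 -0.29      10.96
#> 2 39.37 64.87 61.03  0.34  0.64 -0.69      11.00
#> 3 42.86 70.71 30.71  0.00  0.21  0.98      11.02
#> 4 66.08 25.60 31.45  0.29  0.69  0.67      11.04
#> 5 15.51 59.28 42.53 -0.11 -0.59 -0.80      10.97

ev <- evaluate_detections(res$candidates, ph$truth)
sprintf("recall %.2f  F1(bm) %.2f  F1(am) %.2f  median Ep %.3f mm  median Es %.3f mm",
        ev$recall, ev$f1_bm, ev$f1_am, median(ev$ep_mm), median(ev$es_mm))
#> "recall 1.00  F1(bm) 1.00  F1(am) 1.00  median Ep 0.030 mm  median Es 0.030 mm"
```

Each row of `markers` is one recovered fiducial: `px, py, pz` its position in
mm, `dx, dy, dz` its unit axis (defined up to sign), `spacing_mm` the measured
sphere-to-sphere distance. On this 1 mm phantom the CCA detector finds all 10
spheres (recall 1.00), the marker model keeps exactly the 5 true pairs, the
median centroid error is 0.03 mm (intensity centroids are sub-voxel accurate)
and every measured spacing is within 0.04 mm of the constructive 11 mm.

`run_sweep()` reproduces the comparative experiment on phantoms — methods ×
voxel sizes × noise levels, one evaluation row per cell —
and `detection_benchmark()` ships the published cadaver-head counts for the
worked-example F1 checks.

There is also a small command-line front end:

```sh
Rscript inst/cli/sphereloc generate --voxel-size 1 --noise-sd 0.02 --seed 7 \
    --out vol.nii.gz --truth truth.json
Rscript inst/cli/sphereloc run --method cca --in vol.nii.gz \
    --radius-mm 3.5 --spacing-mm 11 --out markers.json
Rscript inst/cli/sphereloc evaluate --candidates cand.json --truth truth.json \
    --out metrics.json
```

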