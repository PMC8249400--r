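# orbitseg — coarse-to-fine segmentation of the bony orbit in CT and MRI volumes

The bony orbit (eye socket) appears in coronal slices of a head CT or MRI
scan as a closed, roughly circular contour that shrinks and turns
triangular toward the back of the eye. Manual delineation takes from half
an hour (CT) to hours (MRI) per scan; `orbitseg` implements a fully
automatic three-stage pipeline for it, aimed at image-analysis researchers
and method developers who need a trainable, end-to-end testable
implementation:

1. **Global localization** — a compact U-Net (with batch normalization in
   every encoder/decoder block and dropout at the bottleneck) segments the
   orbit region on the half-image; the output is binarized, holes are
   filled, the largest connected component is kept, and its centroid
   proposes the orbit center for a fixed 128 × 128 region of interest.
2. **Local boundary probability** — a second, independently trained U-Net
   maps the ROI to a per-pixel probability of lying on the bone/cavity
   interface (a bright ring).
3. **Closed-contour extraction** — the ROI map is unwrapped into polar
   coordinates about the proposed center, padded with two near-zero-weight
   columns per side, and the contour is found as the minimum-weight
   corner-to-corner Dijkstra path under 4-connectivity with edge weights

   W(a, b) = 2 − (P_a + P_b),

   where P is the boundary probability; the path is mapped back to a
   closed Cartesian contour and filled region mask.

Volume-level post-processing replaces each slice by the 2-of-3 pixel vote
with its neighbours (omitting the unsupported first/last slices), and
k-fold cross-validation models can be combined by strict-majority voting.
Evaluation covers two-class Dice (per slice and pooled volumetrically),
centroid error, boundary mean absolute error, and Hausdorff distance, in
pixels and millimetres.

Since clinical orbit datasets are generally private, the package includes
a seeded phantom generator producing CT-like and MRI-like coronal stacks
with exactly known ground truth (monotonically tapering cross-sections
that blend from circles to rounded triangles posteriorly, a bright
high-contrast bone ring for CT, a textured low-contrast ring for MRI), on
which the entire pipeline is trained and evaluated. The small U-Net and
its Adam / SGD-momentum training loops are implemented in the package
itself (a compiled single-precision backend with a pure-R reference
implementation verified by finite-difference gradient checks).

## Worked example

Generate a CT-like phantom, build a boundary probability map from its
ground truth (standing in for a trained stage-2 network), and extract the
closed contour by polar graph search:

```r
library(orbitseg)

params <- phantom_params("ct", n_slices = 9, medial_radius = 20,
                         taper = 0.9, seed = 7)
vol <- generate_volume(params)
vol
#> <phantom_volume> ct-like, 9 slices of 128 x 128 px, 0.5 mm isotropic
#>   medial radius 20.0 px, taper 0.90, triangularity 0.60, seed 7

vapply(vol$region_masks, sum, 0)   # cross-section area peaks medially
#> [1]  247  351  508  784 1255  781  510  351  243

s <- 7                             # a posterior, triangular slice
rr <- matrix(rep(1:128, 128), 128); cc <- t(rr)
d2 <- matrix(Inf, 128, 128)
for (k in seq_len(nrow(vol$contours[[s]]))) {
  d2 <- pmin(d2, (rr - vol$contours[[s]][k, 1])^2 + (cc - vol$contours[[s]][k, 2])^2)
}
prob <- exp(-d2 / (2 * 1.5^2))     # blurred ring around the true boundary

eb <- extract_boundary(prob, vol$centers[s, ])
dice(eb$mask, vol$region_masks[[s]])
#> 0.983
boundary_mae(eb$contour, vol$contours[[s]])   # px
#> 0.25
hausdorff_distance(eb$contour, vol$contours[[s]])   # px
#> 0.79
```

The filled region recovered from the rounded-triangle slice overlaps the
truth at Dice 0.98 with sub-pixel boundary error — the graph search
follows non-circular rings without a shape template.

The full experiment — phantom cohort, subject-level folds, two-stage
training, ensemble segmentation of held-out subjects, evaluation table
(fold rows, fold mean, ensemble) — is one call:

```r
ex <- run_all(pipeline_config("ct", profile = "desk", seed = 2024))
ex$table   # volumetric/per-slice Dice, centroid error, MAE, Hausdorff
```

The desk profile (depth-3/8-filter networks, 30/60 epochs, 2 folds, 8
subjects of 5 slices at 128 × 128) runs in a few minutes on one CPU; the
`"full"` profile carries the clinical-scale settings (352 × 512 slices,
depth-4/64-filter networks, 100/500 epochs, k = 6). A thin command-line
wrapper with `simulate`, `run-all`, `segment` and `evaluate` subcommands
is in `inst/cli/orbitseg.R`.

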