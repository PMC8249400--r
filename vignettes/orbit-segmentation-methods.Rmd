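---
title: "Coarse-to-fine segmentation of the bony orbit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine segmentation of the bony orbit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(orbitseg)
```

## The problem

The bony orbit is the skull cavity that houses the eyeball. In coronal
slices of a head CT or MRI volume its inner surface appears as a closed,
roughly circular contour that shrinks and becomes triangular towards the
back of the eye. Delineating this contour slice by slice is the basis for
orbital volumetry, trauma assessment and the design of patient-specific
reconstruction implants, but doing it by hand takes from half an hour (CT)
to several hours (MRI) per scan. `orbitseg` implements a fully automatic
three-stage pipeline for this task, together with everything needed to
train and evaluate it end to end on synthetic data with exactly known
ground truth.

## The three stages

**Stage 1 — global localization.** A compact U-Net segments the filled
orbit region on the half-image that contains the orbit of interest. Its
output map is binarized at 0.5 (the two-class argmax), holes are filled
(background regions not 4-connected to the border), all but the largest
8-connected component is discarded, and the component centroid becomes the
proposed orbit center. A fixed 128 x 128 pixel region of interest (ROI) is
cropped around that center, shifted where necessary so it stays inside the
slice. If a slice yields no foreground at all, the center of the nearest
successfully localized slice in the stack is reused.

**Stage 2 — local boundary probability.** A second U-Net of the same
architecture, trained independently, maps the ROI to a per-pixel
probability of lying on the bone/cavity interface. Its ideal output is a
bright ring. No post-processing is applied to this map in single-fold
mode; in ensemble mode the k fold models' maps are binarized at 0.5 and
majority voted (strict majority, at least `ceiling((k+1)/2)` votes).

**Stage 3 — closed-contour extraction.** The ROI map is resampled into
polar coordinates about the proposed center (radius on one axis, angle on
the other), which turns the ring into a near-horizontal band. Two columns
of near-probability-1 padding are appended on each side, and the contour
is found as the minimum-weight path from the top-left to the bottom-right
corner under 4-connectivity, with edge weights

$$W_{ab} = 2 - (P_a + P_b),$$

where $P_a$ and $P_b$ are the boundary probabilities of the two adjacent
nodes. Weights lie in [0, 2] and vanish exactly where both pixels are
certainly boundary, so Dijkstra's algorithm follows the band; the padded
columns let the path enter and leave the band cheaply regardless of where
the corners sit. Diagonal moves are excluded because they let the radius
drift along the path. The path is collapsed to one radius per angle column
(where the path visits a column at several radii, the radius at which it
exits rightward is kept), padding is stripped, and the inverse polar map
yields a closed Cartesian contour plus its filled region mask.

**Volume post-processing.** Each slice mask is replaced by the pixel-wise
2-of-3 majority of itself and its two neighbours; the first and last
slices, which lack a neighbour, are omitted from analysis. Because the
orbit cross-section shrinks monotonically away from the medial slice, this
removes isolated outliers without distorting consistent stacks.

## The U-Net and its training recipes

Both stages use the same encoder–decoder architecture: per encoder level
two 3 x 3 convolutions, each followed by batch normalization and ReLU, then
2 x 2 max pooling; a bottleneck with dropout; per decoder level a learned
2 x 2 transposed-convolution upsampling, concatenation with the encoder
skip feature, and two conv+BN+ReLU pairs; a final 1 x 1 convolution with a
two-class softmax. Being fully convolutional, one network runs on any
input whose sides are divisible by $2^\text{depth}$.

Training uses per-pixel cross-entropy, shuffling each epoch, on-the-fly
augmentation (horizontal reflection with probability 0.5 and rotation by an
angle uniform in ±10°, identical for image and label), and keeps the epoch
with the best validation pixel accuracy:

| stage | optimizer | learning rate | epochs (full / desk) | batch |
|---|---|---|---|---|
| 1 (region) | Adam | 0.001, constant | 100 / 30 | 128 / 2 |
| 2 (boundary) | SGD + momentum 0.9 | 0.01, constant | 500 / 60 | 128 / 2 |

Two decisions here were genuinely open:

* **Checkpoint tie-breaking.** The recipe says "the epoch with best
  validation accuracy" but not what to do on ties. With a boundary class
  occupying ~2 % of pixels, validation pixel accuracy can sit exactly at
  the all-background plateau for many epochs even while the loss falls and
  the predicted probabilities sharpen below the 0.5 threshold. Ties are
  therefore resolved toward the **later** epoch: among equally accurate
  checkpoints the longer-trained weights are kept. With first-of-ties
  selection a plateaued fold can checkpoint a nearly untrained network.
* **Boundary label thickness.** The stage-2 truth is the region outline,
  a curve rather than a filled shape. The default rasterization is 3 px
  thick (`boundary_px = 3`): a 1 px ring at desk scale is ~0.8 % of pixels
  and plain cross-entropy reliably collapses to the background class,
  while at 3 px the class remains learnable and the graph search still
  extracts a single-pixel path. A 1 px label is available via
  `boundary_px = 1`.

Other unspecified architecture constants (depth 4 / 64 base filters in the
full profile, dropout 0.5, momentum 0.9) follow the standard U-Net and
conventional defaults; the desk profile uses depth 3 / 8 filters.

The implementation carries two numerically equivalent backends: a compiled
single-precision path (RcppArmadillo; im2col convolutions over BLAS sgemm,
one call per mini-batch) used for all real work, and a pure-R
double-precision reference used to verify the compiled path. The analytic
gradients of the reference are checked against central finite differences
in the test suite, and the two backends are asserted to agree to
single-precision tolerance. Training is deterministic for a fixed seed on
a fixed machine.

## The phantom generator

Clinical orbit datasets are generally not redistributable, so the package
generates its own study material. A phantom subject is a coronal stack in
which the orbit cross-section is a star-shaped region

$$r(\theta) = r_s \, \frac{1 + g\,t_s \cos 3\theta}{1 + g\,t_s},$$

with per-slice maximal radius $r_s = r_\text{medial} \cdot
\text{taper}^{|s - s_\text{medial}|}$ and triangularity blend $t_s$ growing
linearly from 0 at the medial slice to 1 at the stack ends. This is the
simplest closed-form family that reproduces the two qualitative anatomical
priors the pipeline relies on: cross-sections shrink monotonically away
from the medial slice, and small posterior cross-sections become rounded
triangles. Every slice contains the orbit as a single closed contour; one
orbit sits in the left half-image (matching the half-image crop of the
preprocessing); voxels are 0.5 mm isotropic (stored as metadata).

Intensity styles:

* **CT-like** — uniform background (0.10), cavity (0.30) and a bright bone
  ring (0.90), light Gaussian noise (sd 0.02), and a sparse fraction
  (0.2 %) of extreme-valued outlier pixels that exercise the 1 %/99 %
  percentile saturation step of the CT preprocessing path.
* **MRI-like** — the same geometry at much lower contrast (0.32 / 0.42 /
  0.62) under a smooth multiplicative field and stronger noise (sd 0.05),
  emulating tissue texture and coil inhomogeneity.

The CT style has more than twice the MRI ring/background Michelson
contrast, so the phantom cohort reproduces the qualitative modality
ordering (CT easier than MRI) without claiming anatomical fidelity: the
generator makes no statement about real orbit diameters, skull context,
fractures, or the open orbital entrance, and results on phantoms
demonstrate that the pipeline machinery works, not that it meets clinical
accuracy on patient data.

Ground truth (region mask, ordered boundary contour, center) is computed
analytically per slice and is noise-free by construction; the contour is
exactly the 8-connected outline of the mask and refills to it.

## Preprocessing conventions

* Min–max normalization to [0, 1] per network input; a constant image maps
  to all zeros with a warning rather than failing on the zero range.
* CT inputs to the **global** network are first saturated at the 1st and
  99th intensity percentiles. Percentiles are order statistics (type-1
  quantiles), which makes the operation exactly idempotent; saturation is
  per slice, matching per-image input construction. Whether the local
  network input should also be saturated is ambiguous in the source
  recipe; the default here is global-only, with `saturate_stage2 = TRUE`
  to extend it.
* Resampling to 0.5 mm isotropic in-plane spacing uses bilinear
  interpolation for intensities and nearest-neighbour for masks.
* Rotation augmentation interpolates bilinearly (intensities) /
  nearest-neighbour (masks) about the image center and fills the border
  with the image minimum, so no spurious bright edges are created.

## Graph-search parameters

* Polar resolution: 360 angle bins and ~1 px radial bins up to the ROI
  half-diagonal (`64*sqrt(2) ≈ 91` px for the 128 px ROI), i.e. at most
  ~1 px arc length per bin at the largest radius.
* Padding: 2 columns per side at probability $1 - 10^{-5}$; edges inside
  the padding weigh $2\times10^{-5}$, near zero yet strictly positive so
  non-negativity is never in question.
* The two ends of the angle axis are deliberately **not** connected; the
  padding mechanism replaces angular wrap-around, and closure is imposed
  only when the Cartesian contour is re-formed.
* Degenerate inputs: an all-zero map still yields the minimum-cost path
  (a contour), flagged `low_confidence` when the mean on-path probability
  falls below 0.2.

## Evaluation metrics

Per slice and pooled over the volume: two-class Dice
$2T_P/(2T_P + F_P + F_N)$ for orbit and background (evaluated within the
128 x 128 ROI actually extracted); the volumetric Dice pools the confusion
counts over slices and is *not* the mean of per-slice values. Centroid
error is the Euclidean distance between predicted and true centers (px).
Boundary error is the mean over truth contour points of the distance to
the nearest predicted point (directed truth→prediction by default, which
is stable under differing contour sampling densities; a symmetric variant
is available). The Hausdorff distance is symmetric. Millimetre values are
pixel values times the 0.5 mm spacing. Two edge conventions: Dice of two
empty masks is 1 (flagged), empty-vs-nonempty is 0; slices whose predicted
segmentation is empty keep their overlap scores but have undefined
distances, which are excluded from means and counted in
`n_failed_slices`.

## Problem sizes used by the tests and the acceptance script

The shipped experiments run the desk profile: per modality 8 phantom
subjects of 5 slices at 128 x 128 px (6 in the cross-validation pool, used
as 2 folds of 5 training / 1 validation subjects; 2 fixed test subjects),
depth-3 / 8-filter networks, 30 stage-1 and 60 stage-2 epochs, mini-batch
2 (with ~25 training slices the short desk schedules need the extra
gradient updates per epoch to converge; the full profile keeps the
recipe's mini-batch of 128). These sizes were chosen once as the smallest configuration on which
the full pipeline — both training stages, fold ensembling, graph search,
slice voting and all metrics — is exercised meaningfully; the full
clinical-scale profile (352 x 512 slices, depth-4 / 64-filter networks,
100 / 500 epochs, k = 6) is configured but not run routinely.

## Known limitations

* Phantoms are geometric idealizations: no skull context, no neighbouring
  orbit in the other half-image beyond the crop convention, no fractures,
  no open orbital entrance, no partial-volume effects. Passing tests on
  phantoms validates the machinery, not clinical accuracy.
* The polar graph search assumes the region is star-shaped about the
  proposed center; strongly non-convex cross-sections would need a
  different path topology.
* The 2-of-3 slice vote intentionally suppresses single-slice deviations;
  at the medial slice (a local maximum of cross-section area) it replaces
  the slice by its larger neighbour, a bias that is negligible only when
  adjacent slices differ little — the realistic regime for 0.5 mm-spaced
  anatomy.
* With k = 2 folds the "strict majority" ensemble is an intersection of
  the folds' 0.5-binarized maps, which is doubly demanding: a fold whose
  network ranks boundary pixels correctly but stays under-confident
  (probabilities below 0.5 everywhere — a calibration state the shortened
  desk schedules can end in) vetoes every pixel, and the voted map can be
  empty even though both folds segment well on their own through the
  graph search, which consumes the continuous map. At k = 6 with a 4-vote
  rule (the full profile, the intended operating point of majority
  voting) a weak fold is outvoted instead. Desk-scale headline numbers
  are therefore read from the fold-mean row; the ensemble row is always
  computed and reported alongside.
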