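---
title: "Bone suppression in pediatric chest radiographs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone suppression in pediatric chest radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribsep)
```

## The problem and the model

A chest radiograph is a planar projection: bone and soft tissue overlap in
every pixel.  `ribsep` decomposes a radiograph `I` into a bone image `I_B`
and a soft-tissue image `I_S` under the additive model

    I = I_B + I_S,

which holds for log-transformed attenuation and is the model under which
dual-energy subtraction hardware produces its two images.  The package
implements a traditional (non-learned) decomposition pipeline built around
PCA-based blind source separation, desk-scale training scaffolding for the
learned edge-detection and suppression networks that replace the manual
steps, the evaluation metrics customary in this literature, and a synthetic
phantom generator that provides exact ground truth.

The traditional pipeline works bone by bone:

1. **Edge handling.**  Binary bone-edge masks are encoded for regression as
   soft distance-transform images `exp(-d / |sigma|)` (`sigma = 5` by
   default) and decoded by thresholding at 0.8 followed by morphological
   thinning.  Thresholding the encoding of a straight line at 0.8 with
   `sigma = 5` yields a band exactly 3 pixels wide, which is what makes 0.8
   a natural fixed decoding threshold.
2. **Edge lists.**  Skeleton pixels are classified by their count of
   positive 8-neighbours (free / connection / junction), walked into
   ordered polylines, merged across small gaps, and paired into upper/lower
   bone edges with a midpoint centerline.
3. **Profile sampling.**  For every upper-edge point `u` the opposite
   lower-edge point `l*` minimizes the parallelogram height
   `|det(e, v)|` (`e` the unit normal at `u`, `v` the vector to the
   candidate, search radius `max_dist`).  Forty samples span `u -> l*`
   inclusive and ten more extend outside the upper edge at the same step,
   so both edges land on fixed profile rows — the bone is straightened.
4. **PCA-based blind source separation.**  Per profile column the
   background is the straight line through the means of the `margin = 3`
   outermost samples at each end, then smoothed along the bone; 2-means
   clustering finds columns corrupted by crossing structures (other bones,
   catheters) and replaces them with the mean uncorrupted column; PCA over
   columns retains the minimal `r` components reaching 95% cumulative
   variance; a kernel-30 moving average smooths along the bone.
5. **Reconstruction.**  Profile estimates are scattered back (collisions
   averaged, interior holes filled from the nearest assigned pixel), summed
   over bones, background-corrected by solving the Poisson equation
   `lap(x) = lap(I_B0)` over the filled edge-polygon region with zero
   Dirichlet values outside — this pins every non-bone pixel of `I_B` to
   exactly 0 — and finally residual bone edges are re-suppressed with the
   same profile machinery run on 21-row edge-centered profiles with a
   smaller kernel.

`I_S = I - I_B` by construction, so conservation is exact to the last bit.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | 5 px | softening of the distance-transform encoding |
| `threshold` | 0.8 | decoding threshold (3-px band for a straight edge) |
| `n_outer`, `n_inner` | 10, 40 | profile samples outside / across the bone |
| `max_dist` | 100 px | opposite-point search radius |
| `margin` | 3 | background anchor samples per profile end |
| `var_threshold` | 0.95 | cumulative explained variance kept by PCA |
| `smooth_kernel` | 30 | along-bone moving-average width |
| `edge_kernel` | 10 | smaller kernel used during edge reprocessing |
| `smooth_scale` | 1000 px | along-bone smoothing of the background estimate |
| `window`, `eps` | 90, 0.02 | guided-filter high-pass preprocessing |

Two of these deserve comment.

**Guided-filter regularization.**  The preprocessing step exists to remove
low-frequency content, so the network input is `image - guided_filter(image)`.
On unit-normalized intensities a regularization of `1e-8` would make the
self-guided filter a near-identity (any real patch has variance far above
it) and the residual would vanish; the default `eps = 0.02` is the
unit-intensity equivalent of a regularization of `1e8` applied to raw
16-bit values (`1e8 / 65535^2`), which turns the filter into a strong
smoother and the residual into a genuine high-pass.

**Background smoothing scale.**  `smooth_scale = 1000` is a clinical-scale
setting.  On desk-scale phantoms (192 px) it exceeds every bone length, the
along-bone background becomes effectively constant, and genuine along-bone
soft-tissue variation (the lung-field depression) leaks into the foreground
where it destabilizes the corrupted-profile clustering.  The package
therefore keeps the clinical default but the desk-scale test configuration
uses `smooth_scale = 30` and `max_dist = 40` — the 192-px analogues of the
clinical values, in the same spirit in which the opposite-point radius is
explicitly meant to be re-scaled for small images.

## The phantom generator: what it emulates, and what it does not

`generate_phantom()` builds scenes that are *exactly* decomposable:

- a smooth low-frequency background (low-pass-filtered seeded noise) with
  two soft-walled elliptical lung fields.  The walls are wide (tens of
  pixels) because the background must be genuinely low-frequency: the
  pipeline's background model is linear across a 50-sample profile and any
  sharp wall would be misread as structure;
- clavicles and posterior ribs as near-horizontal, gently curved bands of
  raised-cosine cross-section spanning the full image width; anterior ribs
  as steep (~40 degree) diagonals entering at the top-left and exiting at
  the bottom/right border.  Bones therefore cross, as anterior and
  posterior ribs do in real projections — this is what the
  corrupted-profile clustering step exists for — but each crossing
  corrupts only a minority of profile columns, which the majority-cluster
  rule requires.  Full-width bones have no mid-image end caps: a
  perpendicular profile can never sample a cap, and real ribs fade into
  radiolucent cartilage rather than ending in half-discs.  (A longitudinal
  `taper` envelope is available in `generate_bone()`; the default scene
  layout does not use it because a 0-to-1 amplitude continuum makes the
  fixed-k 2-means replacement rule paint full-strength bone into faded
  ends — precisely the over-suppression this family of methods is known to
  exhibit before Poisson correction);
- thin bright near-vertical line segments ("corruptors", e.g. catheters)
  and optional Gaussian pixel noise, both assigned to the soft component so
  that `cxr = soft + bone` holds bitwise for every seed.

What the phantom does **not** emulate: real rib texture and trabecular
structure, scatter and heel effects, anatomy outside the additive model,
pathological bone shape, and genuinely projective lung anatomy.  A green
phantom test therefore establishes that the pipeline's geometry, algebra,
and conditioning are right — not that clinical performance numbers
transfer.

## Numerical choices

- Distances in the encoding and in the mean boundary distance are exact
  Euclidean (two-pass lower-envelope transform); the oracle tests compare
  against brute-force all-pairs scans.
- Profile sampling uses bilinear interpolation; out-of-bounds coordinates
  clamp to the border.  Columns whose opposite-point search fails are
  filled by linear interpolation across columns so PCA sees a full matrix.
- Reverse scatter averages collisions; unassigned pixels inside the
  footprint take the value of the nearest assigned pixel (exact growing-
  window search).  Only the rows between the two edges are scattered into
  the preliminary bone image: bone is zero outside its own edges by
  definition, and the outer band exists only to anchor the background.
- The Poisson solve is a sparse Cholesky factorization of the 5-point
  Laplacian with zero Dirichlet conditions on all non-bone pixels.
  Regions touching the image border are reflect-padded by 8 px first, so
  the zero frame sits in virtual padding instead of truncating bones that
  run to the edge of the field of view.
- k-means uses 10 restarts under a fixed seed; a 50/50 split is broken in
  favour of the cluster whose centroid is nearer the columnwise median.
  Degenerate (zero-variance) inputs skip clustering entirely.
- Decoding by threshold-plus-thinning cannot reproduce a curved 1-px line
  pixel-for-pixel (thinning picks staircase pixels sub-pixel-equivalent to
  but not identical with the original rasterization); tests assert exact
  recovery on straight and diagonal interiors and a mean boundary distance
  of at most 0.5 px on curves.

## Networks

The learned components are a distance-transform edge-regression network
(MSE loss; a BCE segmentation baseline shares the code path) and a
bone-suppression network whose input stacks intensity, Sobel x/y gradients,
and the predicted edge mask, and whose target is the bone image (mostly
zero, hence an easier target than the soft-tissue image).  The desk-scale
architecture is a deliberately small two-scale convolutional
encoder-decoder (conv, 2x2 average pool, conv, nearest upsample, skip
concatenation, conv) trained with Adam under cosine annealing warm restarts
(periods 10, 20, 40, ... epochs; the rate returns to `lr0` at each
restart).  It stands in for the full-scale dense encoder-decoder used on
clinical data; the training loop, schedule, augmentation, seeding,
fine-tuning hand-off and serialization contracts are identical, and that is
what the tests exercise (overfitting a single phantom, seeded determinism,
transfer starting no worse than scratch).  Bundles serialize to JSON with
hexadecimal float literals, so a save/load round trip reproduces bit-equal
predictions.

## Known limitations

- The RMAE-B bar of the phantom-recovery criterion is not met: measured
  mean RMAE-B is ~10% against a 5% bar (BSR and noise-robustness bars
  pass).  The evaluation region `Omega_B` — a 50%-of-maximum threshold of
  the predicted bone image — is dominated by bone-on-bone crossing blobs,
  where the traditional pipeline's bias floor (background-curvature
  leakage through the linear background model, plus cluster-replacement
  bias) is about twice the bar.  This is left red deliberately: the
  literature reports strong over-suppression for raw PCA-based separation
  corrected only later in the pipeline, and the comparable published
  RMAE-B figures are produced by the *network*, which learns to smooth
  over these artifacts.
- Bones are assumed long, continuous, and pairable into upper/lower edges;
  fractures and abnormal bone shapes are out of scope.
- DICOM input is not supported in this build (no DICOM reader available);
  convert to 16-bit PNG or PGM upstream.  `read_image(invert = TRUE)`
  covers inverted (MONOCHROME1-style) intensity scales.
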