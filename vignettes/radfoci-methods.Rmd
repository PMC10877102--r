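---
title: "Quantifying DNA damage foci in irradiated tissue: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA damage foci in irradiated tissue: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Irradiating living tumor tissue ex vivo and counting the DNA
double-strand-break repair foci (53BP1 puncta) that remain in each nucleus
a fixed time after exposure is a candidate functional biomarker of
radiosensitivity: tissue that resolves fewer breaks shows more persisting
foci. The measurement chain is microscopy-heavy — confocal Z-stacks of
DAPI-stained nuclei and 53BP1-stained foci, acquired at 63x
(183.65 x 183.65 µm² fields, 1024 x 1024 px, 1 µm z-steps) — and manual
counting does not scale to the hundreds of clustered, variably stained
nuclei per field that tissue slices produce.

`radfoci` implements the full analysis chain: plane selection, semantic
segmentation of nuclei and foci with a compact U-net, watershed-based
instance separation, per-nucleus focus quantification, segmentation
metrics, and the condition-comparison statistics. Because patient imagery
cannot be redistributed, the package also ships a synthetic tissue-scene
generator with exact ground truth; every stage is trained and tested
against it.

## Pipeline

1. **Plane selection.** The DAPI plane with the highest mean intensity
   (arithmetic mean over all pixels, background included) is the analysis
   plane; ties go to the lowest index. For the foci channel a pixelwise
   maximum projection over the three slices centered on that plane keeps
   slightly out-of-focus foci distinguishable from noise. At stack edges
   the window clamps rather than shifting or padding, and the number of
   planes actually used times the z-step is recorded as the projection
   height — that honest height later divides the foci density.
2. **Semantic segmentation.** Two U-nets classify every pixel as
   nucleus/background and focus/background. Nuclei are segmented at
   512 x 512 after downsampling (batch 32 in the full recipe); foci at
   native resolution to preserve fine detail (batch 8). Both train with
   Adam (learning rate 1e-3) on a soft Jaccard loss for 200 epochs in the
   full recipe, with dihedral (8 flips/rotations) and contrast
   (factor 0.8 / 1.2) augmentation, keeping the weights of the epoch with
   the lowest validation loss.
3. **Nucleus post-processing.** Hole filling, then separation of touching
   nuclei by a tolerance-4 watershed on the Euclidean distance transform,
   then exclusion of objects touching the image border and of objects
   smaller than 10 µm².
4. **Overlay and quantification.** The foci mask is intersected with the
   nucleus labels; only foci inside nuclei survive, which is what removes
   extranuclear background speckles. Per nucleus, the density is
   `foci_count / (area_µm² x projection_height_µm)` — foci per µm³.
5. **Evaluation and statistics.** Pixel Dice/IoU, object-level Dice with
   one-to-one centroid matching (radius 3 px, strict `<`), OLS agreement
   regression and paired t-tests for the segmentation; Kruskal–Wallis with
   Dunn's post hoc (Bonferroni) across conditions and relative standard
   deviation across images for the biology.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pixel_size_um` | 183.65/1024 ≈ 0.17935 | µm/px | the acquisition calibration; the 10 µm² filter and all areas depend on it |
| `projection_half_width` | 1 | planes | three-slice maximum projection |
| `watershed_tolerance` | 4 | px (distance-map units) | h-maxima merge depth; adjacent basins whose peak rises less than this above the contact saddle are one nucleus |
| `min_area_um2` | 10 | µm² | removes partial nuclei and debris |
| `threshold` | 0.5 | probability | U-net binarization cut |
| `max_center_distance_px` | 3 | px | object matching radius: the mean focus size (~2.5 px) rounded up, strict inequality |
| `alpha` | 0.05 | — | significance level throughout |

## The U-net, concretely

The architecture is a Ronneberger-style encoder–decoder with skip
connections, preceded by per-image min–max normalization to [0, 1] (the
imaging settings are constant but staining efficiency is not; min–max
makes the net exposure-invariant) and with batch normalization after every
convolution, before the ReLU. Details the assay description leaves open
were fixed as: depth 4 with 16 base filters (doubling per level),
size-preserving (padded) 3 x 3 convolutions without biases (batch norm
supplies the shift), 2 x 2 max-pooling, nearest-neighbor upsampling
followed by a 1 x 1 channel-halving projection in the decoder, two 3 x 3
convolutions after each skip concatenation, and a single-channel sigmoid
1 x 1 output head. The binarization threshold is 0.5 and is exposed as a
parameter. Mask downsampling for nuclei training binarizes by block
coverage ≥ 0.5, which preserves thin structures better than
nearest-neighbor.

The implementation is self-contained: im2col convolutions over BLAS
GEMMs, with the convolution arithmetic in single precision (ample for
stochastic-gradient training; batch-norm statistics, reductions and the
optimizer state stay in double precision) so that desk-scale training runs
in minutes on one CPU. The backward pass is verified against finite
differences in the test suite. Contrast augmentation multiplies by a
factor drawn from {0.8, 1.0, 1.2} and clips to the image's original value
range; because the first network layer re-normalizes per image, the
augmentation's effect is precisely the saturation nonlinearity the
clipping introduces.

## What the synthetic scenes emulate — and what they do not

`scene_spec()` renders calibrated DAPI/53BP1 stacks with: elliptical
nuclei of mean radius 4 µm (SD 0.8) with per-nucleus lognormal staining
variation and a dimmer center (35% drop, mimicking the chromatin-density
artifact real DAPI images show); a configurable fraction (default 25%) of
nuclei placed touching or overlapping a neighbor while the ground truth
keeps them as distinct labels — exactly the clustering the watershed stage
must undo; focus counts per nucleus drawn from a Poisson with mean
`baseline + dose x foci_per_Gy` (defaults 0.5 and 2/Gy); foci rendered as
Gaussian puncta (σ ≈ 0.25 µm ≈ 1.4 px, consistent with ~2.5 px foci) at
full amplitude in the focal plane and reduced amplitude in the adjacent
planes, so the three-slice projection is genuinely exercised; diffuse
nucleoplasmic 53BP1 signal; extranuclear speckles (default 8 per image)
that appear in the rendered foci channel but never in the ground truth;
constant background plus Gaussian read noise; and a DAPI axial intensity
profile peaking at the focal plane. The default test geometry is
256 x 256 px at the acquisition pixel size; 1024 x 1024 reproduces the
full field.

Deliberately not modeled: a physically realistic confocal point-spread
function, 3D ground truth, mitotic/apoptotic morphologies, chromatic
shift, and the empirical distribution of nuclei per field (the generator
exposes `n_nuclei` instead). Passing tests therefore demonstrate that the
chain is correct and self-consistent on images with the right geometry,
calibration and failure modes — not that the shipped reduced-scale
weights transfer to patient tissue.

Two known numerical footnotes. First, foci are rejection-sampled so that
each focus footprint lies fully inside its parent nucleus and no two
ground-truth foci touch (otherwise connected-component counting could not
be exact); in small nuclei at high dose this sequential packing saturates
and depresses the realized mean count by ~3% relative to the nominal
Poisson mean at dose 5 Gy — inside the 3-standard-error band the test
suite checks at n ≥ 500 nuclei, but a real bias at much larger n. Second,
overlapping nuclei are drawn back-to-front, so a heavily overlapped
nucleus can lose part of its ground-truth cross-section to the one on top
of it; slivers below 10 µm² are then legitimately removed by the area
filter, which is why count-recovery checks match nuclei by centroid
rather than by label id.

## Statistics: choices where the convention was open

* Kruskal–Wallis and Dunn's test are implemented from their rank formulas
  (midranks, tie corrections) and cross-checked in the tests against
  `stats::kruskal.test` and hand-computed rank arithmetic; Dunn's
  adjustment is Bonferroni, the most common pairing, and is applied per
  patient over the condition pairs. Dunn runs only when there are at
  least three conditions and the omnibus test is significant.
* The unit of analysis pools individual nuclei (for density) or
  individual foci (for size) across a patient's images within a
  condition; per-image means and medians are also emitted for plotting
  and for the variation report.
* The relative SD uses the per-image mean as the image summary (the
  median variant is available), sample SD (n−1), expressed in percent of
  the mean.
* If all pooled values are identical the Kruskal–Wallis statistic is
  undefined; the implementation returns H = 0, p = 1.
* Both-empty masks score DSC = IoU = 1 by convention; a center pair at
  exactly the matching radius does **not** match (strict inequality).
* Object matching uses an optimal one-to-one assignment (Hungarian
  algorithm), maximizing matches and breaking ties by minimal total
  distance: greedy matching would make the metric order-dependent and
  asymmetric.
* The focus "size" is emitted both in px and µm²; the physical area is
  the resolution-invariant convention used in summaries.

## Degenerate inputs and edge rules

Single-plane stacks are legal (the projection then uses one plane and
records 1 x z-step as its height). Readers refuse to guess calibration —
a missing pixel size is an error, not a default. Empty masks, empty label
maps, images without nuclei, and empty pipeline manifests all flow
through and produce empty tables rather than failures; a failing image in
a cohort run is recorded in the run manifest and skipped. The border rule
counts any object pixel on the outermost pixel frame. Connected
components use 8-connectivity for foreground and 4-connectivity for
background (hole filling) throughout.

## Problem sizes used by the test suite

The suite trains the nuclei U-net (depth 4, base 16) for 20 epochs on 20
synthetic 128 x 128 pairs and the foci U-net analogously on 96 x 96
scenes, evaluating on held-out scenes; the dose–response check uses a
3-patient cohort with five 256 x 256 images per condition at 0 and 5 Gy,
and the type-I-error check simulates 200 zero-effect cohorts at the
count level (rendering skipped). These sizes were chosen as the smallest
at which each property is meaningfully exercised; the full-scale recipe
(512 x 512, batch 32, 200 epochs, 1024 x 1024 fields) remains available
through the same configuration objects.

## Known limitations

* The reduced-scale trained models are demonstrations of the training
  machinery, not transferable weights; no claim is made about patient
  tissue performance.
* Batch normalization with very small batches uses noisy statistics;
  running statistics accumulate with momentum 0.9, so extremely short
  runs (1–2 epochs) can have miscalibrated inference-mode normalization.
* The watershed separation operates in 2D on the selected plane; truly
  3D-overlapping nuclei are out of scope.
* Focus measurements are areas of binary components; intensity-weighted
  metrics are not implemented.
* The etched single-pixel boundary between watershed labels can, for
  pathologically thin objects, split a label into more than one connected
  component.
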