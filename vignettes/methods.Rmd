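---
title: "Methods: active-learning segmentation for land use following deforestation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-learning segmentation for land use following deforestation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tree-cover loss products say *where* forest disappeared but not *what
replaced it*. Mapping the land use that follows deforestation — cropland,
pasture, tree crops such as cacao, oil palm, rubber or cashew, mining,
roads, settlements — turns a loss mask into a statement about proximate
drivers. The workflow this package implements does that by semantic
segmentation of high-resolution (≈5 m) four-band mosaics, restricted to
forest-loss pixels, followed by survey-grade accuracy and area estimation
and by spatial/temporal summaries (hotspots, five-year trends).

Two practical obstacles shape the design. First, reference labels are
scarce and imperfect: polygons mix several land uses, boundaries are
sloppy, and whole regions lack labels. Second, fifteen classes are heavily
imbalanced — linear features (roads, rivers) and rare commodity crops
occupy few pixels. The pipeline therefore combines a focal-loss attention
U-Net with pool-based active learning: the model itself points at the
images it is most uncertain about, and an annotator labels those next.

Because the real mosaics and label archive cannot be redistributed, the
package ships a seeded synthetic-scene generator that reproduces the
*statistical structure* the method assumes, making every stage testable
end to end on a laptop CPU.

## Synthetic scenes

`generate_scene()` paints the 15 land-use classes with shape families that
mimic their real geometry: axis-aligned fields for cropland and tea,
elliptical blobs for pasture and mining, full-width polylines for roads,
sinusoidal meanders for rivers, scattered block clusters for settlements,
and rectangles with a small periodic brightness modulation for plantation
lattices (tree crowns alternating with soil). Reflectances are the class's
4-band signature plus Gaussian noise (`band_sd`, default 0.02, plus a
scene-level `noise_sd` of 0.01), clipped to [0, 1]. The defaults follow
the qualitative structure of optical signatures — vegetation bright in
nir, built surfaces bright in the visible, water dark in nir — with
pairwise spectral distances chosen large relative to the noise so that the
mapping problem is solvable (a property the tests verify with a
nearest-centroid classifier as noise goes to zero).

The forest-loss mask thresholds a smooth random field over non-water
pixels (default 35% loss fraction — high relative to real landscapes, but
it keeps every class represented inside loss areas at desk scale), and
each loss pixel draws a loss year uniformly from 2001–2020. A uniform
temporal process is deliberate: the trend analytics only require a defined
five-year partition, not a realistic deforestation history.

What the generator does *not* emulate: atmospheric effects, sensor
seams, phenology, spatially correlated label noise, and the long-tailed
class-frequency distribution of the real archive. Passing the bundled
benchmarks therefore demonstrates the correctness and the qualitative
behaviour of the pipeline, not its accuracy on real mosaics.

### Annotation corruption

`corrupt_annotations()` abstracts the documented pathologies of real
reference polygons into four parameterized corruptions, applied in this
order: a global boundary dislocation of up to `boundary_shift_px` pixels;
"polygon mix" inclusions (a random block inside a fraction of annotation
components is overwritten with another class); exact-count mislabeling
(`round(f·n)` labeled pixels get a guaranteed-different class, so the
measured mislabel rate equals the requested fraction by construction); and
label dropping to the unlabeled code −1. The real archive's error rates
are unknown, so these are free parameters; the bundled benchmark uses 30%
mislabeled and 30% dropped, which is severe enough to depress the initial
model visibly while leaving the task learnable.

## Preprocessing

Bands are kept in [0, 1] (`"fixed"` mode clips; `"minmax"` rescales per
scene when inputs are digital numbers). Three indices extend the stack to
seven channels:

* `ndvi = (nir − red) / (nir + red)`
* `savi = (nir − red) / (nir + red + 0.5) · 1.5`
* `ndmi = (green − nir) / (green + nir)`

The moisture index is implemented with green and nir — the natural
green/nir proxy when no SWIR band exists on these mosaics — rather than
the SWIR-based convention. Zero denominators map to 0 so stacks stay
finite.

The loss-area filter removes connected components below 3.8 ha (1520
pixels at 5 m). Connectivity is 8-connected by default — the less
aggressive choice — and configurable; the criterion is applied per
component, with a per-image variant possible by filtering on total loss
area instead.

## The segmentation model

A compact attention U-Net: `depth` (default 3) encoder levels of two 3×3
same-padded convolutions with BatchNorm and ReLU, 2×2 max pooling, a
bottleneck, and a mirrored decoder. Skip connections pass through
*additive* attention gates — the decoder's coarser feature map is
upsampled, both inputs are projected and summed, and a sigmoid head yields
a per-pixel coefficient in [0, 1] that modulates the encoder features
before concatenation. Additive gating is the standard formulation of
attention U-Nets; the multiplicative variant is not implemented. The
output head is a 1×1 convolution to K logits with a per-pixel softmax
(classes are mutually exclusive). Dropout (rate 0.1) follows each
convolution block during training.

No deep-learning framework is involved: the network — forward pass,
backpropagation, Adam — is implemented directly on BLAS matrix
multiplication. Convolutions use a shift-convolution formulation (nine
per-offset linear maps accumulated with row shifts, the hot paths in
C++), and the analytic gradients are verified against finite differences
in the test suite.

### Focal loss

For a pixel of true class *t* with predicted probability *p*:

FL = −w_t · α_t · (1 − p)^γ · log p

γ (default 2, the canonical setting) focuses the loss on hard pixels;
α and the per-class weights re-balance classes. The reference recipe
states that α, γ and class weights are used but not their values, so the
defaults here are α ≡ 1 and inverse-frequency class weights normalized to
mean 1 and clipped to [1/2, 2], computed from the training labels; all are
configurable. The clip matters: raw inverse frequencies put weight ratios
near 100 between the dominant background and rare plantation classes,
which makes the model annex background pixels to the rare classes
(observed as plantation-forest precision collapsing on clean data);
bounded weights keep the re-balancing without that pathology, and the
weakest class under the default is settlement (small scattered blocks)
rather than any of the rare crops. Pixels
labeled −1 are excluded from the loss entirely — corrupted annotations
with dropped labels must not teach the model a fake class — and the
γ = 0 / unit-weight case reduces exactly to mean cross-entropy.

### Training scales

The reference recipe (200 epochs, batch 64, Adam at 1e-4) assumes GPU
hardware. The package's CPU-scale defaults, chosen once and used
throughout the benchmarks, are: 128×128 scenes cut into 64×64 patches,
batch size 8, Adam at 3e-3, depth 3 with 16 base filters, ≤50 epochs.
An optional `patches_per_epoch` cap decouples epoch cost from pool size
for exploratory runs; the bundled benchmarks do *not* use it, because the
reference procedure retrains on the full (growing) pool each cycle and
capping it was observed to starve later cycles of optimization steps.

## Active learning

The loop mirrors pool-based uncertainty sampling: train on the annotated
pool; score every unannotated image by prediction entropy
H(Y) = −Σ p_i log p_i; send images scoring strictly above the threshold to
the (here simulated, perfect) annotator; retrain from scratch on the
enlarged pool; repeat (default two rounds, giving three trained models).
Three decisions the source procedure leaves open:

* **Entropy scale.** A threshold of 0.6 is ambiguous when the per-pixel
  maximum is ln 15 ≈ 2.71 nats: 0.6 nats would select nearly everything.
  The default scale is therefore *normalized* entropy (H / ln K) with the
  threshold at 0.6 of the maximum; raw nats are available.
* **Aggregation.** Per-image score is the *mean* per-pixel entropy over
  forest-loss pixels (the region the map is made for) when a loss mask
  exists; `max` and `fraction_above` are provided.
* **Empty selections.** If a cycle selects nothing (or the pool is
  empty), no new information exists, so the loop carries the previous
  model and metrics forward instead of refitting from a fresh random
  initialization — retraining on identical data would only add seed noise
  to the reported trajectory.

The test pool is fixed before the first cycle and never touched; all
metrics are computed on it.

The bundled AL benchmark (24 scenes: 8 annotated with 30%/30% corrupted
labels, 12 unannotated, 4 test; 14 epochs per cycle — enough for the
retraining on the grown pool to converge reliably; 3 replicates)
reproduces the qualitative behaviour of the original experiment — a
rising macro-F1 trajectory as informative images are annotated — not its
absolute numbers, which depended on a 2357-image continental archive.

## Accuracy, area, and analytics

Per-class F1 (2PR/(P+R)), macro and micro averages, and user's/producer's
accuracy come from pixel-wise confusion matrices with the zero-denominator
convention F1 = 0 (flagged), which keeps macro averages stable when a rare
class is absent from a small test batch.

Map assessment follows stratified good-practices estimation: strata are
the mapped classes with weights W_h proportional to mapped area; samples
are allocated proportionally (largest-remainder rounding with a
per-stratum minimum — the source does not print its allocation rule);
cell proportions are p̂_ij = W_i n_ij / n_i·; overall, user's and
producer's accuracies and error-adjusted areas with stratified standard
errors follow. The estimators are validated against a census oracle (full
sampling must equal exhaustive confusion-matrix values to machine
precision) rather than against published numbers, since none exist for
this check. Everything is computed independently within each lustrum
(2001–2005, 2006–2010, 2011–2015, 2016–2020) of the loss year; empty
lustra are reported and skipped. Reference labels default to the
generator's truth (a perfect interpreter) with an optional interpreter
error rate.

Hotspots are plain product-Gaussian kernel density estimates evaluated on
a 0.1° grid (bandwidth 0.1°, both configurable; the kernel family is not
named in the source and Gaussian is the default choice). The surface is
scaled to integrate to the number of input points, a mass-conservation
invariant the tests check to 1%, and cross-checked against an independent
bivariate KDE implementation. Geographic distortion (degrees vs metres) is
ignored, matching a plain lat/lon grid — a documented limitation.
Trend tables count pixels per (region, class, lustrum) and normalize
proportions within each (region, lustrum); log scaling is presentation
only. Country tables give percentages over classified pixels per country.

## Numerical choices and degenerate inputs

* Argmax ties resolve to the lowest class id (documented, deterministic).
* Probability simplex tolerance 1e-5; `0·log 0 = 0` throughout.
* Non-loss pixels in emitted maps carry the no-data code 255 (fits 8-bit
  rasters for K ≤ 15).
* A single global seed fans out to per-stage seeds through a fixed affine
  derivation, so stages are independently reproducible.
* Scene I/O uses multi-band TIFF with a JSON sidecar for the
  geotransform; masks are 16-bit with an integer offset so the −1 code
  round-trips exactly.
* Connected components use vectorized min-label propagation (8- or
  4-connected), cross-checked against an independent 4-connected
  implementation.
* The degenerate one-class scene is allowed (useful in tests) even though
  multi-class configurations are the intended use.

## Known limitations

* Synthetic spectra are far cleaner than mosaics stitched from many
  sensors; real-data F1 will be lower and the entropy threshold may need
  re-tuning on real probability distributions.
* The simulated annotator is perfect; real annotation noise would blunt
  the active-learning gain.
* KDE on a degree grid ignores meridian convergence.
* The from-scratch network is CPU-oriented; it is not a platform for
  large-scale training.
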