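---
title: "Weakly supervised MIL classification of duodenal biopsy slides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised MIL classification of duodenal biopsy slides: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Coeliac disease is diagnosed histologically from duodenal biopsies: villous
atrophy, crypt hyperplasia and raised intra-epithelial lymphocyte counts.
Whole-slide images (WSIs) of such biopsies are gigapixel rasters carrying one
*slide-level* label — pixel-level annotation is unavailable at scale. wsimil
implements a multiple-instance-learning (MIL) pipeline for this setting:
slides are split into patches, a two-head patch classifier is trained from
slide labels alone through top-k proxy labelling, and patch predictions are
aggregated back into slide-level calls and localisation heatmaps.

This vignette documents the model, its assumptions, the tunable parameters,
the numerical choices, and what the bundled synthetic-data generator does and
does not emulate.

# Pipeline

## Tiling and background rejection

Slides are processed at a working resolution of roughly 10 µm/pixel. A
sliding window emits 256×256-pixel patches at a stride of 128 (50 % overlap
in each axis); windows that do not fit entirely inside the slide are dropped
rather than padded, so every patch has the exact working shape. Tissue is
separated from the bright slide background with Otsu's method, and a patch is
discarded when more than 75 % of its pixels are background (rule: kept ⇔
background fraction ≤ 0.75, a literal reading of "more than 75 %").

Design choices that the problem statement leaves open, resolved here:

* **Otsu granularity.** One global threshold per slide, computed from the
  luminance (Rec. 601 luma) of a thumbnail subsampled at the tile stride.
  Per-patch thresholds are unstable on nearly empty tiles; a per-slide
  threshold makes the keep/discard decision depend only on the slide, not on
  the tile's own content mix.
* **Class orientation.** Otsu alone does not say which side is background;
  on H&E the background is white, so "background" is defined as *brighter*
  than the threshold.
* **Ties.** The maximiser of the between-class variance is taken at the
  lowest grey level on ties, making the threshold deterministic.

## Macenko stain normalisation

Staining and scanner variation shift H&E colours between laboratories. Each
patch is re-rendered in a fixed reference stain basis before reaching the
classifier:

1. convert to optical density, `od = -log10(max(pixel, 1)/255)`;
2. drop pixels with OD magnitude below `od_min = 0.15` (unstained);
3. take the top-two singular directions of the retained OD cloud (the
   best-fit stain plane through the origin);
4. project, and take the directions at the 1st and 99th percentile of the
   projection angle as the haematoxylin/eosin vectors (haematoxylin is the
   column with the larger blue-channel OD);
5. unmix every pixel by least squares (clipped at zero) and rescale each
   stain by `max_ref / max_src`, where the maxima are 99th-percentile
   concentrations;
6. re-render through the reference matrix.

The constants (`io_white = 255`, `od_min = 0.15`, 1st/99th angle
percentiles, 99th concentration percentile) are the method's customary
defaults and are exposed in `stain_norm_config()`. Estimation subsamples at
most 20 000 stained pixels (deterministic stride), which leaves the
percentile geometry essentially unchanged while keeping per-tile cost low.
Profiles are estimated **per patch** by default (the classifier's inputs
are normalised independently); `prepare_slide_tiles()` also offers
per-slide profiles (`stain_mode = "slide"`) and a fixed reference basis
(`"reference"`). Per-patch estimation proved the strongest choice for the
classifier in our experiments, and per-slide estimation carries a caveat
worth stating: any quantity estimated from the whole slide (its stain
basis, its robust concentration maxima) is a function of the slide's
disease burden, so normalising tiles by it imprints slide-level label
information onto every tile — harmless for slide classification, corrosive
for patch-level localisation claims.

The reference profile is the canonical H&E optical-density basis with
reference maxima `c(H = 0.9, E = 0.9)`, fixed once from the synthetic
generator's canonical rendering; any `stain_profile` can be substituted.
Degenerate inputs fail loudly: fewer than 100 stained pixels ("no stainable
tissue") or a rank-1 OD cloud (single stain) raise errors rather than
returning garbage vectors.

## MIL training

Training follows the weak-supervision recipe exactly:

* one epoch visits every slide in seeded random order;
* at each visit a **bag** of 100 patches is drawn uniformly *with
  replacement* from the slide's kept tiles (a fresh bag every visit);
* the classifier infers on the bag; per-patch **proxy labels** are assigned:
  every patch of a normal slide is labelled `(normal, coeliac) = (1, 0)`;
  on a coeliac slide the α = 10 "least normal" patches are labelled
  `(0, 1)`, the β = 0 "most normal" are labelled `(1, 0)`, and all other
  patches are masked out of the loss entirely (their gradient is exactly
  zero — asserted by finite differences in the tests);
* one Adam step (learning rate 1e-4, weight decay 1e-4, other moments at
  their conventional defaults) on the masked sigmoid binary cross-entropy,
  averaged over active entries;
* ten epochs.

Two readings left open by the recipe are resolved as follows. "Least normal"
ranks patches by the *normal-head* probability ascending (the phrase names
the normal axis); ranking by the coeliac head instead is a different rule
whenever the heads are not perfectly anticorrelated. Ties in the ranking
break by ascending bag index, so labelling is deterministic given
predictions. Masking is implemented as exclusion from the loss mean (the
denominator counts active entries only).

## The compact backbone

The patch classifier is a contract (`forward`, `backward`, parameter
access); any architecture satisfying it can be trained, including adapters
around large pretrained networks. The bundled default is a compact CNN
designed so the full cross-validated experiment trains on one CPU in
minutes:

* inputs are 32×32×4 tensors: the 256×256 normalised patch is mapped to
  haematoxylin-concentration, eosin-concentration and OD-magnitude planes
  (unmixed per patch), plus a local haematoxylin **texture-energy** plane —
  the per-block standard deviation of the haematoxylin concentration at
  full resolution, which preserves nuclear crowding (the
  lymphocyte-density cue) that block-mean downsampling would otherwise
  erase; all planes carry a fixed gain of 12;
* four 3×3 convolution blocks (8, 16, 32, 128 channels; ReLU; 2×2 max
  pooling after the first three), global average pooling, an affine-free
  **layer normalisation** of the pooled features, and a linear two-logit
  head;
* He initialisation for the convolutions, **zero initialisation for the
  head**; in cross-validation every fold's backbone starts from the same
  seeded initialisation.

These choices all answer the same constraint: the recipe is short and slow
(ten epochs over ~50 slides is ~500 optimiser steps, and Adam moves each
parameter by at most `lr × steps ≈ 0.05`), yet out-of-fold scores from
independently trained models must land on a common scale. With a randomly
initialised head the logits would stay dominated by a frozen random
projection of the features — zero initialisation removes that noise floor.
The attainable logit swing after a fixed number of bounded Adam steps
scales with feature magnitude, so the input gain is set so the heads reach
saturation (confident probabilities) within the schedule instead of
stopping mid-ramp. Layer normalisation strips the per-tile common
activation level, concentrating the head's limited movement budget on the
discriminative pattern and making scores comparable across tiles, slides
and folds. Concentration/texture input planes rather than raw RGB align
the input axes with the quantities that carry diagnostic signal, which
shortens the bootstrap phase of MIL training.

## Slide scoring, thresholds, evaluation

The slide score is the arithmetic mean of the per-tile probabilities, one
mean per head; inference covers *all* kept tiles, with no sampling. Each
head is thresholded independently with a strict "exceeds" comparison; the
shipped defaults `(t_normal, t_coeliac) = (0.905, 0.096)` are the operating
points reported for the original clinical cohort, and slides that trigger
both heads or neither are flagged discordant rather than silently resolved.

Cross-validation is case-grouped and stratified: all slides of a case share
a fold, and per-class case counts per fold stay within one of perfect
stratification (shuffled within class strata, dealt greedily to the lightest
fold). Thresholds are re-selected on pooled out-of-fold scores at the
**balance point** — the candidate minimising |sensitivity − specificity|
averaged over folds, ties to the lower threshold, candidates being midpoints
between consecutive distinct scores plus outer sentinels. The literal
objective |TPR − FPR| is also implemented (`objective = "literal"`) but
selects a chance-level operating point (every threshold outside the score
range satisfies TPR = FPR); the balance-point reading is the one consistent
with meaningful operating points and is the default. ROC and PR curves are
swept over all distinct scores with trapezoidal AUC, making the ROC AUC equal
to the Mann–Whitney pairwise statistic with ties counted one half.

Metrics follow the standard definitions (accuracy, precision = TP/(TP+FP),
recall = TP/(TP+FN)) per class head; undefined ratios are reported as `NaN`
with a warning, never silently as zero.

## Heatmaps

Patch predictions are rendered at a default 32× downsample. Where
overlapping kept tiles disagree, the **maximum** prediction wins
(order-independent compositing); regions covered by no kept tile carry an
out-of-band sentinel (a mask channel, not the value 0) so "confidently
normal" and "discarded background" render differently — background is drawn
black in `compose_overlay()`, predictions through a perceptually uniform
colormap.

# The synthetic slide generator

`generate_dataset()` gives every module a download-free test surface. Each
slide is a 1536×1536 raster (≈121 tiles at the working geometry):

* **tissue**: smooth random blobs (bilinearly upscaled coarse Gaussian
  fields thresholded at a per-case tissue fraction of 0.35–0.55 of the
  slide), on a white background with Gaussian pixel noise (σ = 1.5 grey
  levels);
* **colour**: haematoxylin/eosin concentration fields (baselines 0.55 and
  0.40 with smooth spatial variation) rendered through the Beer–Lambert
  model `od = M · c`; each synthetic "scanner" uses a stain matrix rotated
  by up to 10° from the canonical basis, emulating cross-scanner stain
  variation;
* **lesions** (positive slides only): a contiguous sub-region of the tissue
  occupying a uniform 15–50 % of the tissue area, with two superimposed
  signals — a haematoxylin concentration boost (+0.35) and high-frequency
  dark dots (radius 2 px, expected density 0.002/px², amplitude +1.2)
  standing in for raised intra-epithelial lymphocyte density. The
  ground-truth mask is emitted alongside the image.

The lesion signal is deliberately two-scale (colour shift + texture) so that
both a trivial statistic and a small CNN can detect it; `separability_check()`
certifies before any training that a hand-crafted statistic (mean
haematoxylin concentration over stained pixels plus a dark-dot fraction)
separates lesion tiles from normal-slide tiles with ROC AUC ≥ 0.9. The
texture and contrast parameters were chosen once to satisfy that
certification at realistic visual contrast and are not tuned per experiment.

What the generator does **not** emulate — and therefore what passing tests
do not establish about clinical data: real villus/crypt morphology,
cell-level texture, scanner blur and compression artefacts, tissue folds and
pen marks, label noise, class imbalance, and the sheer scale of clinical
WSIs (gigapixels vs ~2.4 MP here). End-to-end results on synthetic cohorts
demonstrate that the pipeline's mechanics are correct and that the training
procedure can recover a localised, weakly supervised signal; they are not
estimates of clinical performance.

## Localisation summary

For positive held-out slides with ground-truth masks, the experiment
reports whether the mean coeliac prediction over lesion tiles strictly
exceeds the mean over non-lesion tiles. Membership follows the mask
literally: a kept tile is lesional if it overlaps the mask at all and
non-lesional otherwise (the `lesion_overlap` argument raises the cut if a
stricter notion is wanted). Trace overlaps are deliberately counted as
lesional — the trained detector responds to even a few percent of lesion
content in a tile, and that response is correct localisation, not a false
positive. Because sizeable lesions under a 50 % window overlap can leave
very few zero-overlap tiles, a slide contributes a measurement only when
both groups have at least three kept tiles; a one-tile "group mean" is
noise, not measurement.

# Study conditions used by the bundled experiment

The cross-validated experiment that the acceptance script and the end-to-end
tests run uses 60 slides (30 normal, 30 positive) over 30 cases and 3
synthetic scanners, 5 case-grouped stratified folds, and the training recipe
above (10 epochs, bag 100, α = 10, β = 0, Adam 1e-4/1e-4). Every fold's
backbone starts from the same seeded initialisation, so fold models differ
only through their training data — a reproducibility choice that also keeps
out-of-fold scores on a common scale. On one CPU the whole experiment
(generation included) runs in about a quarter of an hour.

# Numerical details and degenerate inputs

* Otsu requires at least two non-empty histogram bins; single-valued
  histograms are an error ("degenerate histogram").
* `rgb_to_od()` floors pixels at 1, so OD is finite; `od_to_rgb()` clips to
  `[0, 255]`. The round trip is exact to ±1 grey level.
* Stain estimation: plane orientation is fixed by pointing the first
  singular direction at the cloud mean; extreme vectors are flipped
  non-negative, clipped at zero and renormalised; a second singular value
  below 1e-6 of the first, or an angular spread below 1e-4 rad, is reported
  as a degenerate (single-stain) cloud.
* `select_threshold()` errors on one-class or constant scores.
* Slides with no kept tiles are skipped in training (with a warning) and
  produce an all-sentinel heatmap.
* Training is exactly reproducible under a seed on a fixed BLAS
  configuration; the forward/backward passes themselves are deterministic.

# Known limitations

* The compact backbone is sized for CPU test cycles, not clinical accuracy;
  real deployments should plug a large pretrained encoder into the
  `patch_classifier` contract.
* Per-patch Macenko estimation can flatten genuine intensity differences
  between patches (each patch's 99th-percentile concentration is mapped to
  the same reference maximum): on the synthetic cohorts the interior of a
  dense lesion can end up *less* saturated than its boundary after
  normalisation. Slide-level classification is insensitive to this;
  interpret heatmap intensity with it in mind.
* With β = 0, patches of a positive slide outside the top-α ranking are
  masked rather than labelled normal, so nothing in training pushes a
  positive slide's unremarkable tissue down. Slide-level metrics are
  stable under this (pooled ROC AUC varied by < 0.005 across training
  seeds in our runs), but the patch-level localisation rate is the most
  seed-sensitive quantity the experiment reports: each trained model keeps
  its own idiosyncratic false-positive pattern on positive slides.
* The balance-point threshold rule assumes both classes are present in the
  pooled out-of-fold scores.
* Heatmaps are review aids at 32× downsample; they are not segmentations.
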