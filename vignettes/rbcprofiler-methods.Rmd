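---
title: "Single-cell red blood cell profiling: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell red blood cell profiling: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rbcprofiler` turns paired brightfield/fluorescent microscopy fields of red
blood cells (RBCs) into an interpretable per-cell analysis: instance
segmentation, detection of intracellular Ca²⁺-loaded vesicles in the Fluo-4
channel, a fixed catalog of 135 morphological features, and automated
training of tree classifiers whose decisions can be read off their feature
importances. This vignette explains the models and the decisions behind
them; the README shows the worked pipeline.

## Segmentation: a backend contract, not a model

Cell detection runs behind a minimal contract — anything that maps a
brightfield image to a set of scored binary masks is a backend. Deep
detection models (e.g. a trained Mask R-CNN exposed from another runtime)
can be plugged in through `function_backend()`; the always-available default
is `classical_backend()`:

1. invert and rescale the brightfield (cells are dark on bright ground),
2. Gaussian smoothing (`sigma = 2` px) and Otsu thresholding,
3. hole filling, so central pallor does not puncture masks,
4. distance-transform watershed to split touching cells,
5. removal of regions below `min_area = 50` px (debris).

The classical backend reports confidence 1 for every instance; thresholding
on `min_score` is honored by any backend. Masks are dense binary grids and
may overlap — no single label map is forced at the data-model level, only
when writing label-map files.

Instance segmentation quality is scored by COCO-style average precision
(`mask_ap()`): detections ranked by score across images (ties: larger area,
then id), greedy one-to-one matching at mask-IoU ≥ threshold, area under
the all-points-interpolated precision–recall curve. The matching and
interpolation dialect is a package decision (the common COCO convention);
it is pinned by a brute-force oracle test rather than by external data.

## Vesicle detection

Vesicles — inside-out membrane compartments that sequester Ca²⁺ — appear in
the Fluo-4 channel as small, high-intensity spots inside cells. Let
`I` be the fluorescent image and `U_r(x, y)` the set of pixels within
strict L1 distance `r` of `(x, y)`. Detection has two stages:

1. **Candidates.** A median filter of size `m × m` (reflect padding)
   suppresses single-pixel spikes; a pixel is marked when its filtered
   value equals the maximum over its L1 ball of radius `d` *and* strictly
   exceeds the filtered image minimum (so constant images yield nothing).
   Connected plateaus of marked pixels collapse to their rounded centroid.
   Using the larger radius `d` (not the vesicle radius `v`) for the
   neighborhood guarantees at most one candidate per vesicle.
2. **Contrast test.** A candidate is a vesicle when the mean of the
   *original* intensities over `U_v` minus the threshold `t` strictly
   exceeds the mean over the annulus `U_c \ U_v`.

Defaults are `m = 3`, `d = 10`, `v = 4`, `c = 8`, `t = 1` — the constants
determined for ×100-objective Fluo-4 imagery; they are data-dependent and
exposed via `vesicle_params()`. `t` has a precise reading: it is the least
assumed contrast between a vesicle and its surround, i.e. the algorithm
presumes all *non-vesicle* intensity structure inside a cell stays below
`t`. Each accepted center is assigned to the cell whose mask contains it;
centers outside every mask are kept as unassigned. Erasure sets the
`2v² − 2v + 1`-pixel L1 ball of every vesicle to zero *before* fluorescent
intensity/texture features are computed, so vesicles perturb neither; the
per-cell count itself becomes the feature `ca2+_number_of_vesicles`.

Detection is scored against point annotations by minimum-cost one-to-one
matching (Hungarian algorithm) with a 5-pixel acceptance radius; optimal
rather than greedy matching is a deliberate choice — the tolerance is the
stated criterion, the matching rule is not, and the optimal matching makes
precision/recall independent of enumeration order.

Two open dialect points are settled as: the L1 ball is strict (`< r`), and
the contrast test runs on raw (not median-filtered) intensities — the
defining formula is written on `I` itself.

## The feature catalog

Every cell yields a fixed, ordered catalog: 14 shape features from the
mask; 18 intensity and 42 texture features per channel (suffixes `_bf` /
`_fl`); plus the vesicle count — 135 columns with a fluorescent channel, 74
without. The schema never varies with the data; failed computations become
`NA` values, never missing columns.

Channels are normalized per image to `[0, 255]` by min–max rescaling
(constant images map to zero) before intensity/texture computation, and
discretized with a fixed bin width of 25 anchored at zero (≤ 11 gray
levels) for histogram, GLCM, GLDM, GLSZM and GLRLM statistics. Both the
normalization dialect and the bin width are package decisions — fixed and
documented so texture values are reproducible bit-for-bit across runs and
machines.

Geometry notes: axis lengths, eccentricity and elongation derive from the
moment-equivalent ellipse (4·√eigenvalue of the coordinate covariance);
perimeter uses weighted border-pixel counting (weights 1, √2, (1+√2)/2 by
local boundary direction); convex area counts lattice points in the pixel
convex hull exactly via Pick's theorem. GLCM and GLRLM accumulate at
distance 1 over the four standard 2-D directions and average the
per-direction feature values; GLDM uses the 8-neighborhood with dependence
tolerance 0; GLSZM zones are 8-connected equal-level regions. Degenerate
single-level regions take analytic limits (contrast 0, joint energy 1) and
correlation-type features are `NA`.

The fluorescent channel is read through the *brightfield-derived* masks.
Because the two channels are acquired sequentially, a cell may shift
slightly between them; rather than re-segmenting, all zero-intensity pixels
are excluded from fluorescent feature computation (the background is
(near-)zero, so a shifted mask simply contributes fewer, still-valid
pixels). Vesicle erasure happens before normalization and feature
computation; erased pixels are zeros and fall under the same exclusion.
Brightfield features use all in-mask pixels — the exclusion rule is
motivated by channel shift over zero background, which brightfield does not
have. Cells touching the field border are kept (partial visibility shows up
in the features themselves); `drop_border = TRUE` removes them.

## Annotation and classification

`sample_for_annotation()` draws a plain uniform sample without replacement
(optionally balanced per image) and writes single-cell crops (mask bounding
box + 8 px margin) named by cell id, so an expert can fill in the label
table. `merge_labels()` splits features into labeled/unlabeled partitions
and reports unknown ids without aborting.

`automl()` searches three interpretable tree families — decision tree
(`rpart`), random forest (`ranger`), gradient-boosted trees (`xgboost`) —
with 25 sequential trials each (75 trained configurations by default).
Each trial is scored by mean balanced accuracy over a 5-fold
cross-validation partition; balanced accuracy (mean per-class recall) is
the objective because cell-type data is routinely imbalanced, and
inverse-class-frequency weights (normalized to mean 1) enter fitting as
per-sample weights for the same reason. Partitions are either stratified
random (fold sizes differ by ≤ 1) or image-grouped (whole images assigned
to folds greedily balancing per-fold class counts), so that cells from one
field never straddle training and validation — the grouped mode estimates
generalization to unseen fields.

Search spaces (package decisions, sized for datasets of a few hundred
cells): tree depth 2–20 and minimum leaf 1–20; forest 50–500 trees, depth
2–20, feature-subsample fraction 0.1–1.0; boosted trees 50–500 rounds,
learning rate 10⁻³–0.3 log-uniform, 7–127 leaves. The per-family
optimizer spends 5 of the 25 trials on uniform random warm-up (a
convention, not a claim about any reference implementation), then
maximizes expected improvement under a Gaussian-process surrogate
(squared-exponential kernel, length-scale 0.25 on the unit-scaled space,
standardized scores, 256 random candidates per step). Ties between trials
break toward the earlier index, making the whole search reproducible under
a fixed seed. Missing feature values are median-imputed per training fold;
the final model refits on all labeled cells with full-data medians stored
in the bundle.

Importances are impurity-decrease (information gain) for the decision tree
and random forest and split counts for the boosted trees, all normalized
by the maximum so the top feature scores exactly 1 — rankings, not absolute
magnitudes, are the interpretable object.

## The synthetic generator: what it emulates and what it does not

All tests and the acceptance benchmark run on `render_field()` /
`render_benchmark()` output: fields of four RBC phenotypes with full ground
truth (masks, vesicle centers, labels). Default study conditions: fields of
768 × 1024 px holding 30 non-overlapping cells (12 discocytes, 6
echinocytes, 6 stomatocytes, 6 sickles) of radius 32–42 px. The field/cell
scale follows the imaging regime the vesicle constants were determined for
(×100 objective, cells spanning tens of pixels of *interior* depth): with
much smaller cells the context annulus (`c = 8`) would reach outside any
interior point, which no parameterization of the detector could survive.

Phenotype geometry mirrors the morphological axes the features are meant
to separate: discocytes are discs with a bright central pallor;
echinocytes carry 7 sinusoidal spicules of relative amplitude 0.16 (lower
solidity — the direction real echinocytes show); stomatocytes have an
off-center dark slit; sickles are curved capsules — all pixels within
0.3 R of a circular arc — giving high eccentricity with rounded ends. The
generator asserts only its own orderings (sickle eccentricity above
discocyte, echinocyte solidity below discocyte); it claims nothing about
real cells.

The fluorescent channel has an *exactly zero* background (deliberate: it
exercises the zero-pixel exclusion rule), an in-cell baseline of 60 with a
linear ramp dropping 3.2 units over the outermost 16 px of boundary depth,
Gaussian noise of sd 0.5, and Poisson(1) planted Gaussian spots per cell
(peak 120, sd 1.8 px, centers ≥ 2c = 16 px apart and ≥ 5 px inside the
mask). The ramp encodes the detector's own operating assumption: in-cell
non-vesicle contrast stays below `t = 1` (the interior is flat to within
~0.6 over any ball/annulus pair) while every near-membrane pixel has
strictly brighter neighbors inward (so membrane pixels are never local
maxima and the zero background never enters a candidate's annulus).
Brightfield noise is sd 5 on a background of 200 with cells at 120.

What the generator does **not** emulate: photon (shot) noise and detector
gain, focus drift, overlapping or touching cells, channel misalignment,
staining variability, and intensity textures inside real cells. Passing
tests therefore demonstrate algorithmic correctness under the stated
contrast model — not robustness to the full physics of microscopy. The
paper-scale constants (`m, d, v, c, t`) are dataset-dependent and must be
re-tuned on real imagery.

## Numerical choices and degenerate inputs

* Coordinates are 1-based `(row, col)`; RGB collapses with BT.709 luma
  weights (0.2125, 0.7154, 0.0721) so texture values are identical across
  readers.
* Constant images: segmentation returns an empty set; `local_maxima()`
  returns nothing (strict-excess guard); normalization maps to zero.
* An all-zero fluorescent cell region yields `NA` fluorescent features and
  records how many pixels were excluded.
* Detection-score ties in AP ranking break by larger mask area, then id;
  AutoML trial ties break by earlier index; both for determinism.
* The Hungarian matcher pads rectangular problems internally; empty point
  sets match to nothing with zero cost; empty predictions score precision
  1 by convention (no false positives were asserted).
* All randomness (generator, partitioning, sampling, search) flows from
  explicit integer seeds; per-field seeds derive as `seed + 101 * i`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script are sized for a single CPU:
the planted-spot benchmark uses 20 default fields (~600 vesicles); the
classifier audit uses 150 labeled cells over 5 fields with the full
75-trial search; property tests use small crafted fixtures (≤ 6 instances
for the average-precision oracle, 100 seeds for the leakage check). These
sizes are the package's reference conditions; larger studies scale
linearly in fields and cells.

## Known limitations

* The classical backend assumes dark cells on a bright, roughly uniform
  background; it is a desk-scale and fallback solution, not a replacement
  for a trained detection model on difficult smears.
* Texture features at a single distance/angle set; multi-distance GLCM
  variants are out of scope.
* The vesicle detector reports counts and centers only — no size or
  Ca²⁺-capacity quantification.
* Grouped cross-validation balances class counts greedily; with very few
  images per class the folds can be uneven (a warning is raised when a
  class has fewer members than folds).
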