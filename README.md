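# rbcprofiler

Interpretable single-cell profiling of red blood cells (RBCs) in paired
brightfield / fluorescent (Ca²⁺, Fluo-4) microscopy fields, for
hematology researchers who need per-cell morphology at scale without
hand-tuned image pipelines: segmentation, vesicle detection, a fixed
catalog of 135 hand-crafted features, annotation support, and automated
training of tree classifiers that explain themselves through feature
importances.

## What it computes

* **Segmentation** behind a pluggable backend contract. The built-in
  classical backend (Otsu threshold on the smoothed inverse brightfield →
  hole filling → distance-transform watershed → debris removal) runs
  anywhere; trained detection models can be plugged in via
  `function_backend()`. Quality is scored by COCO-style mask average
  precision: detections ranked by confidence, greedily matched one-to-one
  at mask-IoU ≥ τ, AP = area under the all-points-interpolated
  precision–recall curve.
* **Vesicle detection** in the fluorescent channel. With `U_r(x,y)` the
  strict L1 ball of radius `r`, candidates are local maxima of the
  median-filtered image over `U_d`, and a candidate is a vesicle when

  `mean I[U_v(x*,y*)] − t  >  mean I[U_c(x*,y*) \ U_v(x*,y*)]`

  on the original intensities (defaults `m = 3, d = 10, v = 4, c = 8,
  t = 1`). Detected vesicles are assigned to the cell whose mask contains
  them, counted as the feature `ca2+_number_of_vesicles`, and erased
  (`I ← 0` on `U_v`) before fluorescent intensity/texture features are
  computed.
* **Features** per cell: 14 shape (area, perimeter, axis lengths,
  eccentricity, solidity, …), and per channel 18 first-order intensity
  statistics plus 42 texture statistics from the gray-level co-occurrence
  (15), dependence (7), size-zone (9) and run-length (11) matrices —
  135 columns with both channels, 74 brightfield-only. Fluorescent
  features exclude zero-intensity pixels (zero background tolerates the
  slight channel-to-channel cell shift).
* **Classification** via AutoML: 25 Bayesian-optimization trials for each
  of three tree families (decision tree, random forest, gradient-boosted
  trees) — 75 trained configurations — scored by mean balanced accuracy
  over stratified or image-grouped 5-fold cross-validation with
  inverse-class-frequency sample weights; the best model refits on all
  labeled cells and reports importances normalized so the top feature
  scores exactly 1.
* **Synthetic benchmark**: `render_field()` generates fields of
  discocytes, echinocytes, stomatocytes and sickle cells with ground-truth
  masks, planted fluorescent vesicles and class labels, so every stage is
  testable without any external data.

## Worked example

```r
library(rbcprofiler)

f <- render_field(synthetic_spec(seed = 42), "demo")   # one synthetic field
inst <- segment(f$brightfield)                         # classical backend
mask_ap(list(inst), list(f$instances), 0.5)
#> <ap_result> AP = 1.0000 at IoU >= 0.50 (30 truth, 30 predictions)

feats <- extract_features(f$brightfield, f$fluorescent, inst)
dim(feats)                                             # 30 cells x (2 + 135)
round(feats[1:3, c("shape_eccentricity", "shape_solidity",
                   "intensity_mean_fl", "ca2+_number_of_vesicles")], 3)
#>   shape_eccentricity shape_solidity intensity_mean_fl ca2+_number_of_vesicles
#> 1              0.060              1           156.920                       2
#> 2              0.053              1           156.580                       1
#> 3              0.049              1           157.327                       3

vs <- detect_vesicles(f$fluorescent, f$instances)
score_detection(point_set(as.matrix(vs$centers[, c("row", "col")])),
                f$vesicles)
#> precision 1.000, recall 1.000 over 23 planted vesicles
```

The segmentation AP of 1.0 says every one of the 30 generated cells was
recovered above the IoU threshold; eccentricity near 0 and solidity 1
identify the first rows as discocytes; `intensity_mean_fl` is the mean
Fluo-4 signal inside the (normalized, vesicle-erased) cell; the last
column counts detected Ca²⁺ vesicles per cell.

For a full labeled run: `sample_for_annotation()` → fill in the label
CSV → `merge_labels()` → `make_partition()` → `automl()` →
`predict_unlabeled()`. The same steps are scriptable from a shell via
`exec/rbcprofiler <step> --key value ...` with steps `synth`, `segment`,
`extract`, `annotate`, `classify`, `eval-seg`, `eval-vesicles`.

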