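# thermoprick

Automated reading of skin prick tests (SPT) from paired visible-spectrum and
thermal forearm images.

An SPT introduces allergen drops through small skin punctures; after ~15
minutes a positive site shows a wheal and — because the reaction is driven by
histamine-induced perfusion — a localized hyperthermic spot that long-wave
infrared imaging records directly. For examinations that photograph the whole
forearm in two pixel-correlated spectra before and after application,
thermoprick automates the read-out for allergology research groups working
with such devices:

* **Segmentation** — a U-Net finds the eight highlighter-marked application
  fields per forearm (2 × 4 grid; square = histamine control); candidate
  contours are filtered by marker-sized bounding boxes and partially detected
  grids are completed by a pitch-vector heuristic.
* **Registration** — the pre-application thermal image is aligned to the
  post-application one from the matched marker sets, either by a least-squares
  homography (normalized DLT) or by a rigid transform derived from
  total-least-squares lines fitted through each marker set, and subtracted to
  form a **delta thermal image** `Δ(x) = T_post(x) − T_pre(w(x))` (°C) that
  isolates reaction-induced warming.
* **Classification** — each site becomes a sample: a 300 × 300 visible ROI, a
  delta-thermal ROI at the same coordinates, and four interview attributes
  (sex, age, weight, body temperature). A CNN (eleven 3 × 3 convolutions with
  batch norm and LeakyReLU, channels 32–256, six 3 × 3/stride-2 average pools,
  attributes fused into a 64-unit dense head) outputs `P(reaction)`, trained
  with AdamW (lr 0.001, decoupled weight decay 1e-4) under cross-entropy with
  paired augmentation (flips, ±45° rotation, ±4 px translation, ≤1.3× zoom,
  each with probability ½, identical transforms for both image channels).
* **Evaluation** — patient-grouped k-fold or leave-one-out cross-validation
  (all of a patient's sites stay in one fold), ROC AUC, average precision,
  and accuracy at the F1-optimal threshold, plus the input-spectra ablation
  (both / thermal-only / visible-only).

Clinical image sets of this kind are not public, so the package includes a
synthetic forearm generator with exact ground truth (marker centres,
inter-series rigid transform, per-site labels, reaction bump parameters) used
as the test bed for every stage. No deep-learning framework is required: the
convolutional engine (convolution as shifted BLAS GEMMs, pooling, batch norm,
Adam/AdamW, backprop) is compiled into the package and verified against
finite differences in the test suite.

## Worked example

Simulate one forearm, align its thermal series from the marker grid, and
inspect the per-site delta signal:

```r
library(thermoprick)

cfg  <- scene_config(seed = 42)          # half-resolution forearm, 2x4 grid
case <- generate_case(cfg, patient_seed = 1)
case
#> <synthetic_case P1_L: 8 sites, 2 positive, 0 dropped markers>

pre  <- segments_from_annotations(case$annotations)
post <- segments_from_annotations(case$annotations_post)
ad   <- align_and_delta(case$pre$thermal, case$post$thermal, pre, post,
                        method = "homography")
round(attr(ad$transform, "residual_rms"), 4)   # marker reprojection, px
#> [1] 0

# mean delta (degC) over a 48 px window at each site, against the truth:
sapply(seq_len(8), function(i) {
  roi <- extract_roi(ad$delta$pixels, post[[i]]$center, 48)
  round(mean(roi), 2)
})
#> [1] 0.00 0.00 0.00 0.00 0.00 0.62 0.53 0.00
case$site_meta$label[order(case$site_meta$line, case$site_meta$pos)]
#> [1] 0 0 0 0 0 1 1 0
```

The two positive sites (the histamine control and one reacting allergen
here) carry a clear mean warming in their delta ROI; negative sites sit at
the noise floor. The evaluation metrics work on any scored sample set:

```r
labels <- c(1, 0, 1, 0, 0, 1)
scores <- c(0.9, 0.2, 0.45, 0.4, 0.6, 0.8)
eval_report(labels, scores)
#> <eval_report: n 6, AUC 0.889, AP 0.917, acc 83.33% @ thr 0.450>
#>           predicted
#> true       negative positive
#>   negative        2        1
#>   positive        0        3
```

`run_pipeline(pipeline_config(...))` chains simulate → segment → align →
train → evaluate into one reproducible run with a manifest, and
`inst/scripts/thermoprick.R` exposes the same stages as a command-line tool
(`simulate`, `segment`, `align`, `run-all`).

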