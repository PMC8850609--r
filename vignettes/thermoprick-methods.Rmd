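---
title: "Reading skin prick tests from paired visible and thermal images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading skin prick tests from paired visible and thermal images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The reading problem

A skin prick test (SPT) introduces allergen drops through small punctures on
the forearm and is read about 15 minutes later. A positive site develops a
wheal, and — because the reaction is driven by histamine-induced perfusion —
a localized hyperthermic spot that long-wave infrared (LWIR) imaging captures
directly. thermoprick implements an automated reading pipeline for
examinations that record the whole forearm in two pixel-correlated spectra
(visible RGB and per-pixel temperature in °C) at two time points, before and
after allergen application, together with basic interview data (sex, age,
weight, height, body temperature).

Eight application fields are marked on each forearm with a highlighter — a
2 × 4 grid of circles, with a square for the histamine positive control —
and each forearm also carries a negative (diluent) control. The pipeline
turns a forearm examination into eight per-site decisions:

1. **Segmentation** — find the eight marked sites on the visible image
   (U-Net, contour filtering, grid completion).
2. **Registration** — align the pre-application thermal image to the
   post-application one using the marker sets, and subtract to form a
   *delta thermal image* that isolates reaction-induced warming.
3. **Classification** — for each site, feed a visible ROI, a delta-thermal
   ROI and four patient attributes to a convolutional classifier.
4. **Evaluation** — patient-grouped cross-validation with ROC AUC, average
   precision, and accuracy at an F1-optimal threshold.

Clinical datasets of this kind are not public, so the package ships a
synthetic forearm generator with exact ground truth; every stage is
validated end-to-end against it.

## Segmentation

**Masks.** Manual annotations store two points per site: the injection point
and one point on the marker edge. `annotations_to_mask()` renders each site
as a filled disc of radius equal to the distance between the two points.
Square histamine marks are deliberately rendered as discs too — a
simplification that the downstream bounding-box filter absorbs.

**Model.** `build_unet()` is a classic encoder–decoder with skip
connections: two 3 × 3 same-padding convolutions with ReLU per level, 2 × 2
max pooling down, ×2 nearest-neighbour upsampling followed by a 3 × 3
convolution, skip concatenation and two further convolutions up, and a 1 × 1
sigmoid head. Default widths are 64–1024 over four levels, the original
recipe; the constructor exposes `base_width` and `depth` because the
synthetic marker task is far easier than general biomedical segmentation and
trains well at a fraction of the width. Training (`train_unet()`) minimises
pixel-wise binary cross-entropy with Adam at the framework-default learning
rate 0.001 for a fixed 30-epoch budget, on images downscaled to 512 × 385
(half the native 1024 × 770; width × height) with intensities in [0, 1].

One numerical choice matters at desk scale: the output bias is initialised
at the foreground log-odds of the training masks. Marker pixels are ~5% of
skin, and with Adam's per-parameter step size bounded by the learning rate,
a zero-initialised bias would consume most of a short step budget merely
drifting to the class prior. Prior-initialisation removes that transient; it
changes nothing about the optimum.

**Contours.** Predicted masks are binarised at 0.5 (the natural operating
point of a sigmoid trained with BCE), 4-connected components are labelled,
and bounding boxes are filtered by size and aspect ratio
(`contour_filter()`). The only quantitative anchor for "marker-sized" is the
observed segment statistics — mean box side 85 px, σ = 6, range 60–104 at
native scale — so the default range widens that by ~10% to [54, 114], scaled
by `image_width / 1024` so the same filter works at any resolution. The
aspect-ratio window [0.6, 1.67] accepts modestly elongated boxes.

**Grid completion.** When fewer than eight markers survive filtering,
`complete_grid()` reconstructs the rest in three steps.

*Positions.* Detected segments are split into two lines at the midpoint of
the row range, and the minimal-length displacement vector between
column-adjacent detections serves as a provisional pitch to assign each
detection a column position by rounded offset from the right side. Two
readings of "minimal-length vector" are possible — within-line neighbours
only, or the global minimum over all pairs — and both are implemented
(`pitch` argument); within-line is the default.

*Anchor.* The right-side reference is the rightmost detected marker across
both lines (anchoring each line at its own rightmost detection would shift
a whole line whenever that marker is the missing one). One ambiguity
remains: if the rightmost marker of *both* lines is undetected, no
relative reference can distinguish positions 1–3 from 2–4. The application
protocol centres the grid on the forearm frame, so when the caller passes
the image size (the pipeline always can) the anchor whose completed grid
sits most symmetrically in the frame is chosen.

*Infill.* Missing slots are synthesised from a least-squares fit of the
regular-grid model — per-line two-dimensional intercept plus a pitch
vector shared across lines — over all detected centres, with the median
detected box size and provenance `"inferred"`. A single minimal-length
vector is kept for position *assignment*, where only the rounded step
count matters, but deliberately not for *infill*: the minimum over
several jittered neighbour gaps is biased short by most of the jitter
amplitude, while the pooled fit averages per-marker jitter away. Under
the generator's ±5 px placement jitter this is the difference between
~50% and ~97% of dropped centres recovered within 10 px; the residual
error is dominated by the dropped marker's own unknowable jitter.

Fewer than four detections, or all in one line, is an unrecoverable grid:
the caller falls back to manual annotations (`segment_image()` automates
this fallback and reports it).

## Registration and delta images

Marker sets are matched across series by grid index (`match_markers()`) —
the only reliable key, since nearest-neighbour matching fails exactly in
the large-motion cases alignment exists for. Two estimators are provided:

* `estimate_homography()` — a least-squares homography via the normalized
  direct linear transform over all eight correspondences, without robust
  reweighting (outliers are handled upstream by grid completion).
* `estimate_rigid_lines()` — the lower-degree-of-freedom technique: fit a
  least-squares line through each marker set, rotate by the difference of
  line angles, and translate so the pre centroid's projection lands on the
  post line. The line fit is total least squares (the principal axis).
  An ordinary row-on-column regression is not rotation-equivariant — the
  fitted line of a rotated 2 × 4 grid is not the rotated fitted line — so
  it cannot recover even an exact rigid motion; the orthogonal-distance
  fit can, and needs no special casing for vertical lines. "Minimising the
  distance between the two lines" is interpreted as perpendicular
  point-to-line alignment; the along-line component, which line distance
  leaves free, is fixed by matching centroid projections.

`warp_thermal()` inverse-maps each output pixel through the transform with
bilinear interpolation; pixels without source support are zero and flagged
in a validity mask. `delta_image()` subtracts (post − pre, so warming is
positive) and zeroes invalid pixels rather than using a sentinel, so ROI
crops need no special casing.

Expected numerical behaviour, used as test tolerances: bilinear
interpolation of a smooth field f has error ≤ max|f″|·h²/8. For the
synthetic reaction bump (amplitude ~1.5 °C, σ ~12 px) this is ~1.3 × 10⁻³ °C,
so aligned-delta residuals are asserted below 5 × 10⁻³ °C pointwise and
10⁻³ °C on average over negative forearms — not at machine precision, which
no interpolating warp can reach. For transform recovery under detection
noise, each marker centre is perturbed disc-uniformly by up to 0.5 px in
each series (≤ 1 px relative correspondence error); under that noise the
homography reprojects to ~0.35 px RMS and the rigid fit recovers rotation
to well under half a degree. Noise on both series with magnitude up to
1 px each would put an irreducible σ·√(p/N) ≈ 0.7 px floor under *any*
least-squares homography — a useful reminder that eight correspondences
fit eight projective parameters closely.

## Classification

**Samples.** For each site, a 300 × 300 ROI is cut from the post-series
visible image, centred on the segment centre, and the delta ROI is cut *at
the same coordinates* (the spectra are pixel-correlated; segments are found
on the visible image). Out-of-bounds area is zero-padded. The visible
channel comes from the post series because wheals only exist after
application. Attributes are sex (0/1), age, weight and body temperature —
height is recorded in the interview but not fed to the classifier.

**Normalisation.** Image channels are standardised by per-channel mean and
standard deviation; attributes are min–max rescaled to [0, 1] without
clipping. All statistics come from the training patients of the current
fold only, and `fit_norm_stats()` records which patients contributed so
leakage can be asserted against mechanically.

**Augmentation.** Horizontal/vertical flips, rotation up to 45°,
translation up to 4 px and zoom up to 1.3× — each applied independently
with probability 0.5, parameters uniform, and the *same realised chain*
applied to the visible and delta channels of a sample
(`augment_pair()`). Augmentation happens after normalisation with zero
fill, so filled border pixels sit at the training-channel mean. Fresh draws
are made every epoch.

**Network.** The convolutional trunk follows the published plan: eleven
3 × 3 convolutions with output channels 32, 64, 64, 128, 128, 256, 256,
256, 256, 256, 256, each followed by batch normalisation and LeakyReLU
(slope 0.01), with 3 × 3 stride-2 average pooling after convolutions 1, 2,
5, 7, 9 and 11. Convolutions use same padding; pooling uses none, giving
the spatial trace 300 → 149 → 74 → 36 → 17 → 8 → 3, so the flattened
features number 256·3·3 = 2304. The four attributes are concatenated there
and pass through a 64-unit dense layer, LeakyReLU, 0.5 dropout and a final
dense layer. Input channels are 4 (visible + delta fused), 1 (delta only)
or 3 (visible only) by `input_mode`.

The published description is contradictory about the head: a "single
output channel" cannot carry a softmax (softmax of one logit is constant).
The default head is a single logit with sigmoid and binary cross-entropy —
mathematically identical to a two-way softmax with cross-entropy — and a
two-logit softmax head is available (`head = "softmax2"`).

**Optimisation.** AdamW: Adam (lr 0.001) with decoupled weight decay 10⁻⁴
applied to convolution and dense weight tensors but not biases or
batch-norm parameters, the usual decoupled-regularisation practice. The
"early stopping" rule is a fixed 80-epoch budget — the model overfits only
gradually, so the exact stopping epoch is not critical — with no
validation-patience machinery. Batch size defaults to 32; both are
configuration, not architecture.

**Desk-scale profile.** `classifier_config(profile = "reduced")` keeps the
same layer pattern but with small ROIs and a truncated plan (e.g. 48 px
ROIs through 8-16-32 channels) for synthetic-cohort experiments; the full
300 px architecture remains the default profile.

## Evaluation

`make_patient_folds()` shuffles patients by seed into k near-equal groups
(LOOCV = one patient per fold); every sample of a patient stays in one
fold, so a model never sees another site of a test patient's forearms nor
their attributes. Per fold, normalisation statistics and the classifier
are fitted on training patients and the held-out patients are scored; all
held-out scores are pooled. ROC AUC uses the rank statistic (ties ½); AP
is the step-wise, non-interpolated recall-weighted sum of precisions; the
decision threshold maximises F1 over all midpoints between consecutive
unique scores plus the endpoints, with ties broken toward 0.5 (in practice
it lands near 0.5); predictions use ≥ (ties positive). The threshold is
selected on the pooled cross-validated scores and accuracy reported on the
same pooled scores — matching a single reported accuracy per configuration;
a nested per-fold selection would be stricter but is not the default.
`run_input_ablation()` repeats the cross-validation under each input mode
with identical folds, and the pipeline adds a ground-truth-segmentation
("manual") reference row.

## The synthetic generator

`generate_case()` renders the scene as an *analytic function* of
continuous coordinates — skin tone with low-frequency sinusoidal texture,
ink rings (one square), hair as dark/cool streaks, vessels as warm ridges,
reactions as isotropic Gaussian temperature bumps truncated at 4σ — and
the post series is the same function observed through the inverse of a
random rigid pose change (rotation ≤ 5°, translation ≤ 15 px by default).
Because nothing is rasterised and re-warped, ground truth is exact: the
true transform maps pre marker centres onto post centres to machine
precision, and with zero noise and zero pose change the thermal delta of a
negative forearm is exactly zero outside bump support.

Defaults describe the emulated protocol at half resolution (385 × 512):
marker radii 19–24 px so detected boxes match the observed native-scale
statistics; positional jitter ±5 px; hotspot amplitude 1.5 °C with σ
12 px against 0.05 °C pixel noise (no quantitative reaction amplitude is
published; 1–2 °C gives clean SNR and is a benchmark parameter, not a
clinical claim); hive (wheal) contrast 0.08 in visible units — deliberately
low, reflecting how subtle wheals are against skin, which is what makes the
visible-only configuration the weakest; prevalence 0.3 for non-control
sites, matching the reported ~31.6% positive share; histamine forced
positive and the negative control forced negative, mirroring their
clinical roles; marker dropout 0.1 rendering ink at unreadable contrast in
both series. Patient attributes are drawn uniformly from adult ranges.

What the generator does **not** model: photorealistic skin, perfusion
physiology, blood-flow displacement of reactions away from the injection
point, non-rigid forearm deformation, or camera effects. Tests passing on
this bench therefore demonstrate that the pipeline's machinery — mask
learning, grid reasoning, alignment, delta contrast, grouped evaluation —
is correct and well-calibrated, not that real-world clinical performance
is reproduced; the published headline metrics come from a private dataset
and are out of reach by construction.

## Desk-scale problem sizes

The test-bed sizes are package choices made once: segmentation quality is
benchmarked with a width-4, depth-3 U-Net trained 30 epochs on 40 half-size
forearms and evaluated on 10 more (median per-site IoU ≥ 0.8);
classification with a 40-patient cohort under 5-fold patient-grouped CV at
48 px ROIs (thermal-only AUC ≥ 0.95, visible ≤ fused); registration
recovery with 100 synthetic transform draws; grid completion with 500
grids; metric implementations against exhaustive enumeration on 1000 random
instances. The acceptance script runs the same computations at smaller n
(16 train images; 16 patients, 3 folds) and records each n alongside its
value.

## Known limitations

* The NN engine is single-threaded CPU code; the full 300 px architecture
  is practical for inference and short fine-tuning, not for large-scale
  training experiments.
* Grid completion assumes the 2 × 4 protocol; other layouts would need a
  different completion heuristic.
* The rigid-lines estimator constrains rotation through one fitted axis,
  so its rotation error grows faster with marker noise than the
  homography's; both are exact on noise-free rigid motions.
* Synthetic hives are the only visible-spectrum signal; real wheals also
  displace texture and cast shading, which the generator does not attempt.
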