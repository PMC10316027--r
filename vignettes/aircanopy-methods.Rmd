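---
title: "Methods: aerial wheat canopy phenotyping with aircanopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aerial wheat canopy phenotyping with aircanopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what the synthetic-scene tests
do and do not establish.

## The analysis problem

A drone hovering a few metres above a wheat breeding trial photographs one
1.5 m × 1.5 m plot per frame, with fragments of neighbouring plots at the
frame edges. Estimating yield potential from such imagery needs three
stages: isolate the central plot (its neighbours belong to different
varieties), count spikes inside it to get spike number per square metre
(SNpM², a primary yield component), and extract canopy-level spectral and
textural traits that correlate with performance. A classifier over those
traits then assigns varieties to high/medium/low yield groups.

## Plot segmentation

The segmenter follows the YOLACT design: a convolutional backbone with a
feature pyramid (levels P3–P7, channel width shared), a ProtoNet branch
producing `k` non-negative prototype masks from P3, and a prediction head
that, at every pyramid location, emits 5 anchors (aspect ratios 1, 1/2, 2,
1/3, 3; one scale per level, pinned at 3× the level stride), each with a
class score, a box regression (SSD-style encoding, variances 0.1/0.2) and
`k` mask coefficients in (−1, 1) via tanh. Fast NMS — suppression by *any*
higher-scoring detection, one matrix operation — screens candidates; the
final mask is `sigmoid(Σ_j c_j P_j)` bilinearly upsampled, cropped to the
detection box and thresholded strictly at 0.5. The threshold is fixed at
0.5 because the sigmoid output is a per-pixel posterior; no other
"auto-threshold" is defined here.

The backbone augments each residual stage (C3–C5) with a Res2Net-CBAM
block: the input channels split into four equal sub-graphs, sub-graph
*i* ≥ 2 is 3×3-convolved on its own split plus the previous sub-graph's
output (hierarchical receptive-field growth), a 1×1 convolution fuses the
concatenation, CBAM applies channel then spatial attention to the fused
map — the channel branch pools globally by average *and* max, passes both
through one shared two-layer perceptron with reduction `C/r` (default
r = 16; smaller in desk profiles where channels are narrow) and gates by
the sigmoid of the sum; the spatial branch pools across channels by mean
and max and gates by the sigmoid of a 7×7 convolution — and a residual
connection adds the block input. CBAM sits after the fusion convolution
and before the residual add, mirroring its use in residual networks; the
gate symbols follow the convention that the spatial weights are `Ms`
(one printed source uses `Mc` for both, but only `Ms` makes the spatial
product `F″ = Ms × F′` well-typed).

**Central-plot rule.** Among detections at or above the score threshold,
the one whose mask centroid is nearest the image centre wins; ties break
by score, then index. Absence is a flagged result, not an error, so batch
runs degrade gracefully.

**Training.** SGD with momentum 0.9 and learning rate 0.001 are the
working defaults; the composite loss is anchor-classification binary
cross-entropy (hard-negative mining at 3:1), smooth-L1 box regression on
positive anchors, and mask binary cross-entropy at prototype resolution
against the block-averaged ground-truth mask, weighted 1:1:1 (no source
of imbalance justified anything else). Desk-scale runs use batch size 1
and learning rate 0.003: with four scenes to overfit, more frequent
updates converge in fewer wall-clock minutes than the batch-8 default.

## Spike detection

Spikes are small, dense, bright objects, so the detector is a one-class
anchor grid in the YOLO family: a strided trunk with heads at strides 4,
8 and 16, three anchors per cell, per-anchor outputs (tx, ty, tw, th,
objectness) with the usual decode (sigmoid cell offsets, exponential size
factors clamped to ±4). Sequential (greedy) NMS is used here — the
convention of this detector family — while the plot stage uses Fast NMS,
the convention of its own lineage.

Plot crops are *letterboxed* onto the detector input (placed at native
scale, downscaled only if too large): resampling a crop up to the input
size would inflate spike geometry away from the anchor ladder, which at
desk scale is pinned to the rendered spike hulls ((11,11), (13,6), (6,13)
px at stride 4, doubling per scale).

Two supervision details matter in dense scenes and were settled
empirically on synthetic plots before the tests were frozen:

* every unassigned anchor is supervised as background with a small uniform
  weight, **plus** extra weight concentrated on the currently
  highest-scoring negatives (≈3:1 to positives). Uniform-only pressure
  leaves per-anchor gradients ~150× weaker than the positives and
  convergence stalls; mining-only oscillates ("whack-a-mole");
* in a cell that owns a ground truth, the two unassigned anchor slots are
  explicit negatives. Left unsupervised they fire as duplicates whose
  unconstrained box sizes NMS cannot merge.

`SNpM² = count / plot_area_m2`, default area 2.25 m² (a 1.5 m square
breeding plot), overridable per record.

An overfit desk detector is *phase-sensitive*: shifting the crop origin by
a non-multiple of the stride changes sub-cell alignment and degrades the
memorized objectness map, which matters end-to-end because a predicted
plot mask crops at a slightly different origin than the ground-truth crop
the detector trained on. Two mitigations exist: the pipeline dilates the
predicted mask a few pixels before masking the detector input
(`mask_dilate_px`, default 4), so boundary spikes are not clipped, and
`train_spike_detector()` exposes a translation-jitter option (several
letterbox origins cycled over iterations). Jitter is off by default at
desk scale: in our experiments it buys shift tolerance at the price of
slower per-phase convergence, leaving counts biased high within the same
iteration budget, and the desk validation evaluates ground-truth-aligned
crops where no shift occurs.

## Trait engine

Spectral indices use chromatic coordinates `r = R/(R+G+B)` etc., so all
three are invariant to uniform illumination scaling: `ExR = 1.4r − g`,
`NDYI = (G−B)/(G+B)`, `VARI = (G−R)/(G+R−B)` clipped to [−1, 1] because
its denominator can vanish on real pixels; ratio denominators carry
ε = 1e−6. The index formulas are the standard literature forms — the
application domain names the indices without printing formulas, and no
other reading is defensible. Canopy coverage thresholds `ExG = 2g−r−b`
with Otsu's method over the mask's own histogram, falling back to the
fixed rule `ExG > 0` when the histogram is degenerate (a pure canopy has
no soil mode to separate). GLCM texture uses 32 grey levels of BT.601
luma, distance-1 offsets at 0°/45°/90°/135°, symmetric counts averaged
over offsets and normalized; `ASM = Σ p²` (1 iff the quantized region is
constant) and dissimilarity `Σ p|i−j|` (0 iff the GLCM is diagonal).
Texture is the one trait family *not* invariant to illumination scaling
(quantization moves bin boundaries); this is documented rather than
asserted in tests.

## Detection evaluation

Greedy score-ordered matching at an IoU threshold (ties on score by
index, ties on IoU by truth index — determinism requires *some* rule),
precision `TP/(TP+FP)`, recall `TP/(TP+FN)` with degenerate denominators
flagged as 0, and AP as the area under the all-points-interpolated P(R)
curve. mAP averages IoU 0.50:0.05:0.95 (the COCO convention, matching how
AP50/AP75/mAP triples are reported in this field). One caution for users:
greedy matching is the field convention but is not maximum-cardinality
matching — an adversarial high-scoring prediction overlapping two truths
can starve a later prediction. The test suite pins the implemented rule
against an exhaustive enumeration of its definition and checks the
always-true bound against the optimal assignment, rather than pretending
the two coincide.

## Architecture accounting

Complexity is totalled over convolutional layers only: a `K×K` conv with
`Cin`→`Cout` channels carries `K²·Cin·Cout + Cout` parameters and costs
`Cin·K²·Cout·H·W` multiply-accumulates on an `H×W` output; biases and
activations are excluded from the operation count, and fully connected
layers count as 1×1 convolutions. A weight-shared head is counted once
for parameters but per application for operations.

The published totals this package reproduces (31.65 M params / 15.34 G
ops baseline; 33.86 M / 16.75 G with Res2Net-CBAM, at the 550-px input
padded to 576) come with no published layer table, and the genuine
full-scale YOLACT++/ResNet-101 architecture is several times larger on
both axes. The accounting configuration is therefore *pinned by
calibration*: a 33-bottleneck backbone (100 conv layers — the "101-style"
depth) with stage channels (48, 272, 320, 1040) and depths (2, 2, 3, 26),
FPN width 96, 16 prototypes, 5 anchors, and one Res2Net-CBAM replacement
at the head of each of stages C3–C5. The deep narrow C5 stage is what
reconciles the parameter total with the operation total (most parameters
must sit at 1/32 resolution for the printed ratio to close); the
Res2Net-CBAM placement is pinned the same way, since the replacement
count per stage is otherwise unspecified. `segnet_accounting_config()`
exposes every knob, and `segnet_layer_table()` returns the full layer
tibble so the convention is auditable line by line.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` renders a soil background with value-noise texture,
partial neighbour plots hugging the frame edges, a central textured-green
plot (optionally rotated), and bright yellow-green elliptical spikes with
random orientation, placed under a pairwise-separation bound; ground
truth (plot polygon, spike boxes, count) is exact by construction, and
images are 8-bit quantized so byte-identical determinism holds. The four
augmentation operators match the usual field-data recipe: luminance
scaling, rotation (annotation boxes become axis-aligned hulls of rotated
corners — VOC box semantics), salt-and-pepper impulse noise (the standard
reading of impulse-style photographic noise), and four-scene mosaic
composition with remapped, clipped annotations.

Desk-scale defaults — 160 px frames, a plot spanning ~55% of the frame,
40–60 spikes of 5–9 px major axis — keep one CPU training run inside a
few minutes while preserving the geometry that matters (dense small
objects inside a dominant central region). Real spike densities are an
order of magnitude higher per plot; rendering ~1000 distinguishable
spikes at 160 px is geometrically impossible, so synthetic SNpM² values
are desk-scale, not agronomic. What overfit-recovery tests establish is
that the losses, geometry transforms, decoders and NMS are mutually
consistent — a sign-flip anywhere stops recovery. They do not establish
field accuracy: synthetic scenes have no occlusion, no awns crossing
plot borders, no specular soil, no motion blur, and no varietal
morphology differences.

## Yield classifier

`simulate_yield_dataset()` draws Gaussian class clusters over the seven
traits with the 101/90/19 high/medium/low imbalance of a ~210-variety
trial; by default SNpM² (means 520/450/380, SD 22 per m²), NDYI (0.68 /
0.56 / 0.45, SD 0.035 — the high/low peaks observed in field
distributions) and ASM (descending 0.24/0.20/0.16) carry the signal at
~3 within-class SDs of separation, while ExR, VARI, coverage and
dissimilarity are pooled noise. The 7:3 split uses largest-remainder
stratification so 210 records give exactly 147/63 with preserved class
proportions. Grid search is the exhaustive Cartesian product (default
axes: trees 100/300/500, depth 3/5/7, learning rate 0.05/0.1/0.3, row and
feature subsampling 0.7/1.0 — the tuned quantities of gradient boosting;
values are conventional since none are prescribed) evaluated by
stratified k-fold CV accuracy, k = 5 by default, ties broken by grid
order, winner refit on all training data. Importances are gain-based and
normalized to sum 1. xgboost is pinned to one thread and seeded, so the
whole tuning pipeline is bit-reproducible.

## Numerical choices and degenerate inputs

* Internal box convention: 0-based half-open; VOC (1-based inclusive) and
  COCO conversions live only in readers/writers, and conversion is
  involutive.
* BCE on logits uses the `max(z,0) − z·t + log1p(exp(−|z|))` form; no
  overflow for any logit.
* Empty masks, empty truth sets, zero-variance references, k exceeding
  the smallest class, non-divisible attention channels: all are explicit
  typed errors (`aircanopy_validation_error`, `aircanopy_config_error`,
  …) rather than NaN propagation. Empty *prediction* sets are valid
  inputs wherever a count of zero is meaningful (AP 0, flagged precision).
* Problem sizes in the default test run: 4 scenes at 160 px plus one
  soil-only negative, 180 plot iterations and 650 spike iterations,
  210-record classifier datasets, exhaustive 512-case and ≤4-box oracle
  sweeps. These were chosen as the smallest sizes at which the recovery
  margins are comfortable, and are stated here so readers know what the
  default run demonstrates.

## Known limitations

* The autodiff engine is single-image; throughput is R-interpreter-bound
  at roughly half a second per desk-scale training iteration. The
  `standard` profiles are constructible and trainable but not sized for
  interactive use.
* Mask-AP uses polygon/box geometry only; run-length-encoded masks are
  out of scope.
* The accounting configuration reproduces published *totals*; it is not
  a claim about the published model's internal layer allocation.
* Trained desk models are scene-family-specific by design (overfit
  validation); nothing here ships pretrained field weights.
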