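---
title: "Lightweight attention-augmented underwater detectors: models, accounting, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight attention-augmented underwater detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udet)
```

## The problem

Optical imagery of benthic organisms — holothurians, echinus, scallops,
starfish — is hard for object detectors: the water column removes contrast
and reddens nothing (a green-blue cast), targets are small, blurred, and
often clustered, and their shapes vary strongly. At the same time the robots
that carry the cameras have little memory and compute, so the models must be
small. `udet` implements a family of lightweight one-stage detectors for
this setting: a YOLOv10n-style base network and three architectural
refinements that can be toggled independently, giving eight named variants
(`baseline`, `B`, `S`, `E`, `BS`, `BE`, `SE`, `BSE`):

* **B** — the neck is replaced by a single-round *bidirectional weighted
  feature pyramid*: every fusion node combines its inputs with learnable
  non-negative weights, \(O = \sum_i w_i I_i / (\epsilon + \sum_i w_i)\)
  with \(\epsilon = 10^{-4}\), the high-resolution P2 level joins the
  fusion, single-input nodes are removed, and skip edges connect the raw
  pyramid inputs to the output nodes.
* **S** — the plain C2f blocks of the neck become *S_C2f*: each bottleneck
  embeds a multi-scale attention synergy module (MASM) after its second
  convolution. MASM gates channels (average- and max-pooled descriptors
  through a shared two-layer 1×1 stack, sigmoid), then forms the elementwise
  product of a pixel-attention path (per-position sigmoid gate) and a
  spatial-attention path (5×5 depthwise base plus 1×K/K×1 depthwise strips
  for K ∈ {7, 11, 21}, mixed by one pointwise convolution).
* **E** — grouped *efficient multi-scale attention* (EMA) modules are
  inserted in backbone and neck: channels are split into groups; a 1×1
  branch re-weights each group from horizontal/vertical 1-D pooled
  descriptors, a 3×3 branch extracts local context, and a cross-branch
  softmax interaction builds a sigmoid-gated spatial map.

The package is written around its own array compute engine — a reverse-mode
tape over `(C, H, W)` arrays with Rcpp convolution/pooling kernels — because
every operator must be inspectable down to scalar arithmetic for the
equation-level tests, and the structural accounting must see exactly the
layers the forward pass executes.

## The base topology and one inherited block

The baseline follows the YOLOv10n inventory: CBS stem (conv–BN–SiLU),
C2f stages, spatial-channel decoupled downsampling (SCDown), SPPF (three
cascaded 5×5 max-pools, receptive fields 5/9/13), partial self-attention
(PSA, multi-head self-attention on half the channels), an FPN+PAN neck, and
a dual head: a one-to-many branch used during training and a one-to-one
branch decoded NMS-free at inference, with distribution-focal box
regression (`reg_max` = 16 bins per side). One detail matters for the
accounting: the base model's final neck stage is a C2fCIB — a C2f whose
bottleneck is a compact inverted block with a large-kernel (7×7 depthwise)
branch. We include it because the published parameter totals of this model
family are only reproducible with it; with a plain C2f there the baseline
would carry ≈0.21 M extra parameters.

## Accounting conventions

`count_parameters()` counts the *training-time* model: both head branches,
unfused batch-norm affine pairs, fusion weights, attention internals, and
the 16-entry fixed integration kernel of the distribution-focal decode.
This convention is what makes the baseline land at 2.71 M (the deploy-time
one-branch model would be ≈2.3 M). `compute_flops()` propagates shape
tokens through the same training-time graph and sums 2 × multiply-accumulates
over convolution layers only — the dialect of the profilers convention used
for this model family, in which pooling, activations, normalization and the
raw attention matrix products are not hooked. Rounding is half-up: two
decimals for millions of parameters, one decimal for GFLOPs.

```{r accounting}
variant_table(c("baseline", "B", "S", "E", "BSE"))
```

Against the published ablation column (2.70, 2.43, 2.73, 2.71, 2.47 M and
8.2 / 8.3 GFLOPs for baseline / full variant), the B, E and full-variant
totals and both GFLOPs figures agree exactly at the printed precision; the
baseline and S totals are 0.01 M above the printed values (2.71 vs 2.70,
2.74 vs 2.73), a residual we attribute to micro-differences between our
layer inventory and the authors' unpublished one.

## Calibrated wirings

Three structural choices are stated only pictorially in the source
architecture; we expose them in `model_config()` and fix defaults by
calibrating against the printed parameter and FLOP deltas:

* *Bidirectional neck wiring.* Fusion at native level widths
  (32/64/128/256), weighted-add (not concat). Nodes: P4-td and P3-td on the
  top-down pass, P3-out, P4-out, P5-out on the bottom-up pass. C2f blocks
  follow the P4-td, P3-out and P4-out fusions; P3-td and P5-out are
  fusion-only. Up edges carry pre-upsample 1×1 aligns; the P3/P4 skip edges
  carry 1×1 aligns; down edges are depthwise-3×3-stride-2 plus 1×1 lifts
  (the P4-out→P5-out edge lifts first, then downsamples). P2 joins the
  P3-out node through a down edge and has no output node of its own.
* *S_C2f placement.* The three plain C2f neck blocks become S_C2f; the
  C2fCIB stage keeps its inverted bottleneck (it has no standard bottleneck
  to host a MASM). This reproduces the printed +0.03 M delta; replacing a
  hypothetical fourth block as well would overshoot to +0.07 M.
* *EMA insertions.* Four modules with `groups = 8`: after the backbone's
  stage-2 (P2, 32 ch) and stage-4 (P3, 64 ch) C2f blocks, and after the
  neck's P3-level and P4-level output blocks. Early, high-resolution
  placement suits the small-object motivation and reproduces the printed
  +0.01 M / +0.2 GFLOP deltas; a post-PSA placement alone would give the
  right parameters but the wrong FLOPs.

MASM's hidden width (the two-convolution gating stacks) is
`max(1, C %/% 8)` with the average/max stacks shared — the equations reuse
one convolution symbol for both paths, and sharing is the reading consistent
with the printed parameter budget. No batch-norm is used inside MASM (only
ReLU and sigmoid appear in its definition); depthwise convolutions carry
biases, the pointwise mixer does not.

## The synthetic scene generator

No public underwater benchmark can ship with the package, so every pipeline
stage is exercised on synthetic scenes that emulate the documented
pathologies of the real imagery: low-frequency green-blue backgrounds,
contrast compression (`contrast`, default 0.35 — foreground pixels are
blended toward the background), Gaussian blur (`blur_sigma`, default 2 px),
additive sensor noise (`noise_sigma`, default 0.03), small objects
(`object_scale_range`, default 5–18 % of the image side), and clustered
placement (`cluster_factor`, default 0.7, drawing object centres around a
few cluster centres). Four parametric silhouettes stand in for the classes:
an elongated wavy blob, a spiked disc, a ridged fan with a rounded hinge,
and a five-armed star. The shapes are deliberately chunky so that the exact
pre-degradation mask fills at least 60 % of its tight bounding box for
nominal radii of 8 px and above; below that, pixel quantization of the
one-pixel box inflation dominates any geometry. Degradations are applied
after the boxes are recorded, so labels never move.

What passing tests on these scenes shows — and does not show: the generator
validates the *mechanics* (shapes flow, losses descend, a perfect predictor
scores mAP 1.0, an overfit run memorizes its training set). It does not
emulate real water-column optics, occlusion statistics, or biological
texture, so no accuracy number obtained on it transfers to real benchmark
performance; the published accuracy columns are out of scope here.

```{r scene, fig.width = 5, fig.height = 5}
scene <- generate_scene(scene_config(image_size = 320, n_objects = 8, seed = 7))
autoplot(scene)
```

## Training at desk scale

`train_demo()` is intentionally simple plumbing, not the published training
recipe (300 epochs, mosaic augmentation, SGD on GPU). It letterboxes the
images, assigns positives by center-in-box with a 2.5-stride
center-sampling radius for the one-to-many branch and a *top-1* assignment
(one anchor per ground-truth box, at the level whose stride best matches the
box size) for the one-to-one branch, and minimizes binary cross-entropy on
class logits plus an IoU loss (weight 5) on the distribution-expectation box
decode, with Adam at batch size 1. Because the engine always sees one image
at a time, its normalization layers are instance-style: per-map statistics
are used both during training and at inference (there are no running
moments), which keeps the train-time and eval-time functions identical. The
closed-loop check trains a narrow variant (channel plan 8/8/16/16/16,
`reg_max` 8, EMA groups 4) at 64×64 on 16 synthetic scenes drawn with larger
objects and milder degradation than the study-condition defaults — an
overfit sanity check needs a memorizable target, not a hard benchmark — and
requires train-set mAP@0.5 ≥ 0.9. Evaluation decodes the one-to-one head at
a 0.05 confidence floor (average precision is a ranking metric; a high floor
truncates the recall axis).

## Evaluation dialect

`map_summary()` pools detections per class over images, matches greedily in
score order (a detection is a true positive iff its best-IoU unmatched
same-class box reaches the threshold), and integrates the precision
envelope with 101-point interpolation — the COCO dialect, chosen because
the composite mAP@0.5:0.95 it reports is COCO's; a continuous-envelope mode
is available behind `method = "continuous"` and agrees within 0.01 on random
instances. Degenerate conventions are explicit: precision and recall are 1
when their denominators are zero, and classes without ground truth are
excluded from the class mean with a warning.

## Numerical choices and degenerate inputs

* Fusion weights are clamped at zero before use (fast normalized fusion),
  initialized at 1; all-zero weights return a zero map via the
  \(\epsilon\) guard rather than an error.
* Normalization uses \(\epsilon = 10^{-5}\) and per-map statistics in
  every mode (batch size 1 makes this instance-style normalization; a
  running-average eval mode was rejected because the per-image statistics
  it replaces differ strongly between scenes, degrading the very detections
  the training loss optimizes).
* The equation-level tests compare every attention operator against an
  independent loop-based scalar implementation at ≤ 4 channels and ≤ 8×8
  spatial extent, to 10⁻⁶ relative error in double precision.
* Same-padding strip convolutions make any H, W ≥ 1 legal in MASM; stride-2
  blocks halve odd sizes by ceiling division.
* Problem sizes in the test-suite are deliberately small — structural
  accounting runs at the full 640×640 configuration (shape tokens make it
  exact and instant), while numerical forwards run at 64–96 px and the
  overfit check uses 16 scenes and a narrow channel plan; these sizes are
  the package's chosen desk-scale study conditions.

## Known limitations

* The engine is single-image (batch 1); there is no GPU path, so the
  package audits architectures and runs desk-scale demonstrations rather
  than large-scale training.
* The exact wiring of the source architecture's figures is not published;
  our calibrated defaults reproduce the printed structural columns to
  ±0.01 M, but they are one of several wirings within that tolerance, and
  the ±0.01 M residuals on the baseline and S variants are documented
  above. The GFLOPs of the intermediate ablation variants (E, BS, BE, SE)
  deviate by 0.1–0.2 G from the printed column under our convention.
* The one-to-one decode keeps at most one detection per anchor with no
  cross-anchor suppression; with an undertrained model, neighbouring
  anchors may duplicate a detection (they are trained, not filtered, away).
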