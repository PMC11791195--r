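---
title: "Methods: the dual-track DFU classifier and its building blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dual-track DFU classifier and its building blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The classification problem

Diabetic foot ulcer (DFU) photographs are classified into four complication
classes — `none`, `infection`, `ischemia`, `both` — from close-up 224×224 RGB
images. Clinically useful cues live at two scales: the global configuration of
the wound (extent, position, surrounding tissue) and fine local texture
(erythema, slough, pallor at the wound margin). The model therefore runs two
feature extractors in parallel and fuses them:

* a **hierarchical shifted-window (Swin) transformer track** for global
  context, producing a 7×7 map with 768 channels from a 224×224 input, and
* an **efficient multi-scale attention-driven network (EMADN)** — a compact
  CNN of five stride-2 stages — producing an aligned 7×7 map with 150
  channels.

The two maps are concatenated channel-wise (768 + 150 = 918 channels,
transformer channels first), refined by a **shuffle attention** block, pooled
by global average pooling, and classified by a ReLU hidden layer with dropout
and a 4-way linear output trained with cross-entropy.

This package implements the whole pipeline in pure R on top of a small
tape-based reverse-mode autodiff engine (`dt_*` ops, `nn_*` layers, a
`forward()` generic). Feature maps are arrays with dims `(H, W, C, N)`.

## The transformer track

Images are partitioned into 4×4 patches and linearly embedded (width 96, with
layer norm). Four stages of transformer blocks follow, with patch merging
between stages: each merge concatenates 2×2 neighboring tokens (4C channels)
and linearly reduces them to 2C, so token count drops 4× and width doubles
(96 → 192 → 384 → 768) while the grid shrinks H/4 → H/8 → H/16 → H/32.

Each block applies window-restricted multi-head self-attention inside 7×7
token windows with the canonical pre-norm residual structure — layer norm,
(shifted-)window attention, residual; layer norm, two-layer GELU MLP,
residual. Blocks alternate between regular and shifted windows; the shifted
variant cyclically rolls the grid by ⌊M/2⌋ and masks attention across the
stitch boundaries (additive −1e9 logits), which restores cross-window
information flow without quadratic global attention. The per-window cost is
the usual `4hwC² + 2M²hwC` (exposed as `wmsa_complexity()`).

Layout details were fixed by calibrating the track's trainable-parameter
count against the published ablation total for the standalone track
(27,512,560 including its pooled head):

* depths (2, 2, 6, 2), heads (3, 6, 12, 24), embed width 96, window 7,
  MLP ratio 4, qkv bias on;
* **relative position bias shared across heads** — one (2M−1)² table per
  block rather than one per head;
* patch merging reduction **with bias and without layer norm**;
* standalone head: pooled 768 → 24 hidden (no bias) → 4 classes.

These three departures from the most common layout are exactly what the
printed count pins down; every alternative toggle combination we enumerated
misses it. No pretrained weights are used anywhere; initialization is
seedable Kaiming-style Gaussian.

Input sizes must be divisible by the patch size, and each stage's token grid
by its (possibly clipped) window; otherwise the track rejects the input with
an explicit error rather than silently padding. A window larger than the
grid degenerates to full-grid attention.

## The EMADN track

Five LMDS stages, each followed by a GDA block, halve the spatial size per
stage: 224 → 112 → 56 → 28 → 14 → 7.

**LMDS (lightweight multi-scale deformable shuffle) block.** A ghost module
(half the output channels from a dense 3×3 convolution, half from a cheap
depth-wise 3×3 on those intrinsic maps; batch norm + ReLU) feeds two parallel
branches at the same width: (a) channel shuffle (2 groups) followed by
MixConv — depth-wise convolution with per-group kernel sizes 3/5/7, uneven
channel remainders going to the leading groups — and (b) DDSC, a depth-wise
k=2, dilation-2 convolution followed by a 1×1 point-wise mix. The branch
outputs are merged by element-wise (Hadamard) product — the only reading of
an "element-wise" merge consistent with feeding a single tensor to the next
layer, and the reason both branches are built at identical widths. A
deformable 3×3 convolution with stride 2 then down-samples: its 18 offset
channels (row offsets for the 9 taps, then column offsets) are predicted by a
zero-initialized 3×3 convolution, so training starts as a regular strided
convolution; sampling is bilinear and differentiable in the offsets.

Padding rule: odd kernels get symmetric same-padding; even kernels put the
odd remainder on the bottom/right (k=2, d=2 pads 1+1).

**GDA (global dilated attention) block** at each stage width: a global
context block (softmax attention pooling over positions from a 1×1-conv
logit, bottleneck transform `W_v2 ReLU(LN(W_v1 z))`, broadcast-added back),
then a dilated convolution with learnable spacings (DCLS), then coordinate
attention (direction-wise pooled profiles, shared 1×1 bottleneck with batch
norm and hard-swish, per-direction sigmoid gates multiplied into the input).

DCLS is implemented **densely**: each of the `n_el` kernel elements carries a
weight per in/out channel pair, and the element's continuous 2-D position
(shared across channels, clamped to the extent) spreads those weights
bilinearly onto an L×L effective kernel, keeping the operator differentiable
in positions as well as weights. A depth-wise DCLS cannot reach the printed
parameter difference between the track with and without GDA blocks
(295,383) at any width ≤ 150, so the dense form is the only consistent
reading.

**Frozen stage plan.** The published totals fix what the text does not state.
With stage outputs 24, 52, 96, 130, 150, branch widths 22, 44, 48, 66, 66,
GCB and CA reduction 8, DCLS with 5 elements and extent 7, and a standalone
head hidden width of 196:

| quantity | value |
|---|---|
| LMDS stages total | 381,606 |
| GDA blocks total | 295,383 |
| track + head | 707,373 |
| track without GDA + head | 411,990 |

`scripts/calibrate_params.R` re-derives these closed forms, verifies the
constructed models, and can re-run the neighborhood search.

## Fusion, shuffle attention, head

Shuffle attention splits the 918 fused channels into G = 3 groups; each group
halves into a channel branch (sigmoid gate on an affine transform of the
per-channel spatial mean) and a spatial branch (sigmoid gate on an affine
transform of the per-channel spatially-standardized map), re-joined and
passed through a final 2-group channel shuffle. The four affine vectors and
the normalization affine pair are **shared across groups** (each of length
918/6 = 153), giving exactly 3C/G = 918 parameters — which is precisely the
printed difference between the full model (29,161,395) and the model without
shuffle attention (29,160,477); per-group parameters would triple it.
The full model's head hidden width (1,072) closes the last equation of the
calibration; the remaining totals then match to the digit.

## Training

Defaults follow the tuned regime: learning rate 1e-4, weight decay 1e-3, SGD
with momentum 0.9, step-LR with step 1 and gamma 0.99 (`lr · 0.99^epoch`),
dropout 0.6, cross-entropy loss, fixed class order `none, infection,
ischemia, both`. `train_model()` records per-epoch train/validation loss and
accuracy, keeps the best-validation state and the final state (no early
stopping), and aborts with a diagnostic on non-finite loss. `grid_search()`
exhaustively evaluates a discrete configuration grid by validation macro F1
with a deterministic first-in-grid-order tie-break; grid points that diverge
are recorded as failed rather than aborting the sweep. Batch size (unstated
in the source regime) defaults to 32. Adam is available for desk-scale
capacity checks, where plain SGD at the reference learning rate would take
impractically many epochs.

## Synthetic data

The generator emulates only the coarse statistics that the pipeline's
*plumbing* needs: skin-toned backgrounds with low-frequency texture and
class-specific lesions (red blobs for infection-like images, pale-rimmed
blobs for ischemia-like images, both for the mixed class, none for healthy
skin). Classes are separable by construction; a nearest-centroid rule on
channel summaries already beats chance comfortably. It does **not** emulate
real wound photographs — no camera noise model, specular highlights,
anatomy, or label noise — so passing tests demonstrate that the
architecture, training loop, and bookkeeping are correct, not that the model
generalizes to clinical data.

Augmentation uses exactly the stated lossless right-angle operations —
vertical flip, horizontal flip, rotation from {0°, 90°, 270°} (180° is
deliberately absent from that set) — sampled independently per copy;
duplicates among the four copies of an original are allowed since the regime
specifies counts, not distinctness. `make_splits_and_balance()` produces a
stratified 60/20/20 split (seeded per-class shuffle, rounded counts) and adds
four augmented copies per ischemia/both original in the train *and*
validation splits, never in test. `augmentation_bookkeeping()` applies the
same ×5 arithmetic to the published before-augmentation class table and
reproduces every after-augmentation cell (680/1860 minority train cells,
5,704 train total, 1,866 validation total). The published per-class totals
sum to 6,055, slightly above the stated 5,955 labelled images; the per-class
column is taken as ground truth for the arithmetic. Training images are
standardized per channel with statistics from the training split.

## Numerical choices

* Double precision throughout; batch/layer/group norm use eps = 1e-5 and
  exact gradients through the batch statistics.
* Softmax subtracts the row maximum; masked attention uses additive −1e9
  logits (exp underflows to exactly zero).
* Bilinear sampling outside the padded support reads zeros; position
  gradients at a clamped DCLS coordinate are zeroed (the clamp is active).
* The classifier output layer is initialized at 5% of Kaiming scale so the
  initial cross-entropy sits at the four-class chance level ln 4 ≈ 1.386.
* Grad-CAM normalizes by min-max; an all-non-positive pre-ReLU map is
  defined as all zeros, and a constant positive map as all ones. The target
  layer defaults to the shuffle-attention output (the last convolutional
  representation); any cached representation (`fused`, `swin`, `emadn`) can
  be attributed instead.

## Desk-scale problem sizes

The full reference model (29.2 M parameters) is instantiated for parameter
accounting, which is exact and fast. Functional end-to-end checks — gradient
flow, memorization capacity, Grad-CAM, evaluation — run on
`tiny_model_config()`: the same dual-track assembly (both tracks, fusion,
shuffle attention, pooled head) scaled to 32×32 inputs, embed width 8, five
EMADN stages 8–16 channels, ~175 k parameters. The capacity check trains on
32 synthetic images (8 per class) with Adam at 3e-3 and reaches 100%
training accuracy within a few epochs; the same check at the full 224×224
reference scale is a GPU-class computation and is out of scope for this
package's CPU-only engine.

## Known limitations

* The engine favors clarity over speed: convolutions are im2col + BLAS
  matrix products, attention loops over window/head slices. Training the
  reference-scale model is not practical; the package targets architectural
  fidelity, desk-scale verification, and explainability.
* Reported headline accuracies on the license-gated clinical dataset are not
  reproducible here (no data, no GPU training); nothing in this package
  claims otherwise.
* The EMADN stage plan and the Swin layout variants are fixed by parameter
  calibration, which is a strong but indirect constraint: other
  architectures with identical counts exist. The calibration script
  documents the equivalence class we chose from and why this member
  (smooth width progression, conventional reduction ratios) was frozen.
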