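---
title: "Methods: adaptive-kernel, bidirectional-pyramid cell segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-kernel, bidirectional-pyramid cell segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the pieces of `akbseg` fit together, which
quantities are assumptions versus measurements, and where genuinely open
design decisions were resolved.

## The segmentation model

`akbseg` implements a single-stage instance segmenter for bright-field cell
images. The baseline (`model_spec(variant = "baseline_s_seg")`) is the
familiar small CSP layout: a backbone with C2f blocks and an SPPF tail
producing features at strides 8/16/32, a PAN neck (upsample–concat–C2f
top-down, strided-conv bottom-up), and a decoupled head. The head predicts,
per pyramid cell: 4 × `reg_max` distribution-focal logits whose
softmax-expectation decodes to box-side distances in stride units, one
sigmoid classification score per class, and `num_mask_coeffs` mask
coefficients combined linearly with a shared prototype bank (stride 4,
produced by a small branch with a transpose-convolution upsample) and
passed through a sigmoid; masks are binarized at 0.5 and cropped to their
box.

The full variant (`"akb_full"`) rebuilds the neck:

* every level is projected by a 1×1 convolution + batch norm to a common
  fusion width (`bifpn_channels`);
* four fusion nodes — the top-down intermediate at stride 16 and the three
  outputs — combine their input paths by fast-normalized weighted fusion
  `O = Σ relu(wᵢ)Fᵢ / (ε + Σ relu(wⱼ))`. The raw weights are learnable
  scalars initialized at 1; rectification keeps effective coefficients in
  [0, 1), and `ε = 1e-4` guards the all-zero case. A would-be stride-32
  top-down node has a single input edge and is removed;
* each fusion is followed by a node transform — a C2f block in the
  intermediate ablation variant, an adaptive-kernel convolution
  (`N = 3, stride 1`, no bias) in the full variant — and a
  depthwise-separable convolution with batch norm;
* enlargement along the graph is nearest-neighbour; reduction is stride-2
  max pooling, which keeps the fusion graph parameter-light.

AKConv lays out its `N` sampling points by grid expansion from the top-left
origin (`k = round(√N)` full rows, then a partial row: `N = 3` gives
(0,0), (0,1), (1,0)). A 3×3 convolution predicts a `(B, 2N, H, W)` offset
field, initialized at zero so the layer starts as a fixed sparse-sampling
convolution; sampling positions `P0 + Pn + offset` are read bilinearly with
border clamping (offsets are unconstrained reals, as in deformable
convolution practice), and a 1×1 convolution over the `C·N` stacked samples
aggregates them, followed by batch norm and SiLU. The parameter count
`C_in·k²·2N + C_in·N·C_out + 2C_out` is affine in `N`.

### Fusion width and the complexity ladder

The reference description of this architecture family pins its size at
three points — baseline 11,780 K parameters, BiFPN variant 12,035 K, full
AKB variant 10,364 K (a 13.9 % reduction from the AKConv swap) — without
printing the exact neck wiring. The wiring above, with the head's
box/class/coefficient branch widths held at the baseline family values
(64/128/32) and the default fusion width `bifpn_channels = 328`, reproduces
all three counts to within 0.15 %; the fusion width is the one free scalar
chosen to land on that budget, and it scales freely for desk-size models.

The "number of BiFPN layers" knob is exposed as `bifpn_layers` (stacked
fusion repeats, each with its own weights and transforms). Its default here
is 1: the reference per-depth parameter counts are not mutually consistent
with the ladder values above under either reading of "layers" (repeats or
fused scales), and the ladder is what the package treats as authoritative.
Parameter growth in `bifpn_layers` is exactly affine, which the test suite
asserts.

Soft-NMS is an inference-time rule and contributes no parameters, so the
`plus_softnms` variant counts equal the baseline by construction.

## Preprocessing

`preprocess()` runs contrast-limited adaptive histogram equalization and
Gaussian smoothing, CLAHE first by default (`order` is configurable since
the two stages do not commute). CLAHE defaults follow common practice:
`clip_limit = 2` (histogram ceiling at twice the uniform bin height, excess
redistributed uniformly), `tile_grid = c(8, 8)`, bilinear blending between
tile-center mappings; a tile whose histogram occupies a single bin maps to
the identity, so constant images pass through unchanged. The Gaussian stage
uses an odd kernel (default 3) with `σ = 0.3((k−1)/2 − 1) + 0.8` when not
given, and reflection borders, so constants are preserved exactly.
Enhancement is deterministic and is meant to be applied identically to
training and inference images.

## Training objective and protocol

The loss is the weighted sum of three terms, evaluated per batch and
normalized by the number of assigned positives: classification
cross-entropy over all pyramid cells (one-vs-all with clipped
probabilities, `eps = 1e-7`), squared-error regression of decoded
`(x, y, ω, h)` in normalized image units with coordinate weight
`λ_cor = 1`, and binary cross-entropy of assembled prototype masks,
restricted to the ground-truth box padded by 20 % and normalized per
instance. Squared-error box regression is the package's canonical
objective; term weights default to `(λ_cls, λ_box, λ_seg) = (1, 5, 1)` —
the box term operates on normalized coordinates whose squared errors are
numerically tiny, and the factor 5 simply rebalances its gradient scale.

Assignment is a deliberately simple documented rule: each ground-truth box
goes to the pyramid level whose stride best matches `√(wh)/4`, at the cell
containing its center; collisions fall back to the next-best level. A
task-aligned one-to-many assigner would likely help crowded scenes but is
out of scope.

Optimization is SGD with momentum 0.9 and weight decay 5e-4; the full-scale
defaults in `train_config()` (640 px, batch 16, 200 epochs, lr 0.001)
mirror the reference recipe, while `desk_train_config()` holds the reduced
protocol (96 px input, batch 8, 30 epochs, lr 0.02 decayed linearly to
0.002) used by the shipped experiments. After the last epoch the batch-norm
running statistics are re-estimated by plain averaging over up to 10
forward passes with the final weights: the exponential averages accumulated
while weights move lag behind them, which otherwise degrades
evaluation-mode predictions badly (catastrophically for batch size 1).

## Inference

Images are letterboxed (gray 114/255 padding) to the square input,
candidates above `conf` are decoded, and per-class NMS runs Gaussian
Soft-NMS (`exp(−IoU²/σ)` decay applied only when IoU ≥ N_t, exactly the
piecewise rule; `N_t = 0.5, σ = 0.5, score_min = 0.001`) for the Soft-NMS
variants or classic greedy suppression for the baseline. Ties are broken by
score then lexicographic box coordinates, so suppression is permutation
invariant; the σ → 0 limit reproduces hard NMS, which the tests assert
against a brute-force reference. Suppression is decided on boxes; the
surviving detection keeps its mask.

## Synthetic scenes: what they do and do not show

`generate_scene()` renders star-shaped deformed ellipses (log-uniform radii
for multi-scale spread, low-order Fourier boundary perturbation for
irregular outlines), places them with a configurable adhesion probability
(touching/overlapping placement) or a minimum separation, darkens them
against a gradient background, and applies Gaussian blur and noise; masks
are rasterized before blur/noise so ground truth is exact, and an analytic
coverage value is computed on a 2× supersampled raster (it agrees with
mask-union confluence to < 1 %). Scenes are bit-reproducible from their
seed.

The easy configuration used by the end-to-end study
(`easy_scene_config()`: 128 px, 3–7 disjoint cells of radius 9–18 px, mild
blur and noise) emulates a sparse, well-focused culture; passing the
mAP ≥ 0.8 check shows the whole pipeline — assignment, backprop through
AKConv/BiFPN, decoding, Soft-NMS, prototype masks, evaluation — learns and
generalizes on in-distribution synthetic data. It does not demonstrate
robustness to real optics, debris, mitotic figures, or the densely
adherent colonies the full-scale model targets; those axes exist in the
generator (`adhesion`, `blur_sigma`, `noise_sd`) but are deliberately mild
in the study conditions.

## Problem sizes and numerical choices

The shipped experiments use the reduced model (width multiple 0.125,
fusion width 48, `reg_max = 4`, 8 mask coefficients, 96 px input; about
0.5 M parameters), 200 training and 40 held-out scenes, 30 epochs — sizes
chosen so a full run of the test suite and the acceptance script completes
comfortably on a single CPU. Kernel weights are He-initialized from the
seeded R RNG (builds are bit-reproducible given spec + seed); offset
predictors start at zero; the final classification bias starts at −4 so the
untrained head predicts a low foreground prior. Batch norm uses ε = 1e-5
and momentum 0.1. Probability clipping in the losses uses 1e-7. Degenerate
inputs have defined behaviour: empty detection sets pass through NMS,
AP without ground truth raises, mask IoU of two empty masks raises,
all-zero fusion weights return zero, and scenes that cannot place all
requested cells return fewer with a warning.

## Known limitations

* Single-class segmentation is the tested path; the multi-class code path
  exists but has no study behind it.
* The box mAP of the desk-scale study trails its mask mAP slightly — the
  coarse 4-bin distribution-focal decode at 96 px limits localization
  sharpness; `reg_max` is configurable where that matters.
* The squared-error form is the canonical training objective; complete-IoU
  box loss exists as an alternative in the standalone loss module but the
  trainer does not use it.
* Throughput metrics (FPS) are hardware statements, deliberately not
  modelled; FLOPs accounting is informational only and not a tested
  surface.
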