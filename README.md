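# akbseg

Single-stage instance segmentation of cells in bright-field microscopy
images, implemented entirely in R and C++ (no external deep-learning
runtime). The package targets the quantitative readouts that matter in
cell-culture monitoring — per-cell masks, confluence (percentage of the
dish covered by cells), and cell counts — under the conditions that make
cultured cells hard to segment: order-of-magnitude size spread, dense
adhesion, irregular outlines, and low-contrast boundaries.

## The method

The network is a small CSP-backbone single-stage segmenter (decoupled
detection head with distribution-focal box regression plus
prototype-coefficient masks) whose neck is rebuilt around three ideas:

- **AKConv — adaptive-kernel convolution.** A convolution with an arbitrary
  number *N* of sampling points laid out by grid expansion from a top-left
  origin, displaced per position by a learned offset field of shape
  (B, 2N, H, W), resampled bilinearly, and aggregated by a convolution.
  Parameter count is *affine* in N (`C_in·k²·2N + C_in·N·C_out + 2C_out`),
  unlike the quadratic growth of square k×k kernels, so the neck gets
  lighter while adapting its receptive field to irregular cell shapes.
  Operating point: `N = 3, stride = 1, bias = FALSE`.
- **BiFPN — bidirectional weighted fusion.** Pyramid levels are projected to
  a common width and fused along top-down and bottom-up paths with
  fast-normalized weights, `O = Σᵢ wᵢFᵢ / (ε + Σⱼ wⱼ)` with rectified
  learnable `wᵢ` and `ε = 1e-4`; nodes with a single input edge are removed.
- **Gaussian Soft-NMS.** Instead of deleting overlapping candidates,
  a neighbour of the current maximum **M** with IoU ≥ N_t has its score
  decayed by `exp(−IoU(M,bᵢ)²/σ)`; boxes under the threshold keep their
  score. This preserves genuinely adjacent cells in dense clusters.

Training minimizes a weighted sum of classification cross-entropy,
squared-error box regression `λ_cor Σ[(x−x̂)² + (y−ŷ)² + (ω−ω̂)² + (h−ĥ)²]`,
and binary cross-entropy on assembled prototype masks. Evaluation reports
precision, recall, and mAP50 (mean AP at IoU 0.5) separately for boxes and
masks, with mask IoU `|A∩B|/|A∪B|` on the instance rasters.

Because real culture images of this kind are not redistributable, the
package ships a seeded synthetic scene generator (deformed-ellipse cells
with adhesion, blur, noise, and analytic ground truth) so every stage —
preprocessing, training, NMS, evaluation, analytics — runs end-to-end out
of the box.

## Worked example

```r
library(akbseg)

# complexity accounting across the ablation ladder
parameter_ladder()
#>              variant params_k
#> 1     baseline_s_seg 11790.47
#> 2       plus_softnms 11790.47
#> 3 plus_bifpn_softnms 12021.92
#> 4           akb_full 10366.17
```

Replacing the neck C2f blocks with AKConv takes the BiFPN model from
12,021.9 K to 10,366.2 K trainable parameters — a 13.8 % reduction — while
the full AKB variant stays 12 % below the baseline.

```r
# desk-scale end-to-end study: 200 easy synthetic scenes, reduced model
res <- run_end_to_end(seed = 1)
c(box = res$map50_box, mask = res$map50_mask)
#>       box      mask
#> 0.9179816 0.9781566

# segment an image and report culture analytics
sc <- generate_scene(easy_scene_config(size = 128, seed = 7))
r  <- predict_image(res$model, sc$image)
confluence_report(r, dim(sc$image))
```

The end-to-end run trains the reduced AKB variant (width multiple 0.125,
fusion width 48, 96 px input) for 30 epochs and evaluates 40 held-out
scenes; mask mAP50 of 0.98 means essentially every synthetic cell is
recovered with a correct mask at IoU 0.5.

A thin command-line entry point is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "akbseg", package = "akbseg"))')
$CLI synth --n 20 --size 320 --seed 0 --format yolo_seg --out data/
$CLI preprocess --in data/images --out enhanced/ --clip 2.0 --tiles 8x8 --blur 3
$CLI train --data data/ --seed 0 --weights model.ckpt
$CLI evaluate --weights model.ckpt --data data/ --iou 0.5
$CLI report --weights model.ckpt --in data/images --out report.json
```

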