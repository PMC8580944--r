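---
title: "Delineating the fetal head circumference by distance-field regression"
author: "fetalHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating the fetal head circumference by distance-field regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Head circumference (HC) is a routine fetal biometric: a sonographer images a
transthalamic plane, traces the skull outline as an ellipse, and reports the
ellipse perimeter in millimetres using the scanner's pixel calibration.
Manual tracing is slow and varies between operators. `fetalHC` implements a
fully automatic pipeline that (i) detects the head with a region-proposal
detector, (ii) regresses a *distance field* around the skull contour inside
the detected region, (iii) thresholds the field and fits an ellipse by
non-iterative least squares, and (iv) converts the perimeter to millimetres.

The regression target is deliberately not a binary mask. The HC annotation
is a thin (2 px) elliptical outline; asking a network to reproduce a
near-measure-zero curve is ill-conditioned. Instead each annotation is
converted to a smooth field

$$F(p) = \exp\left(-\frac{d(p)^2}{2\sigma^2}\right), \qquad \sigma = r/2,$$

where $d(p)$ is the Euclidean distance from pixel $p$ to the skeletonized
(one-pixel-wide) contour and $r$ is the thickness of the band the field
lives on ($r = 100$ px at full scale, which covers the skull section
comfortably at HC18 resolutions). $F$ is 1 exactly on the skeleton and
decays smoothly, giving the regression loss a useful gradient everywhere
near the contour.

## Ground-truth construction

`buildTargets()` chains the four steps, each exposed on its own:

1. `rasterizeEllipse()` draws the annotation as a 2 px outline — a pixel is
   on when its centre lies within 1 px of the analytic contour (measured
   against a dense parametric polyline, not a rounded raster, so the band
   width is exact).
2. `skeletonizeContour()` thins the outline to a one-pixel closed ring
   (Zhang–Suen thinning with a connectivity-preserving clean-up of residual
   2×2 blocks). No installed R package provides morphological thinning, so
   the package carries its own implementation with property-style tests
   (idempotence, one-pixel width, ring closure).
3. `buildDistanceField()` is the Gaussian of the exact Euclidean distance
   transform of the skeleton (`EBImage::distmap`), which is mathematically
   identical to erecting Gaussian cross-profiles along the contour normals
   but trivial to verify: the test suite compares it against a brute-force
   nearest-skeleton-pixel search at $10^{-6}$.
4. `fieldBBox()` is the minimal box containing the field's support; it is
   the detector's box target.

**Support truncation.** A band of *thickness* $r$ around the contour ends at
$d = r/2$, where the Gaussian still has value $e^{-1/2} \approx 0.607$. We
truncate there — `fieldConfig(r, support = "half")` — accepting the step to
zero at the band edge; `support = "full"` (truncation at $d = r$, where the
Gaussian has decayed to $e^{-2} \approx 0.14$) is available if a smoother
tail is preferred. Nothing downstream is sensitive to the choice: the
delineation threshold (0.9) lives far inside either support.

**Coordinates.** Rasters are `[row, col]` matrices; exported coordinates are
0-based with x along columns; boxes are half-open `[x1, x2) × [y1, y2)`.
One convention everywhere removes a whole class of off-by-one bugs.

## The network

`netConfig()` describes a standard two-stage detector: a ResNet backbone
(depths 18/34/50/101) with a feature-pyramid top (P2–P6, strides 4–64,
256 channels), a region-proposal network over 5 scales × 3 aspect ratios,
quantization-free ROI align to $d \times d$ ($d = 14$), and three heads:

* classification (two shared 1024-unit FC layers, then 2 softmax scores);
* box refinement (4 linear outputs);
* distance-field regression: four 3×3 convolutions, then an upsampling path
  that restores resolution before a final linear 1×1 convolution. Two
  variants are configurable — `"upconv"` (2× nearest upsampling followed by
  a 2×2 and two 3×3 convolutions per step, the UNet-decoder style) and
  `"transposed"` (a single stride-2 transposed convolution per step) — with
  `nUpsamplings` in 1..3, so the head emits $(2^u d)^2$ patches. Every head
  convolution except the final 1×1 is followed by batch normalization and
  ReLU. The final 1×1 is linear so the regression can express values near 0
  and 1 symmetrically.

Hyper-parameters that a standard Mask-RCNN implementation fixes and the
configuration does not need to expose are kept at their standard values:
RPN positive/negative IoU 0.7/0.3, proposal NMS 0.7, head-training positive
IoU 0.5, detection NMS 0.3, FPN level assignment
$k = \lfloor 4 + \log_2(\sqrt{wh}/224)\rfloor$ clamped to P2–P5.

Because no deep-learning framework is part of the package's dependency
footprint, the network and its training are implemented in the package
itself: a small reverse-mode autodiff tape in R over C++ kernels
(im2col+GEMM convolutions, fused batch norm, ROI align, pooling), each with
numerically checked gradients. Batch normalization uses batch statistics in
both training and evaluation — the optimizer runs at batch size 1, where
running averages are poorly estimated, and batch statistics keep train and
validation behaviour identical and deterministic.

## Training

The multi-task loss is
$$L = \alpha L_{cls} + \beta L_{box} + \gamma L_{df}, \qquad
\alpha = \beta = \gamma = 1,$$
with $L_{df}$ the root-mean-square error between predicted and target field
patches, averaged over positive ROIs (a field target only exists where a
head is). The RPN is trained jointly, as in any standard two-stage
detector; its objectness cross-entropy is folded into $L_{cls}$ and its
smooth-L1 box term into $L_{box}$, so the $L$ identity above holds exactly
for every logged step (the suite asserts it at $10^{-6}$).

Optimization is plain SGD with momentum (lr 0.001, momentum 0.9, batch
size 1, no schedule) in three stages: (1) RPN and heads with a frozen
backbone, (2) the distance-field head alone — its loss decays more slowly
than the detection terms — and (3) the whole network. One checkpoint per
epoch records the validation $L$; `selectBest()` takes the argmin (ties to
the earliest epoch).

On-the-fly augmentation applies one affine transform per sample per epoch:
scale in [0.9, 1.1], translation ±5% of the image side, rotation ±15°,
shear ±8° — modest perturbations consistent with probe placement
variability in fetal ultrasound. The transform acts identically on image
and field; the box is recomputed from the transformed field, and a draw
that pushes the head off the canvas is resampled (10 tries, then the
sample passes through unaugmented). All randomness — initialization, ROI
and anchor sampling, augmentation, epoch shuffling — flows from
`trainConfig(seed = )`; two runs with one seed produce identical loss
traces on one CPU.

## From field to millimetres

At inference the top-scoring detection's field patch is resized into its
box on a zero canvas, clipped to [0, 1], mapped back through the inverse of
the aspect-preserving resize (`resizeWithPadding()`), and thresholded at
0.9. **The fit runs on the crest of the field, not on the raw superlevel
set.** This choice deserves its rationale: on an exact Gaussian band with
$r = 100$, the 0.9-superlevel set is an annulus about 46 px thick whose
area density grows with radius; *every* unweighted least-squares fit is
biased outward on it (3–5 px on the axes for algebraic fits, and even an
ideal geometric fit lands ~3.5 px high). Thinning the binary mask to its
medial axis is not enough either: for small, eccentric heads the inner
offset of the contour degenerates where the curvature radius drops below
the band half-width, and the medial axis pulls inward at the major-axis
ends (1–3 px of axis underestimation). The crest of the *field* has
neither problem: inside the superlevel set the fit keeps only pixels not
dominated by either neighbour along the quantized gradient direction
(non-maximum suppression, as in edge thinning), then thins the crest to
one pixel. On exact fields this recovers the generating contour to under
0.1 px across the whole size range; on network output it extracts the
ridge of the predicted band. `delineate(ridge = FALSE)` restores the
raw-superlevel behaviour, and `weighted = TRUE` exposes a
field-value-weighted fit.

The ellipse fit itself is an unconstrained, non-iterative least squares on
the conic with the $x^2$ coefficient normalized (centred and scaled for
conditioning), followed by a canonicalization to $a \ge b$,
$\theta \in [0, \pi)$; non-elliptical or rank-deficient solutions raise a
typed fit-failure. It is exact (relative error $\le 10^{-6}$) on noise-free
samples up to axis ratio 10. The perimeter uses Ramanujan's second
approximation, which the suite checks against adaptive quadrature of the
elliptic arc-length integral ($\le 10^{-4}$ relative for $a/b \le 5$); HC
in mm is the perimeter times the per-image pixel size.

Evaluation metrics: signed difference DF = HC$_{pred}$ − HC$_{gt}$ (so a
negative mean reads as under-estimation), its magnitude ADF, the classic
max–min Hausdorff distance between densely sampled contours (3600 points;
10× denser sampling moves it by <1%), and Dice on filled-head masks.

## The synthetic phantom generator

Real HC18 images cannot ship with a package, so `generateDataset()` writes
an HC18-layout dataset (images, `*_Annotation.png` 2 px outlines, the pixel
size/HC CSV, COCO-style boxes) of structural phantoms: one bright
elliptical skull band per image (Gaussian cross-profile of drawn thickness,
drawn contrast) over a low-frequency soft-tissue background, optional
angular shadow sectors attenuating the band, unit-mean multiplicative gamma
speckle, light smoothing, 8-bit quantization. Pixel sizes are drawn with a
uniform marginal on [0.052, 0.326] mm, negatively correlated (Gaussian
copula, ρ = 0.7) with head size — bigger heads are imaged at coarser pixel
sizes, as depth settings do clinically. Head position, size, orientation
and ellipticity are uniform under a containment margin; generation is
byte-reproducible from the seed.

What the phantom does *not* emulate: B-mode physics (no point-spread
function, no polar fan geometry, no reverberation artefacts), anatomy
beyond the skull band (no brain structures, no uterine wall), and the real
HC18 intensity statistics — contrast and noise levels are free parameters,
not fitted to clinical data. Tests passing on phantoms therefore establish
that the pipeline is implemented correctly and can be learned end-to-end,
not that clinical-grade accuracy transfers to real ultrasound.

## Desk-scale study conditions

The end-to-end checks train two variants (the `"upconv"` u = 3 default and
the single-transposed-convolution `"transp1"` baseline) under identical
conditions chosen once for a single-CPU budget: 128 px phantoms with
$r = 24$, ResNet-18 at stem width 16, 32 FPN channels, an 8-channel field
head with $d = 7$ (output 56×56), 128-unit FC layers, 32 training ROIs per
image with the field loss on up to 4 positives, anchor scales
[16, 32, 64, 96, 128], 200 training / 25 validation / 50 held-out images,
and the staged schedule at 5+5+5 epochs. The detection score threshold is
0.5 at this scale (after 15 epochs the classifier's scores are not yet
saturated; the full-scale default stays 0.7). During the frozen-backbone
stages the implementation skips backpropagation below the pyramid — a pure
compute saving with no effect on the frozen parameters, which the suite
checks are bit-identical.

## Known limitations

* The detector assumes exactly one head per image (true of HC18); no
  multi-instance logic.
* Pixels are assumed square (true of HC18); no anisotropic calibration.
* The classic Hausdorff definition is implemented; challenge servers
  sometimes use modified/averaged variants, so absolute HD values need not
  be comparable across toolchains.
* The hand-rolled training loop is adequate for the desk-scale studies and
  for correctness work, but it is single-threaded CPU code; full-scale
  (512 px, depth-101, 150-epoch) training is outside its practical budget.
* COCO-pretrained backbone weights can be injected via
  `initNetParams(cfg, pretrained = )` if shapes match, but no download is
  attempted and random initialization is the default.
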