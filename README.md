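# fetalHC

Automatic delineation of the fetal head circumference (HC) in 2-D
ultrasound images by **distance-field regression**. Instead of segmenting
the head or regressing biometric numbers directly, a region-proposal
detector finds the head and a dedicated head regresses, inside the detected
box, a Gaussian field of the distance to the skull contour:

```
F(p) = exp(-d(p)^2 / (2 sigma^2)),   sigma = r/2
```

where `d(p)` is the Euclidean distance from pixel `p` to the skeletonized
(1-px) contour annotation and `r` is the band thickness (100 px at full
scale). The predicted field is thresholded at 0.9, reduced to its crest
(gradient non-maximum suppression, thinned to one pixel), fitted with a
non-iterative least-squares ellipse, and the ellipse
perimeter (Ramanujan's second approximation) times the per-image pixel size
gives HC in millimetres.

The package is aimed at researchers in ultrasound image analysis who want a
fully inspectable, dependency-light implementation of this pipeline: the
ground-truth construction, the detector (ResNet/FPN backbone, RPN, ROI
align, classification / box / distance-field heads with the upsampling-path
variants), the staged training procedure with the multi-task loss
`L = a*L_cls + b*L_box + g*L_df`, the evaluation metrics (signed/absolute
HC difference, Hausdorff distance, Dice), HC18-layout and COCO-style I/O,
and a synthetic speckle-phantom generator so everything runs and tests
without clinical data. The network and its training loop are implemented in
the package itself (an autodiff tape over Rcpp kernels) — no external
deep-learning framework is required.

## Worked example

Generate a small synthetic dataset, build targets, and measure an oracle
field (the geometry chain alone, no training):

```r
library(fetalHC)

man <- generateDataset(5, phantomConfigDesk(seed = 4), writeImages = FALSE)
s <- attr(man, "samples")[[1]]

# ground-truth construction for one annotation
tg <- buildTargets(s$gtEllipse, 128, 128, fieldConfig(24))
range(tg$field)
#> [1] 0 1

# measure the HC from the (here: ground-truth) field
m <- measureField(s$field, s$mmPerPx)
m
#> HCMeasurement: HC = 35.76 mm (163.6 px at 0.2186 mm/px)
s$hcMm
#> [1] 35.83342
```

The measured 35.76 mm agrees with the generating ellipse's analytic HC
(35.83 mm) to 0.08 mm (0.2%); across phantoms the geometry chain recovers
centers and axes to well under a pixel.

End-to-end at desk scale (about ten minutes on one CPU):

```r
samples <- attr(generateDataset(275, phantomConfigDesk(seed = 4),
                                writeImages = FALSE), "samples")
run <- stagedTraining(samples[1:200], samples[201:210],
                      netConfigDesk(), trainConfig(stageEpochs = c(5, 5, 5),
                                                   seed = 11))
model <- list(params = selectBest(run$checkpoints)$params,
              netCfg = netConfigDesk())
ev <- evaluateModel(samples[226:275], model)
ev$summary
```

On the 50 held-out phantoms this prints a mean Dice of 0.86, a mean
absolute HC difference of 1.53 mm (median 3.9% of the phantom HC) and a
mean Hausdorff distance of 1.65 mm, with no failed detections — the
scaled-down analogue of the full study, at the problem sizes described in
the methods vignette (`vignettes/distance-field-hc.Rmd`).

A thin CLI over the same functions lives in `inst/cli/fetalhc`
(`synth`, `make-targets`, `train`, `predict`, `evaluate`).

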