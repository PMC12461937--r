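# fimpipe

Image processing for flow-imaging microscopy (FIM) of freshwater
phytoplankton, built for autonomous monitoring instruments that
photograph a sample as it passes a flow cell. The package implements the
full processing chain — particle segmentation, morphometric features,
out-of-focus filtering, background-particle removal, CNN classification,
and classification with rejection for out-of-distribution particles —
together with a synthetic scene generator that provides exact ground
truth, so every stage can be calibrated and validated without instrument
data.

## Who it is for

Researchers and operators working with widefield FIM frame sequences
(e.g. drinking-water intake monitoring for cyanobacterial blooms) who
need reproducible, testable particle counting and classification, and
method developers who want a controlled synthetic benchmark for the
individual pipeline stages.

## What is inside

* **Synthetic scenes** (`renderSequence`): frames at the instrument
  geometry (725 × 545 μm field of view, 1.55 μm/px) seeded with target
  particles placed fresh per frame and stationary background particles
  re-rendered each frame with jitter bounded by 12 px. Ground truth for
  every particle in every frame.
* **Segmenter** (`segmentFrame`, `evaluateOda`): threshold +
  8-connected components with morphological closing; detections scored
  in the five categories TP / FP / FN / merge / split.
* **Features** (`computeRoiFeatures`, `pruneCorrelated`,
  `rankImportance`): a 47-feature catalog (shape, intensity, edge-noise
  statistics), Pearson-correlation pruning, impurity-based ranking.
* **Focus filter** (`trainFocusClassifier`, `retrainTopK`,
  `filterInFocus`): random forest on the features, 70:30 stratified
  split, retrained on the 12 top-ranked features.
* **Background-particle detection** (`runBpd`): the two-stage
  algorithm — DBSCAN over x–y positions of three consecutive frames,
  feature-agreement sub-clustering, and the two-of-three flagging rule:

  a particle is background iff its sub-cluster recurs in ≥ 2 of 3
  consecutive frames. Defaults are calibrated so detection stays ≥ 95 %
  for per-frame travel up to 20 px (`calibrateTolerance` reproduces the
  curve).
* **Micro-CNN classifier** (`trainClosedSet`, `predictCnn`): one
  CONV–MP block, four CONV–MP–dropout blocks (rate 0.25), two dense
  layers, SoftMax output; Adam (lr 0.001), categorical cross-entropy;
  stratified 70:15:15 split with lossless 8-fold dihedral augmentation
  of the training split. The training engine is compiled code inside the
  package and is deterministic under a fixed seed.
* **Classification with rejection** (`softmaxReject`, `mcdPredict`,
  `trainCac`, `trainWithKoc`, `precisionRecallRejection`): SoftMax
  thresholding; Monte-Carlo dropout (50 passes, mean probabilities);
  class-anchor clustering (distance-based open-set head); optional known
  out-of-distribution class (KOC) whose predictions map to a null label;
  shared precision–recall / rejection-rate analysis over a quantile
  threshold grid.
* **Pipeline runner** (`runPipeline`, `inst/scripts/fimtool.R`): stage
  orchestration over on-disk artifacts with a JSON run report.

## Worked example

```r
library(fimpipe)

cfg <- SceneConfig(nFrames = 10, nTargetsPerFrame = 15, nBackground = 5,
                   seed = 42)
scene <- renderSequence(cfg)
fovCoverage(groundTruth(scene), cfg)      # 0.47 (% of field covered)

set <- segmentFrames(scene)
evaluateOda(set, groundTruth(scene))
#> OdaEvalResult: TP=190 FP=0 FN=0 merge=5 split=0 (accuracy 0.950 on 200 particles)

res <- runBpdScene(scene)                 # segment + features + BPD
evaluateBpdParticles(res$truth)
#> accuracy 1.000, false positives 0, false negatives 0 (n = 155 particles)

raw <- mean(tapply(!res$flags, res$particles$frame, sum))
estimateConcentration(raw)                # 1.86e5 particles per mL
```

Reading the numbers: at this density the segmenter recovers 190 of 200
seeded particles one-to-one (5 merges account for the rest — overlapping
particles fused into one ROI, no spurious or lost detections). The
background-particle stage then identifies all 5 stuck particles from
their recurrence across consecutive frames without flagging any of the
150 flowing ones, dropping the mean count from 19.5 to 14.7 particles
per frame; the corrected count converts to a concentration through the
imaged volume (field of view × 200 μm channel depth).

## Repository layout

```
R/                  implementation (S4 classes, one file per stage)
src/                compiled kernels: component labeling, morphology, CNN
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, calibration, limitations)
scripts/acceptance.R  evaluation protocol runner
inst/scripts/fimtool.R  command-line wrapper (simulate/segment/bpd/run)
```
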