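#' @import methods
#' @importFrom randomForest randomForest
#' @importFrom stats median quantile sd cor predict rnorm runif setNames
#' @importFrom utils head read.csv write.csv
#' @useDynLib fimpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sprite specification for the synthetic scene generator
#'
#' A sprite is the rendered appearance of one particle. `diameterUm` is the
#' area-equivalent diameter: every shape kind is scaled so its mask covers
#' approximately `pi * (d/2)^2` square microns, which makes field-of-view
#' coverage depend only on the diameter distribution and not on shape.
#'
#' @slot shapeKind character; one of `"disk"`, `"ellipse"`, `"filament"`,
#'   `"colony"`, plus the extension kinds `"debris"` and `"ring"` used as
#'   out-of-distribution material in open-set experiments.
#' @slot diameterUm positive area-equivalent diameter in microns.
#' @slot intensityContrast fraction of the background level in `[-1, 1]`;
#'   negative values give dark particles on a bright field.
#' @slot blurSigmaPx non-negative Gaussian blur sigma in pixels; 0 = in focus.
#' @export
setClass("SpriteSpec", representation(
  shapeKind = "character",
  diameterUm = "numeric",
  intensityContrast = "numeric",
  blurSigmaPx = "numeric"
))

.sprite_kinds <- c("disk", "ellipse", "filament", "colony", "debris", "ring")

setValidity("SpriteSpec", function(object) {
  msg <- character()
  if (!object@shapeKind %in% .sprite_kinds)
    msg <- c(msg, paste("unknown shapeKind:", object@shapeKind))
  if (!is.finite(object@diameterUm) || object@diameterUm <= 0)
    msg <- c(msg, "diameterUm must be > 0")
  if (!is.finite(object@intensityContrast) ||
      abs(object@intensityContrast) > 1)
    msg <- c(msg, "intensityContrast must lie in [-1, 1]")
  if (!is.finite(object@blurSigmaPx) || object@blurSigmaPx < 0)
    msg <- c(msg, "blurSigmaPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SpriteSpec-class
#' @param shapeKind,diameterUm,intensityContrast,blurSigmaPx see slots.
#' @return A `SpriteSpec` object.
#' @examples
#' SpriteSpec("disk", diameterUm = 10)
#' @export
SpriteSpec <- function(shapeKind = "disk", diameterUm = 10,
                       intensityContrast = -0.5, blurSigmaPx = 0) {
  new("SpriteSpec", shapeKind = shapeKind, diameterUm = diameterUm,
      intensityContrast = intensityContrast, blurSigmaPx = blurSigmaPx)
}

setMethod("show", "SpriteSpec", function(object) {
  cat(sprintf("SpriteSpec: %s, d=%.2f um, contrast=%.2f, blur=%.2f px\n",
              object@shapeKind, object@diameterUm, object@intensityContrast,
              object@blurSigmaPx))
})

#' Scene configuration for the synthetic frame generator
#'
#' Defaults reproduce the imaging geometry of the flow-imaging instrument the
#' pipeline targets: a 725 x 545 micron field of view sampled at 1.55
#' microns per pixel, i.e. 468 x 352 pixel frames. Background particles are
#' placed once and re-rendered in every frame with a bounded random jitter
#' (at most `maxJitterPx` pixels from the base position); target particles
#' are drawn fresh in every frame.
#'
#' @slot frameWidthPx,frameHeightPx frame size in pixels.
#' @slot umPerPx sampling resolution, microns per pixel.
#' @slot nFrames number of frames in the sequence.
#' @slot nTargetsPerFrame target (moving) particles seeded per frame.
#' @slot nBackground stationary background particles for the whole sequence.
#' @slot maxJitterPx bound on per-frame displacement of background particles
#'   from their base position (pixels).
#' @slot backgroundLevel mean background intensity in `[0, 1]`.
#' @slot noiseSigma additive Gaussian pixel noise sigma.
#' @slot seed integer RNG seed; identical configurations (including seed)
#'   render bitwise-identical sequences.
#' @slot jitterMode `"uniform"` (direction uniform, magnitude uniform on
#'   `[0, maxJitterPx]`), `"tnorm"` (magnitude from a truncated normal with
#'   `jitterMeanPx`/`jitterSdPx`, for tolerance-calibration experiments), or
#'   `"linear"` (each background particle moves exactly `displacementPx`
#'   pixels per frame along a fixed random direction).
#' @slot jitterMeanPx,jitterSdPx truncated-normal jitter parameters (pixels).
#' @slot displacementPx exact per-frame travel in `"linear"` mode (pixels).
#' @slot diameterRangeUm range of sprite area-equivalent diameters (microns).
#' @slot contrastRange range of sprite intensity contrasts.
#' @slot blurSigmaRangePx range of sprite blur sigmas (pixels).
#' @slot shapeKinds shape kinds sampled for sprites.
#' @export
setClass("SceneConfig", representation(
  frameWidthPx = "integer", frameHeightPx = "integer",
  umPerPx = "numeric", nFrames = "integer",
  nTargetsPerFrame = "integer", nBackground = "integer",
  maxJitterPx = "numeric", backgroundLevel = "numeric",
  noiseSigma = "numeric", seed = "integer",
  jitterMode = "character", jitterMeanPx = "numeric",
  jitterSdPx = "numeric", displacementPx = "numeric",
  diameterRangeUm = "numeric", contrastRange = "numeric",
  blurSigmaRangePx = "numeric", shapeKinds = "character"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@frameWidthPx < 1L || object@frameHeightPx < 1L)
    msg <- c(msg, "frame dimensions must be positive")
  if (object@umPerPx <= 0) msg <- c(msg, "umPerPx must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@nTargetsPerFrame < 0L || object@nBackground < 0L)
    msg <- c(msg, "particle counts must be non-negative")
  if (object@maxJitterPx < 0) msg <- c(msg, "maxJitterPx must be >= 0")
  if (!object@jitterMode %in% c("uniform", "tnorm", "linear"))
    msg <- c(msg, "jitterMode must be uniform, tnorm or linear")
  if (length(object@diameterRangeUm) != 2L ||
      any(object@diameterRangeUm <= 0))
    msg <- c(msg, "diameterRangeUm must be two positive values")
  if (length(msg)) msg else TRUE
})

#' @rdname SceneConfig-class
#' @param frameWidthPx,frameHeightPx,umPerPx,nFrames,nTargetsPerFrame,nBackground,maxJitterPx,backgroundLevel,noiseSigma,seed,jitterMode,jitterMeanPx,jitterSdPx,displacementPx,diameterRangeUm,contrastRange,blurSigmaRangePx,shapeKinds see slots.
#' @return A `SceneConfig` object.
#' @examples
#' SceneConfig(nFrames = 5, nTargetsPerFrame = 10, nBackground = 3, seed = 1)
#' @export
SceneConfig <- function(frameWidthPx = round(725 / 1.55),
                        frameHeightPx = round(545 / 1.55),
                        umPerPx = 1.55, nFrames = 30L,
                        nTargetsPerFrame = 10L, nBackground = 3L,
                        maxJitterPx = 12, backgroundLevel = 0.5,
                        noiseSigma = 0.01, seed = 1L,
                        jitterMode = "uniform", jitterMeanPx = 16.8,
                        jitterSdPx = 11.5, displacementPx = 0,
                        diameterRangeUm = c(6, 16),
                        contrastRange = c(-0.7, -0.3),
                        blurSigmaRangePx = c(0, 0),
                        shapeKinds = c("disk", "ellipse", "filament",
                                       "colony")) {
  new("SceneConfig",
      frameWidthPx = as.integer(frameWidthPx),
      frameHeightPx = as.integer(frameHeightPx),
      umPerPx = umPerPx, nFrames = as.integer(nFrames),
      nTargetsPerFrame = as.integer(nTargetsPerFrame),
      nBackground = as.integer(nBackground),
      maxJitterPx = maxJitterPx, backgroundLevel = backgroundLevel,
      noiseSigma = noiseSigma, seed = as.integer(seed),
      jitterMode = jitterMode, jitterMeanPx = jitterMeanPx,
      jitterSdPx = jitterSdPx, displacementPx = displacementPx,
      diameterRangeUm = diameterRangeUm, contrastRange = contrastRange,
      blurSigmaRangePx = blurSigmaRangePx, shapeKinds = shapeKinds)
}

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(paste0(
    "SceneConfig: %d x %d px (%.2f um/px), %d frames\n",
    "  targets/frame: %d, background: %d, jitter: %s (<= %g px), seed %d\n"),
    object@frameWidthPx, object@frameHeightPx, object@umPerPx,
    object@nFrames, object@nTargetsPerFrame, object@nBackground,
    object@jitterMode, object@maxJitterPx, object@seed))
})

#' Synthetic scene: rendered frames plus ground truth
#'
#' @slot frames list of numeric matrices (rows = y, columns = x), intensities
#'   in `[0, 1]`.
#' @slot truth data.frame with one row per rendered particle per frame:
#'   `frame`, `particle_id`, `x`, `y` (0-based center coordinates),
#'   `is_background`, `shape_kind`, `diameter_um`, `contrast`, `blur_sigma`,
#'   `area_px`, `class_label`, plus list columns `mask` (binary patch) and
#'   `x0`/`y0` (0-based patch offsets).
#' @slot config the `SceneConfig` used.
#' @export
setClass("SyntheticScene", representation(
  frames = "list", truth = "data.frame", config = "SceneConfig"
))

#' @describeIn SyntheticScene-class rendered frames as a list of matrices.
#' @param x,object a `SyntheticScene`.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname SyntheticScene-class
#' @export
setMethod("frames", "SyntheticScene", function(x) x@frames)

#' @describeIn SyntheticScene-class ground-truth table.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname SyntheticScene-class
#' @export
setMethod("groundTruth", "SyntheticScene", function(x) x@truth)

#' @describeIn SyntheticScene-class scene configuration.
#' @export
setGeneric("sceneConfig", function(x) standardGeneric("sceneConfig"))
#' @rdname SyntheticScene-class
#' @export
setMethod("sceneConfig", "SyntheticScene", function(x) x@config)

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d frames (%d x %d px), %d truth records\n",
              length(object@frames), object@config@frameWidthPx,
              object@config@frameHeightPx, nrow(object@truth)))
})

#' Segmenter parameters
#'
#' @slot backgroundEstimation `"flat"` (scalar median of the frame) or
#'   `"median"` (local median filter background).
#' @slot thresholdOffset absolute intensity offset; pixels deviating from the
#'   background estimate by more than this are foreground.
#' @slot minAreaPx,maxAreaPx retained component area range (pixels).
#' @slot closingRadiusPx morphological closing radius (0 disables).
#' @slot padPx crop padding around the bounding box.
#' @slot medianRadiusPx local-median background radius (pixels).
#' @export
setClass("SegmenterParams", representation(
  backgroundEstimation = "character", thresholdOffset = "numeric",
  minAreaPx = "integer", maxAreaPx = "integer",
  closingRadiusPx = "integer", padPx = "integer",
  medianRadiusPx = "integer"
))

setValidity("SegmenterParams", function(object) {
  msg <- character()
  if (!object@backgroundEstimation %in% c("flat", "median"))
    msg <- c(msg, "backgroundEstimation must be 'flat' or 'median'")
  if (object@minAreaPx > object@maxAreaPx)
    msg <- c(msg, "minAreaPx must be <= maxAreaPx")
  if (object@thresholdOffset <= 0) msg <- c(msg, "thresholdOffset must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SegmenterParams-class
#' @param backgroundEstimation,thresholdOffset,minAreaPx,maxAreaPx,closingRadiusPx,padPx,medianRadiusPx see slots.
#' @return A `SegmenterParams` object.
#' @export
SegmenterParams <- function(backgroundEstimation = "flat",
                            thresholdOffset = 0.08,
                            minAreaPx = 4L, maxAreaPx = 100000L,
                            closingRadiusPx = 1L, padPx = 2L,
                            medianRadiusPx = 15L) {
  new("SegmenterParams", backgroundEstimation = backgroundEstimation,
      thresholdOffset = thresholdOffset, minAreaPx = as.integer(minAreaPx),
      maxAreaPx = as.integer(maxAreaPx),
      closingRadiusPx = as.integer(closingRadiusPx),
      padPx = as.integer(padPx), medianRadiusPx = as.integer(medianRadiusPx))
}

#' Set of detected particle regions of interest
#'
#' Bounding boxes are half-open `[x0, x1) x [y0, y1)` in 0-based pixel
#' coordinates with x = column and y = row; centroids are sub-pixel 0-based.
#'
#' @slot roi data.frame with columns `frame`, `roi_id`, `x0`, `y0`, `x1`,
#'   `y1`, `cx`, `cy`, `area_px`.
#' @slot masks list of binary matrices, one per ROI, cropped to the bbox.
#' @slot crops list of numeric matrices, the (padded) image crops.
#' @export
setClass("ParticleSet", representation(
  roi = "data.frame", masks = "list", crops = "list"
))

setValidity("ParticleSet", function(object) {
  n <- nrow(object@roi)
  if (length(object@masks) != n || length(object@crops) != n)
    return("masks/crops length must equal nrow(roi)")
  if (n > 0 && any(object@roi$area_px <= 0))
    return("all ROIs must have positive area")
  TRUE
})

#' @rdname ParticleSet-class
#' @param roi,masks,crops see slots.
#' @export
ParticleSet <- function(roi = data.frame(), masks = list(), crops = list()) {
  new("ParticleSet", roi = roi, masks = masks, crops = crops)
}

#' @describeIn ParticleSet-class ROI geometry table.
#' @param x,object a `ParticleSet`.
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))
#' @rdname ParticleSet-class
#' @export
setMethod("roiTable", "ParticleSet", function(x) x@roi)

#' @describeIn ParticleSet-class binary masks (list of matrices).
#' @export
setGeneric("roiMasks", function(x) standardGeneric("roiMasks"))
#' @rdname ParticleSet-class
#' @export
setMethod("roiMasks", "ParticleSet", function(x) x@masks)

#' @describeIn ParticleSet-class image crops (list of matrices).
#' @export
setGeneric("roiCrops", function(x) standardGeneric("roiCrops"))
#' @rdname ParticleSet-class
#' @export
setMethod("roiCrops", "ParticleSet", function(x) x@crops)

#' @rdname ParticleSet-class
#' @export
setMethod("length", "ParticleSet", function(x) nrow(x@roi))

#' @rdname ParticleSet-class
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ParticleSet", function(x, i, j, ..., drop = FALSE) {
  ParticleSet(roi = x@roi[i, , drop = FALSE],
              masks = x@masks[i], crops = x@crops[i])
})

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet: %d ROIs over %d frame(s)\n", nrow(object@roi),
              length(unique(object@roi$frame))))
  if (nrow(object@roi)) print(head(object@roi, 4))
})

#' Combine ParticleSets
#' @param x,... ParticleSet objects.
#' @export
setMethod("c", "ParticleSet", function(x, ...) {
  sets <- c(list(x), list(...))
  ParticleSet(roi = do.call(rbind, lapply(sets, roiTable)),
              masks = do.call(c, lapply(sets, roiMasks)),
              crops = do.call(c, lapply(sets, roiCrops)))
})

#' Parameters of the background-particle-detection algorithm
#'
#' @slot distanceThresholdPx DBSCAN neighbourhood radius over centroid
#'   coordinates (pixels). The default (25) is the calibrated value: it links
#'   consecutive sightings of a stationary particle displaced by up to 20
#'   pixels per frame (and bounded jitter up to 12 px, i.e. up to 24 px
#'   between consecutive frames) while staying far below typical
#'   target-to-target distances.
#' @slot minClusterSize DBSCAN minimum points (>= 2; the point itself counts).
#' @slot featureTolerance relative per-feature tolerance for stage-2
#'   sub-clustering.
#' @slot featureSubset features used in stage 2.
#' @export
setClass("BpdParams", representation(
  distanceThresholdPx = "numeric", minClusterSize = "integer",
  featureTolerance = "numeric", featureSubset = "character"
))

setValidity("BpdParams", function(object) {
  msg <- character()
  if (object@distanceThresholdPx <= 0)
    msg <- c(msg, "distanceThresholdPx must be > 0")
  if (object@minClusterSize < 2L) msg <- c(msg, "minClusterSize must be >= 2")
  if (object@featureTolerance < 0) msg <- c(msg, "featureTolerance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BpdParams-class
#' @param distanceThresholdPx,minClusterSize,featureTolerance,featureSubset see slots.
#' @export
BpdParams <- function(distanceThresholdPx = 25, minClusterSize = 2L,
                      featureTolerance = 0.12,
                      featureSubset = c("area", "perimeter",
                                        "eccentricity", "solidity",
                                        "extent", "equivalent_diameter",
                                        "mean_intensity",
                                        "integrated_intensity")) {
  new("BpdParams", distanceThresholdPx = distanceThresholdPx,
      minClusterSize = as.integer(minClusterSize),
      featureTolerance = featureTolerance, featureSubset = featureSubset)
}

#' Trained focus-quality classifier
#'
#' @slot forest fitted `randomForest` object.
#' @slot featureNamesUsed features the model consumes, in order.
#' @slot trainSeed seed used for the stratified split and forest.
#' @slot metrics list with `overall`, `per_class` held-out accuracies.
#' @slot threshold decision threshold on the out-of-focus probability.
#' @export
setClass("FocusModel", representation(
  forest = "ANY", featureNamesUsed = "character", trainSeed = "integer",
  metrics = "list", threshold = "numeric"
))

setMethod("show", "FocusModel", function(object) {
  cat(sprintf(
    "FocusModel: random forest on %d features, held-out accuracy %.3f\n",
    length(object@featureNamesUsed), object@metrics$overall))
})

#' Micro-CNN configuration
#'
#' The architecture is one CONV-MP block followed by four CONV-MP-DO blocks
#' and two dense layers, with SoftMax output for closed-set training and a
#' K-dimensional embedding for class-anchor training.
#'
#' @slot inputSize square input side in pixels (must be divisible by 32).
#' @slot widths channel widths of the five convolution blocks.
#' @slot hidden width of the first dense layer.
#' @slot dropoutRate dropout fraction in blocks 2-5 (default 0.25).
#' @slot learningRate Adam learning rate (default 0.001).
#' @slot epochs,batchSize training schedule.
#' @slot seed RNG seed for initialisation, shuffling and dropout.
#' @slot anchorMagnitude class-anchor scale for CAC training.
#' @slot cacLambda weight of the anchor-attraction term in the CAC loss.
#' @slot classWeighting `TRUE` to weight the cross-entropy loss inversely to
#'   class frequency.
#' @export
setClass("CnnConfig", representation(
  inputSize = "integer", widths = "integer", hidden = "integer",
  dropoutRate = "numeric", learningRate = "numeric", epochs = "integer",
  batchSize = "integer", seed = "integer", anchorMagnitude = "numeric",
  cacLambda = "numeric", classWeighting = "logical"
))

setValidity("CnnConfig", function(object) {
  msg <- character()
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@inputSize %% 2^length(object@widths) != 0L)
    msg <- c(msg, "inputSize must be divisible by 2^(number of blocks)")
  if (length(msg)) msg else TRUE
})

#' @rdname CnnConfig-class
#' @param inputSize,widths,hidden,dropoutRate,learningRate,epochs,batchSize,seed,anchorMagnitude,cacLambda,classWeighting see slots.
#' @export
CnnConfig <- function(inputSize = 32L, widths = c(8L, 16L, 32L, 32L, 64L),
                      hidden = 64L, dropoutRate = 0.25,
                      learningRate = 0.001, epochs = 15L, batchSize = 32L,
                      seed = 1L, anchorMagnitude = 10, cacLambda = 0.1,
                      classWeighting = TRUE) {
  new("CnnConfig", inputSize = as.integer(inputSize),
      widths = as.integer(widths), hidden = as.integer(hidden),
      dropoutRate = dropoutRate, learningRate = learningRate,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      seed = as.integer(seed), anchorMagnitude = anchorMagnitude,
      cacLambda = cacLambda, classWeighting = classWeighting)
}

#' Trained micro-CNN model
#'
#' @slot params list of weight matrices from the training engine.
#' @slot config the `CnnConfig` used.
#' @slot classes class labels in output order.
#' @slot history data.frame with per-epoch `train_loss` and `val_accuracy`.
#' @slot method `"softmax"` (closed set / KOC) or `"cac"` (class anchors).
#' @slot kocLabel name of the known-out-of-distribution class, or `NA`.
#' @export
setClass("MicroCNN", representation(
  params = "list", config = "CnnConfig", classes = "character",
  history = "data.frame", method = "character", kocLabel = "character"
))

setMethod("show", "MicroCNN", function(object) {
  va <- object@history$val_accuracy
  cat(sprintf(
    "MicroCNN (%s): %d classes [%s], %d epochs, final val accuracy %.3f\n",
    object@method, length(object@classes),
    paste(object@classes, collapse = ", "), nrow(object@history),
    if (length(va)) va[length(va)] else NA_real_))
})

#' Open-set evaluation report
#'
#' @slot curve data.frame indexed by a shared threshold grid with columns
#'   `threshold`, `precision`, `recall`, and one `rejection_<group>` column
#'   per unknown group.
#' @slot misassignment named numeric: fraction of unknown items assigned to
#'   each known class when nothing is rejected.
#' @slot method rejection method the report was computed for.
#' @export
setClass("OpenSetReport", representation(
  curve = "data.frame", misassignment = "numeric", method = "character"
))

setMethod("show", "OpenSetReport", function(object) {
  cat(sprintf("OpenSetReport (%s): %d thresholds\n", object@method,
              nrow(object@curve)))
  print(head(object@curve, 3))
})
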