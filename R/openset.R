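# Classification with rejection: SoftMax thresholding, Monte-Carlo dropout
# (MCD) and class-anchor clustering (CAC), plus training with a known
# out-of-distribution class (KOC) and the precision-recall / rejection-rate
# analysis shared by all methods.
#
# Unified convention: every method exposes (label, score, rejected) with a
# single scalar score. SoftMax/MCD reject when score < threshold (score =
# max probability); CAC rejects when score > threshold (score = distance to
# the nearest anchor). The analysis layer normalises the direction.

#' SoftMax-threshold rejection
#'
#' Marks predictions whose maximum SoftMax probability falls below the
#' threshold as out-of-distribution.
#'
#' @param pred data.frame from [predictCnn()] (or [mcdPredict()]).
#' @param threshold rejection threshold on the maximum probability.
#' @return the prediction data.frame with `rejected` updated.
#' @export
softmaxReject <- function(pred, threshold) {
  pred$rejected <- pred$score < threshold
  if (!is.na(.koc_of(pred))) pred$rejected <- pred$rejected |
      pred$label == .koc_of(pred)
  pred
}

.koc_of <- function(pred) {
  k <- attr(pred, "kocLabel")
  if (is.null(k)) NA_character_ else k
}

#' Monte-Carlo-dropout prediction
#'
#' Runs `passes` stochastic forward passes with dropout active and averages
#' the per-pass SoftMax outputs; the score is the maximum of the mean
#' probabilities and is thresholded exactly like a SoftMax score. With a
#' dropout rate of zero this reduces to the deterministic prediction.
#'
#' @param model a SoftMax [MicroCNN-class].
#' @param crops list of crop matrices.
#' @param passes number of forward passes (default 50).
#' @param seed integer seed for the dropout configurations.
#' @param ids optional identifiers.
#' @return prediction data.frame (`method = "mcd"`) with mean probabilities
#'   in `attr(, "probs")`.
#' @export
mcdPredict <- function(model, crops, passes = 50L, seed = 1L, ids = NULL) {
  if (passes < 1L) stop("passes must be >= 1")
  if (model@method == "cac") stop("MCD applies to SoftMax models")
  acc <- NULL
  for (p in seq_len(passes)) {
    o <- .forward(model, crops, dropoutActive = TRUE,
                  seed = seed * 1000L + p, output = "prob")
    acc <- if (is.null(acc)) o else acc + o
  }
  probs <- t(acc / passes)
  colnames(probs) <- model@classes
  lab <- model@classes[apply(probs, 1, which.max)]
  out <- data.frame(
    id = if (is.null(ids)) seq_along(crops) else ids,
    label = lab, score = apply(probs, 1, max), rejected = FALSE,
    method = "mcd", stringsAsFactors = FALSE)
  attr(out, "probs") <- probs
  out
}

#' Train a class-anchor-clustering open-set model
#'
#' The network head outputs a K-dimensional embedding; class anchors are
#' fixed at `anchorMagnitude` times the one-hot points. The loss combines a
#' cross-entropy over softmin of anchor distances (repelling other anchors)
#' with an attraction term on the distance to the particle's own anchor,
#' so training minimises intraclass distance while maximising interclass
#' distance. Prediction assigns the nearest anchor; the score is that
#' distance, and rejection uses `score > threshold`.
#'
#' @param train,val lists with `crops` and `labels`.
#' @param config a [CnnConfig-class] (`anchorMagnitude`, `cacLambda`).
#' @return a [MicroCNN-class] with `method = "cac"`.
#' @export
trainCac <- function(train, val, config = CnnConfig()) {
  .train_cnn(train, val, config, loss = "cac", method = "cac")
}

#' Embeddings of crops under a CAC model
#'
#' @param model a CAC [MicroCNN-class].
#' @param crops list of crop matrices.
#' @return matrix (crops x K embedding dimensions).
#' @export
cacEmbed <- function(model, crops) {
  if (model@method != "cac") stop("not a CAC model")
  t(.forward(model, crops, output = "embed"))
}

#' Train a classifier with a known out-of-distribution class
#'
#' Trains an ordinary (K+1)-class SoftMax model in which one class (the
#' KOC, typically debris-like material) absorbs non-target particles. At
#' reporting time KOC predictions map to a null label: they are treated as
#' rejected independently of any threshold.
#'
#' @param crops list of crop matrices including KOC examples.
#' @param labels class labels; `kocLabel` marks the KOC class.
#' @param config a [CnnConfig-class].
#' @param kocLabel name of the KOC class in `labels`.
#' @param ratios,seed passed to [splitDataset()].
#' @return a [MicroCNN-class] with `kocLabel` set.
#' @export
trainWithKoc <- function(crops, labels, config = CnnConfig(),
                         kocLabel = "KOC", ratios = c(0.7, 0.15, 0.15),
                         seed = 1L) {
  if (!kocLabel %in% labels) stop("KOC class absent from labels")
  sp <- splitDataset(crops, labels, ratios = ratios, seed = seed)
  .train_cnn(sp$train, sp$val, config, loss = "ce", method = "softmax",
             kocLabel = kocLabel)
}

#' Predictions with KOC-aware null labelling
#'
#' @param model a [MicroCNN-class] (KOC-trained or not).
#' @param crops list of crop matrices.
#' @param ids optional identifiers.
#' @return prediction data.frame; for KOC models the `kocLabel` attribute
#'   is set so that rejection layers can treat KOC assignments as null.
#' @export
predictWithNull <- function(model, crops, ids = NULL) {
  pred <- predictCnn(model, crops, ids = ids)
  attr(pred, "kocLabel") <- model@kocLabel
  if (!is.na(model@kocLabel))
    pred$rejected <- pred$label == model@kocLabel
  pred
}

#' Precision-recall and rejection-rate analysis over a threshold grid
#'
#' For each threshold, precision and recall are computed over the known-class
#' items (a rejected known item counts against recall but not precision) and
#' the rejection rate of each unknown group is the fraction of its items
#' rejected. The default grid is 101 evenly spaced quantiles of the observed
#' score distribution, so curves are resolution-independent. KOC-labelled
#' predictions count as rejected at every threshold.
#'
#' @param pred prediction data.frame from [predictCnn()], [mcdPredict()] or
#'   [predictWithNull()].
#' @param truth true labels, aligned with `pred`; unknown items may carry
#'   any label listed in `unknownGroups`.
#' @param knownClasses labels considered known.
#' @param unknownGroups named list mapping group name (e.g. `"debris"`,
#'   `"novel"`) to the truth labels belonging to it.
#' @param nGrid number of threshold quantiles (default 101).
#' @param thresholds optional explicit threshold grid (overrides `nGrid`).
#' @return an [OpenSetReport-class].
#' @export
precisionRecallRejection <- function(pred, truth, knownClasses,
                                     unknownGroups = list(), nGrid = 101L,
                                     thresholds = NULL) {
  stopifnot(nrow(pred) == length(truth))
  truth <- as.character(truth)
  method <- pred$method[1]
  koc <- .koc_of(pred)
  # unified direction: accept when acceptScore >= cut
  acceptScore <- if (method == "cac") -pred$score else pred$score
  if (is.null(thresholds)) {
    cuts <- quantile(acceptScore, probs = seq(0, 1, length.out = nGrid),
                     names = FALSE)
  } else {
    cuts <- if (method == "cac") rev(-thresholds) else thresholds
  }
  is_known <- truth %in% knownClasses
  koc_null <- if (!is.na(koc)) pred$label == koc else rep(FALSE, nrow(pred))
  rows <- lapply(cuts, function(ct) {
    rejected <- acceptScore < ct | koc_null
    acc_known <- is_known & !rejected
    correct <- acc_known & pred$label == truth
    r <- data.frame(
      threshold = if (method == "cac") -ct else ct,
      precision = if (any(acc_known)) sum(correct) / sum(acc_known) else NA,
      recall = sum(correct) / max(sum(is_known), 1L))
    for (g in names(unknownGroups)) {
      in_g <- truth %in% unknownGroups[[g]]
      r[[paste0("rejection_", g)]] <-
        if (any(in_g)) sum(rejected & in_g) / sum(in_g) else NA
    }
    r
  })
  curve <- do.call(rbind, rows)
  # misassignment of unknowns to known classes with no score rejection
  unk <- truth %in% unlist(unknownGroups)
  mis <- vapply(knownClasses, function(cl)
    if (any(unk)) sum(unk & !koc_null & pred$label == cl) / sum(unk)
    else NA_real_, 1.0)
  new("OpenSetReport", curve = curve, misassignment = mis,
      method = method)
}
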