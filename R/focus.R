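# In-focus / out-of-focus particle classification from the feature catalog,
# using a random forest with correlation pruning and top-k retraining.

#' Train the focus-quality random forest
#'
#' Splits the feature table into stratified train/test parts (default
#' 70:30), fits a random forest with class weights inverse to class
#' frequency, and records held-out overall and per-class accuracy.
#' Deterministic for a fixed seed.
#'
#' @param table feature data.frame (non-feature columns `roi_id`, `frame`,
#'   `label` are ignored as predictors).
#' @param labels character/factor with the two focus classes
#'   (`"in_focus"` / `"out_of_focus"`).
#' @param splitRatio fraction used for training (default 0.7).
#' @param seed integer seed for the split and the forest.
#' @param ntree forest size (default 200).
#' @param threshold decision threshold on the out-of-focus probability.
#'   The focus boundary is physically continuous, so this is a knob, not a
#'   constant.
#' @return a [FocusModel-class].
#' @export
trainFocusClassifier <- function(table, labels, splitRatio = 0.7,
                                 seed = 1L, ntree = 200L,
                                 threshold = 0.5) {
  tab <- as.data.frame(table)
  tab <- tab[, !(names(tab) %in% c("roi_id", "frame", "label")),
             drop = FALSE]
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("both focus classes must be present")
  .with_seed(seed, {
    tr_idx <- unlist(lapply(levels(labels), function(l) {
      idx <- which(labels == l)
      sample(idx, max(1L, round(splitRatio * length(idx))))
    }))
    if (nlevels(droplevels(labels[tr_idx])) < 2L ||
        nlevels(droplevels(labels[-tr_idx])) < 2L)
      stop("stratification error: a class is absent from a split")
    wt <- 1 / table(labels[tr_idx])
    wt <- as.numeric(wt / sum(wt))
    fit <- randomForest::randomForest(
      x = tab[tr_idx, , drop = FALSE], y = labels[tr_idx],
      ntree = ntree, classwt = wt)
    pred <- predict(fit, tab[-tr_idx, , drop = FALSE])
    truth <- labels[-tr_idx]
    per_class <- vapply(levels(labels), function(l)
      mean(pred[truth == l] == l), 1.0)
    new("FocusModel", forest = fit, featureNamesUsed = names(tab),
        trainSeed = as.integer(seed),
        metrics = list(overall = mean(pred == truth),
                       per_class = per_class),
        threshold = threshold)
  })
}

#' Retrain a focus model on its top-k features
#'
#' Ranks the model's features by ensemble impurity decrease
#' ([rankImportance()]) and refits using only the `k` top-ranked ones
#' (default 12).
#'
#' @param model a [FocusModel-class].
#' @param table,labels the training data (as in [trainFocusClassifier()]).
#' @param k number of features to keep.
#' @param splitRatio,ntree as in [trainFocusClassifier()].
#' @return a new [FocusModel-class] with `featureNamesUsed` of length `k`.
#' @export
retrainTopK <- function(model, table, labels, k = 12L, splitRatio = 0.7,
                        ntree = 200L) {
  tab <- as.data.frame(table)
  feats <- model@featureNamesUsed
  if (k > length(feats)) stop("k exceeds the number of available features")
  ranked <- rankImportance(tab[, feats, drop = FALSE], labels,
                           seed = model@trainSeed, ntree = ntree)
  top <- ranked[seq_len(k)]
  trainFocusClassifier(tab[, top, drop = FALSE], labels,
                       splitRatio = splitRatio, seed = model@trainSeed,
                       ntree = ntree, threshold = model@threshold)
}

#' Partition particles into in-focus and out-of-focus
#'
#' @param set a [ParticleSet-class] (or `NULL` to get only the logical
#'   partition).
#' @param features feature data.frame for the ROIs, containing every column
#'   in `model@featureNamesUsed`.
#' @param model a [FocusModel-class].
#' @param threshold optional override of the model's decision threshold on
#'   the out-of-focus probability.
#' @return list with `inFocus` and `outOfFocus` (ParticleSets, input order
#'   preserved), `isInFocus` (logical) and `pOutOfFocus` (numeric).
#' @export
filterInFocus <- function(set, features, model, threshold = NULL) {
  if (is.null(threshold)) threshold <- model@threshold
  feats <- model@featureNamesUsed
  missing_cols <- setdiff(feats, names(features))
  if (length(missing_cols))
    stop("schema error: missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(as.data.frame(features))
  if (n == 0L) {
    empty <- ParticleSet(roi = .empty_roi())
    return(list(inFocus = empty, outOfFocus = empty,
                isInFocus = logical(0), pOutOfFocus = numeric(0)))
  }
  probs <- predict(model@forest,
                   as.data.frame(features)[, feats, drop = FALSE],
                   type = "prob")
  p_out <- if ("out_of_focus" %in% colnames(probs))
    probs[, "out_of_focus"] else 1 - probs[, 1]
  keep <- p_out < threshold
  list(
    inFocus = if (is.null(set)) NULL else set[which(keep)],
    outOfFocus = if (is.null(set)) NULL else set[which(!keep)],
    isInFocus = unname(keep), pOutOfFocus = unname(p_out))
}
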