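# Closed-set classification of particle crops with a micro-CNN: one
# CONV-MP block, four CONV-MP-DO blocks, two dense layers, SoftMax output;
# Adam with categorical cross-entropy; lossless 8-fold dihedral
# augmentation of the training split.

.rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Eight lossless dihedral transforms of a crop
#'
#' Returns the orbit of the crop under the dihedral group of order 8: the
#' identity, the three 90-degree rotations, the mirror image, and its three
#' rotations. All transforms are pixel-exact permutations (the pixel
#' multiset is preserved), so augmentation is non-destructive.
#'
#' @param crop numeric matrix; must be square unless `padToSquare = TRUE`.
#' @param padToSquare pad a non-square crop to a square with its border
#'   median before transforming.
#' @return list of 8 matrices.
#' @export
augmentDihedral <- function(crop, padToSquare = FALSE) {
  if (nrow(crop) != ncol(crop)) {
    if (!padToSquare)
      stop("shape error: crop is not square (use padToSquare = TRUE)")
    crop <- .pad_square(crop)
  }
  r1 <- .rot90cw(crop); r2 <- .rot90cw(r1); r3 <- .rot90cw(r2)
  mr <- crop[, ncol(crop):1, drop = FALSE]
  m1 <- .rot90cw(mr); m2 <- .rot90cw(m1); m3 <- .rot90cw(m2)
  list(crop, r1, r2, r3, mr, m1, m2, m3)
}

# pad to square with the border median (keeps background statistics)
.pad_square <- function(crop) {
  nr <- nrow(crop); nc <- ncol(crop)
  if (nr == nc) return(crop)
  s <- max(nr, nc)
  border <- c(crop[1, ], crop[nr, ], crop[, 1], crop[, nc])
  out <- matrix(median(border), s, s)
  oy <- (s - nr) %/% 2L; ox <- (s - nc) %/% 2L
  out[oy + seq_len(nr), ox + seq_len(nc)] <- crop
  out
}

# aspect-preserving pad-to-square then resize to size x size
.preprocess_crop <- function(crop, size) {
  sq <- .pad_square(crop)
  if (nrow(sq) != size) {
    img <- EBImage::resize(EBImage::Image(t(sq)), w = size, h = size)
    sq <- t(EBImage::imageData(img))
  }
  sq - median(sq)   # background-centred
}

# crops list -> (size*size) x N matrix
.crops_to_matrix <- function(crops, size) {
  X <- matrix(0, size * size, length(crops))
  for (i in seq_along(crops))
    X[, i] <- as.numeric(.preprocess_crop(crops[[i]], size))
  X
}

#' Stratified 70:15:15 split with train-only augmentation
#'
#' Splits crops per class into train/validation/test parts and applies the
#' 8-fold dihedral augmentation to the training split only; validation and
#' test stay unaugmented and no image appears in two splits.
#'
#' @param crops list of crop matrices.
#' @param labels class labels.
#' @param ratios train/val/test fractions (must sum to 1).
#' @param seed integer seed.
#' @param augment apply dihedral augmentation to the train split.
#' @return list of three lists `train`, `val`, `test`, each with `crops`
#'   and `labels`.
#' @export
splitDataset <- function(crops, labels, ratios = c(0.70, 0.15, 0.15),
                         seed = 1L, augment = TRUE) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(crops) == length(labels))
  labels <- as.character(labels)
  .with_seed(seed, {
    tr <- va <- te <- integer(0)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      if (n < 3L)
        stop("stratification error: class '", cl, "' has fewer than 3 images")
      ntr <- max(1L, floor(ratios[1] * n))
      nva <- max(1L, floor(ratios[2] * n))
      if (ntr + nva >= n) { ntr <- n - 2L; nva <- 1L }
      tr <- c(tr, idx[seq_len(ntr)])
      va <- c(va, idx[ntr + seq_len(nva)])
      te <- c(te, idx[(ntr + nva + 1L):n])
    }
    train_crops <- crops[tr]; train_labels <- labels[tr]
    if (augment) {
      aug <- lapply(train_crops, augmentDihedral, padToSquare = TRUE)
      train_crops <- unlist(aug, recursive = FALSE)
      train_labels <- rep(train_labels, each = 8L)
    }
    list(train = list(crops = train_crops, labels = train_labels),
         val = list(crops = crops[va], labels = labels[va]),
         test = list(crops = crops[te], labels = labels[te]))
  })
}

.engine_cfg <- function(config, loss, classes, labels) {
  K <- length(classes)
  w <- rep(1, K)
  if (config@classWeighting && loss == "ce") {
    n <- as.numeric(table(factor(labels, levels = classes)))
    w <- sum(n) / (K * pmax(n, 1))
    w <- w / mean(w)
  }
  list(epochs = config@epochs, batch_size = config@batchSize,
       learning_rate = config@learningRate,
       dropout_rate = config@dropoutRate, loss = loss,
       anchor_magnitude = config@anchorMagnitude,
       cac_lambda = config@cacLambda, seed = config@seed,
       class_weights = w)
}

.train_cnn <- function(train, val, config, loss, method,
                       kocLabel = NA_character_) {
  classes <- sort(unique(as.character(train$labels)))
  if (length(classes) < 2L) stop("need at least 2 classes")
  S <- config@inputSize
  X <- .crops_to_matrix(train$crops, S)
  y <- match(train$labels, classes) - 1L
  Xv <- .crops_to_matrix(val$crops, S)
  yv <- match(val$labels, classes) - 1L
  if (anyNA(yv)) stop("validation labels outside the training classes")
  params <- .cnn_init(config@seed, S, config@widths, config@hidden,
                      length(classes))
  fit <- .cnn_train(params, X, y, Xv, yv,
                    .engine_cfg(config, loss, classes, train$labels))
  if (any(!is.finite(fit$train_loss)))
    stop("training error: loss diverged")
  new("MicroCNN", params = fit$params, config = config, classes = classes,
      history = data.frame(epoch = seq_along(fit$train_loss),
                           train_loss = fit$train_loss,
                           val_accuracy = fit$val_accuracy),
      method = method, kocLabel = kocLabel)
}

#' Train the closed-set micro-CNN
#'
#' @param train,val lists with `crops` and `labels` (see [splitDataset()]).
#' @param config a [CnnConfig-class].
#' @return a [MicroCNN-class] with SoftMax output over the training classes.
#' @export
trainClosedSet <- function(train, val, config = CnnConfig()) {
  .train_cnn(train, val, config, loss = "ce", method = "softmax")
}

# chunked forward pass; returns K x N matrix
.forward <- function(model, crops, dropoutActive = FALSE, seed = 0L,
                     output = c("prob", "embed")) {
  output <- match.arg(output)
  S <- model@config@inputSize
  X <- .crops_to_matrix(crops, S)
  n <- ncol(X)
  out <- NULL
  step <- 256L
  for (s in seq(1L, n, by = step)) {
    e <- min(s + step - 1L, n)
    o <- .cnn_forward(model@params, X[, s:e, drop = FALSE],
                      list(dropout_active = dropoutActive,
                           dropout_rate = model@config@dropoutRate,
                           seed = as.integer(seed + s),
                           output = output))
    out <- cbind(out, o)
  }
  out
}

#' Predict class probabilities for crops
#'
#' For SoftMax models the score is the maximum class probability; for
#' class-anchor models the embedding is computed, the predicted class is the
#' nearest anchor and the score is that distance (smaller = more confident).
#' Inference is deterministic (dropout off).
#'
#' @param model a [MicroCNN-class].
#' @param crops list of crop matrices.
#' @param ids optional identifiers.
#' @return data.frame with `id`, `label`, `score`, `rejected` (all `FALSE`;
#'   apply a rejection rule downstream), `method`; class probabilities in
#'   `attr(, "probs")` (rows = crops, columns = classes).
#' @export
predictCnn <- function(model, crops, ids = NULL) {
  if (model@method == "cac") {
    emb <- .forward(model, crops, output = "embed")
    d <- .anchor_distances(emb, model@config@anchorMagnitude)
    lab <- model@classes[apply(d, 2, which.min)]
    score <- apply(d, 2, min)
    probs <- t(apply(-d, 2, function(z) {
      z <- z - max(z); e <- exp(z); e / sum(e)
    }))
  } else {
    p <- .forward(model, crops, output = "prob")
    lab <- model@classes[apply(p, 2, which.max)]
    score <- apply(p, 2, max)
    probs <- t(p)
  }
  colnames(probs) <- model@classes
  out <- data.frame(
    id = if (is.null(ids)) seq_along(crops) else ids,
    label = lab, score = score, rejected = FALSE,
    method = model@method, stringsAsFactors = FALSE)
  attr(out, "probs") <- probs
  out
}

.anchor_distances <- function(emb, magnitude) {
  K <- nrow(emb)
  d <- matrix(0, K, ncol(emb))
  for (k in seq_len(K)) {
    diff <- emb
    diff[k, ] <- diff[k, ] - magnitude
    d[k, ] <- sqrt(colSums(diff^2))
  }
  d
}

#' Confusion matrix and accuracy
#'
#' @param predicted predicted labels (or a [predictCnn()] data.frame).
#' @param truth true labels.
#' @return list with `confusion` (rows = truth, columns = predicted),
#'   `overall` accuracy (trace / total) and `per_class` accuracy.
#' @export
confusionAndAccuracy <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$label
  if (!length(truth)) stop("empty input")
  lev <- sort(unique(c(as.character(predicted), as.character(truth))))
  cm <- table(truth = factor(truth, levels = lev),
              predicted = factor(predicted, levels = lev))
  per_class <- diag(cm) / pmax(rowSums(cm), 1)
  list(confusion = cm, overall = sum(diag(cm)) / sum(cm),
       per_class = per_class[rowSums(cm) > 0])
}
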