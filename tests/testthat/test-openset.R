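test_that("SoftMax thresholding follows the score convention exactly", {
  pred <- data.frame(id = 1:3, label = c("a", "b", "a"),
                     score = c(0.6, 0.95, 0.4), rejected = FALSE,
                     method = "softmax", stringsAsFactors = FALSE)
  expect_false(any(softmaxReject(pred, 0)$rejected))
  expect_true(all(softmaxReject(pred, 1 + 1e-9)$rejected))
  # probs (0.6, 0.3, 0.1) with threshold 0.7 -> rejected
  expect_true(softmaxReject(pred, 0.7)$rejected[1])
  expect_false(softmaxReject(pred, 0.7)$rejected[2])
})

test_that("MCD averages simplex points and collapses to the deterministic path", {
  ds <- sprite_data_small()
  sp <- splitDataset(ds$crops, ds$labels, seed = 9)
  m0 <- trainClosedSet(sp$train, sp$val,
                       CnnConfig(seed = 9, epochs = 3L, dropoutRate = 0))
  expect_error(mcdPredict(m0, sp$test$crops, passes = 0), "passes")
  det <- predictCnn(m0, sp$test$crops)
  mcd <- mcdPredict(m0, sp$test$crops, passes = 3, seed = 1)
  # dropout rate 0: every pass is the deterministic forward pass
  expect_equal(attr(det, "probs"), attr(mcd, "probs"), tolerance = 1e-12)
  fx <- cnn_model_small()
  mcd2 <- mcdPredict(fx$model, fx$split$test$crops[1:20], passes = 6,
                     seed = 2)
  expect_equal(unname(rowSums(attr(mcd2, "probs"))), rep(1, 20),
               tolerance = 1e-6)
})

test_that("more MCD passes shrink the score variance", {
  fx <- cnn_model_small()
  crops <- fx$split$test$crops[1:20]
  score_sd <- function(passes) {
    scores <- vapply(1:6, function(s)
      mean(mcdPredict(fx$model, crops, passes = passes,
                      seed = 100 + s)$score), 1.0)
    sd(scores)
  }
  expect_lt(score_sd(20), score_sd(2))
})

test_that("class-anchor training pulls embeddings to their own anchors", {
  ds <- sprite_data_small()
  sp <- splitDataset(ds$crops, ds$labels, seed = 10)
  mc <- trainCac(sp$train, sp$val, CnnConfig(seed = 10, epochs = 8L))
  emb <- cacEmbed(mc, sp$val$crops)
  K <- length(mc@classes)
  d <- vapply(seq_len(K), function(k) {
    e <- t(emb); e[k, ] <- e[k, ] - mc@config@anchorMagnitude
    sqrt(colSums(e^2))
  }, numeric(nrow(emb)))
  own <- d[cbind(seq_len(nrow(d)), match(sp$val$labels, mc@classes))]
  other <- (rowSums(d) - own) / (K - 1)
  expect_lt(mean(own), mean(other))
  # training-class crops sit closer to their anchors than noise does
  set.seed(41)
  noise <- replicate(40, matrix(runif(32 * 32), 32, 32), simplify = FALSE)
  pn <- predictCnn(mc, noise)
  pv <- predictCnn(mc, sp$val$crops)
  expect_lt(mean(pv$score), mean(pn$score))
  # an infinite distance threshold rejects nothing
  rep_inf <- precisionRecallRejection(
    pv, sp$val$labels, knownClasses = mc@classes, thresholds = Inf)
  expect_equal(rep_inf@curve$recall[1],
               mean(pv$label == sp$val$labels))
})

test_that("KOC-trained models expose a null route for unknowns", {
  ds <- sprite_data_small()
  set.seed(42)
  koc <- makeSpriteDataset(40, classes = "debris", seed = 43)
  crops <- c(ds$crops, koc$crops)
  labels <- c(ds$labels, rep("KOC", length(koc$crops)))
  m <- trainWithKoc(crops, labels, CnnConfig(seed = 11, epochs = 6L),
                    kocLabel = "KOC", seed = 11)
  expect_equal(length(m@classes), 5)
  held <- makeSpriteDataset(30, classes = "debris", seed = 44)
  pred <- predictWithNull(m, held$crops)
  probs <- attr(pred, "probs")
  expect_equal(unname(rowSums(probs)), rep(1, 30), tolerance = 1e-6)
  # held-out KOC-like crops are routed to the KOC class above chance
  expect_gt(mean(pred$label == "KOC"), 1 / 5)
  expect_true(all(pred$rejected[pred$label == "KOC"]))
})

test_that("threshold endpoints give closed-set recall and total rejection", {
  fx <- cnn_model_small()
  known <- fx$split$test$crops
  set.seed(45)
  unk <- makeSpriteDataset(20, classes = "ring", seed = 46)
  pred <- predictCnn(fx$model, c(known, unk$crops))
  truth <- c(fx$split$test$labels, rep("ring", 20))
  rep0 <- precisionRecallRejection(
    pred, truth, knownClasses = fx$model@classes,
    unknownGroups = list(novel = "ring"), thresholds = c(-Inf, Inf))
  curve <- rep0@curve
  lo <- which.min(curve$threshold); hi <- which.max(curve$threshold)
  closed <- confusionAndAccuracy(pred$label[seq_along(known)],
                                 fx$split$test$labels)
  expect_equal(curve$recall[lo], closed$overall)
  expect_equal(curve$rejection_novel[lo], 0)
  expect_equal(curve$rejection_novel[hi], 1)
  expect_equal(curve$recall[hi], 0)
  # curves share one threshold grid and stay within [0, 1]
  rep1 <- precisionRecallRejection(
    pred, truth, knownClasses = fx$model@classes,
    unknownGroups = list(novel = "ring"), nGrid = 21)
  expect_equal(nrow(rep1@curve), 21)
  ok <- with(rep1@curve, c(precision, recall, rejection_novel))
  expect_true(all(ok >= 0 & ok <= 1, na.rm = TRUE))
})

test_that("every rejection method exposes the same (label, score, rejected) contract", {
  fx <- cnn_model_small()
  crops <- fx$split$test$crops[1:10]
  ps <- predictCnn(fx$model, crops)
  pm <- mcdPredict(fx$model, crops, passes = 3, seed = 5)
  for (p in list(ps, pm)) {
    expect_true(all(c("id", "label", "score", "rejected", "method")
                    %in% names(p)))
    expect_type(p$score, "double")
    expect_type(p$rejected, "logical")
  }
})
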