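test_that("dihedral augmentation is an 8-element lossless group orbit", {
  set.seed(31)
  crop <- matrix(runif(49), 7, 7)
  aug <- augmentDihedral(crop)
  expect_length(aug, 8)
  # pixel multiset preserved by every transform
  for (a in aug) expect_equal(sort(as.numeric(a)), sort(as.numeric(crop)))
  # group closure: transforming every element again and deduplicating
  # returns the same 8-element set
  key <- function(m) paste(signif(as.numeric(m), 12), collapse = ",")
  orbit1 <- sort(vapply(aug, key, ""))
  expect_length(unique(orbit1), 8)
  again <- unlist(lapply(aug, augmentDihedral), recursive = FALSE)
  orbit2 <- sort(unique(vapply(again, key, "")))
  expect_identical(orbit2, unique(orbit1))
  # a fully symmetric crop maps to 8 identical outputs
  unif <- matrix(0.3, 5, 5)
  expect_true(all(vapply(augmentDihedral(unif),
                         function(a) identical(a, unif), TRUE)))
  # non-square input is a shape error unless padded
  expect_error(augmentDihedral(matrix(0, 3, 5)), "shape")
  expect_length(augmentDihedral(matrix(0, 3, 5), padToSquare = TRUE), 8)
})

test_that("stratified split is exact, disjoint and augment-on-train-only", {
  crops <- replicate(100, matrix(runif(25), 5, 5), simplify = FALSE)
  labels <- rep("a", 100)
  crops2 <- replicate(40, matrix(runif(25), 5, 5), simplify = FALSE)
  sp <- splitDataset(c(crops, crops2), c(labels, rep("b", 40)), seed = 5)
  expect_equal(sum(sp$train$labels == "a"), 70 * 8)
  expect_equal(sum(sp$val$labels == "a"), 15)
  expect_equal(sum(sp$test$labels == "a"), 15)
  expect_equal(length(sp$train$crops), 8 * (70 + 28))
  # no raw image appears in two splits
  key <- function(m) paste(signif(as.numeric(m), 12), collapse = ",")
  kv <- vapply(sp$val$crops, key, "")
  kt <- vapply(sp$test$crops, key, "")
  expect_length(intersect(kv, kt), 0)
  # determinism
  sp2 <- splitDataset(c(crops, crops2), c(labels, rep("b", 40)), seed = 5)
  expect_identical(sp$val$crops, sp2$val$crops)
  expect_error(splitDataset(crops[1:2], c("a", "a"), seed = 1),
               "stratification")
})

test_that("the network memorises a single batch", {
  ds <- sprite_data_small()
  set.seed(32)
  idx <- sample(length(ds$crops), 32)
  train <- list(crops = ds$crops[idx], labels = ds$labels[idx])
  cfg <- CnnConfig(seed = 3, epochs = 60L, dropoutRate = 0,
                   batchSize = 32L)
  m <- trainClosedSet(train, train, cfg)
  pred <- predictCnn(m, train$crops)
  expect_equal(mean(pred$label == train$labels), 1)
})

test_that("probabilities normalise and inference is deterministic", {
  fx <- cnn_model_small()
  pred <- predictCnn(fx$model, fx$split$test$crops)
  probs <- attr(pred, "probs")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
               tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # duplicate crop gives an identical prediction (dropout off)
  dup <- predictCnn(fx$model, fx$split$test$crops[c(1, 1)])
  expect_identical(dup$score[1], dup$score[2])
  expect_identical(dup$label[1], dup$label[2])
})

test_that("training with shuffled labels stays at chance on validation", {
  ds <- sprite_data_small()
  sp <- splitDataset(ds$crops, ds$labels, seed = 8)
  set.seed(33)
  sh <- sp
  sh$train$labels <- sample(sh$train$labels)
  m <- trainClosedSet(sh$train, sh$val, CnnConfig(seed = 8, epochs = 4L))
  final <- tail(m@history$val_accuracy, 1)
  expect_lt(final, 0.55)   # 1/K = 0.25 plus generous sampling slack
})

test_that("rotating a crop moves its prediction coherently through the augmented model", {
  # the strong (>= 95%) rotation-invariance contract is asserted on the
  # fully trained model in the acceptance suite; here the briefly trained
  # fixture only needs to carry most predictions across a 90-degree turn
  fx <- cnn_model_small()
  pred0 <- predictCnn(fx$model, fx$split$test$crops)
  rot <- lapply(fx$split$test$crops, function(m)
    fimpipe:::.rot90cw(fimpipe:::.pad_square(m)))
  pred90 <- predictCnn(fx$model, rot)
  expect_gte(mean(pred0$label == pred90$label), 0.7)
})

test_that("confusion matrix bookkeeping is exact", {
  truth <- c("a", "a", "b", "b", "c")
  pred <- c("a", "b", "b", "b", "c")
  ca <- confusionAndAccuracy(pred, truth)
  expect_equal(ca$overall, 4 / 5)
  expect_equal(unname(rowSums(ca$confusion)),
               as.numeric(table(factor(truth))))
  perfect <- confusionAndAccuracy(truth, truth)
  expect_equal(perfect$overall, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_error(confusionAndAccuracy(character(0), character(0)), "empty")
})
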