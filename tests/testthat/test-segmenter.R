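test_that("blank and degenerate frames yield no ROIs", {
  set.seed(1)
  blank <- matrix(0.5, 80, 80) + matrix(rnorm(6400, 0, 0.01), 80, 80)
  expect_length(segmentFrame(blank), 0)
  expect_warning(out <- segmentFrame(matrix(0.5, 40, 40)),
                 "constant")
  expect_length(out, 0)
})

test_that("well-separated particles are recovered one ROI each with sub-pixel centroids", {
  g <- make_grid_frame(10, kind = "disk", seed = 2)
  set <- segmentFrame(g$frame)
  expect_length(set, 10)
  roi <- roiTable(set)
  for (i in seq_len(g$n)) {
    inside <- roi$x0 <= g$centers[i, 1] & g$centers[i, 1] < roi$x1 &
      roi$y0 <= g$centers[i, 2] & g$centers[i, 2] < roi$y1
    expect_equal(sum(inside), 1)
    j <- which(inside)
    err <- sqrt((roi$cx[j] - g$centers[i, 1])^2 +
                (roi$cy[j] - g$centers[i, 2])^2)
    expect_lt(err, 1)
  }
})

test_that("nearby particles merge under a wide closing radius", {
  # two disks 4 px apart edge-to-edge, closing radius large enough to fuse
  set.seed(3)
  frame <- matrix(0.5, 60, 80)
  spr <- makeSprite(SpriteSpec("disk", diameterUm = 10), seed = 3)
  P <- nrow(spr$patch); h <- (P - 1L) / 2
  blit <- function(fr, cx, cy) {
    ys <- (cy - h):(cy + h) + 1L; xs <- (cx - h):(cx + h) + 1L
    fr[ys, xs] <- fr[ys, xs] + 0.5 * spr$patch
    fr
  }
  # mask radius is ~3.2 px (10 um at 1.55 um/px), so centres 10 px apart
  # leave a ~3.5 px gap between the masks
  gap <- 10L
  frame <- blit(frame, 30L, 30L)
  frame <- blit(frame, 30L + gap, 30L)
  frame <- frame + matrix(rnorm(60 * 80, 0, 0.005), 60, 80)
  near <- segmentFrame(frame, SegmenterParams(closingRadiusPx = 0L))
  expect_length(near, 2)
  fused <- segmentFrame(frame, SegmenterParams(closingRadiusPx = 3L))
  expect_length(fused, 1)
  # the fused ROI contains both centres -> scored as one merge
  truth <- data.frame(frame = 1L, particle_id = c("a", "b"),
                      x = c(30, 30 + gap), y = c(30, 30),
                      is_background = FALSE,
                      x0 = c(30L - h, 30L + gap - h), y0 = 30L - h,
                      stringsAsFactors = FALSE)
  truth$mask <- list(spr$mask, spr$mask)
  ev <- evaluateOda(fused, truth)
  expect_equal(ev@merge, 1L)
  expect_equal(ev@truePositive, 0L)
})

test_that("five-category scoring covers TP, FP, FN and split cases", {
  g <- make_grid_frame(6, kind = "ellipse", seed = 4)
  set <- segmentFrame(g$frame)
  truth <- grid_truth(g)
  ev <- evaluateOda(set, truth)
  expect_equal(ev@truePositive, 6L)
  expect_equal(ev@falsePositive + ev@falseNegative + ev@merge + ev@split, 0L)
  expect_equal(ev@accuracy, 1)
  # an extra fabricated ROI overlapping nothing is a false positive
  fake_roi <- roiTable(set)[1, ]
  fake_roi$roi_id <- "fake"
  fake_roi$x0 <- 1L; fake_roi$x1 <- 5L; fake_roi$y0 <- 1L; fake_roi$y1 <- 5L
  fp_set <- ParticleSet(
    roi = rbind(roiTable(set), fake_roi),
    masks = c(roiMasks(set), list(matrix(TRUE, 4, 4))),
    crops = c(roiCrops(set), list(matrix(0.5, 4, 4))))
  ev2 <- evaluateOda(fp_set, truth)
  expect_equal(ev2@falsePositive, 1L)
  expect_equal(ev2@truePositive, 6L)
  # splitting one truth mask across two ROIs scores a split
  half <- truth$mask[[1]]
  half_l <- half; half_l[, (ncol(half) %/% 2 + 1):ncol(half)] <- FALSE
  half_r <- half & !half_l
  roi1 <- roiTable(set)[1, ]
  split_set <- ParticleSet(
    roi = rbind(transform(roi1, roi_id = "L"),
                transform(roi1, roi_id = "R")),
    masks = list(half_l, half_r),
    crops = list(matrix(0.5, nrow(half), ncol(half)),
                 matrix(0.5, nrow(half), ncol(half))))
  split_set@roi$x0 <- truth$x0[1]; split_set@roi$y0 <- truth$y0[1]
  split_set@roi$x1 <- truth$x0[1] + ncol(half)
  split_set@roi$y1 <- truth$y0[1] + nrow(half)
  ev3 <- evaluateOda(split_set, truth[1, ])
  expect_equal(ev3@split, 1L)
  expect_error(evaluateOda(set, transform(truth, frame = 99L)),
               "mismatch")
})

test_that("category counts never exceed the number of ROIs", {
  for (s in 1:3) {
    cfg <- SceneConfig(nFrames = 2, nTargetsPerFrame = 15,
                       nBackground = 3, seed = 40 + s)
    sc <- renderSequence(cfg)
    set <- segmentFrames(sc)
    ev <- evaluateOda(set, groundTruth(sc))
    expect_lte(ev@truePositive + ev@falsePositive + ev@falseNegative +
               ev@merge + ev@split, length(set))
  }
})

test_that("raising the minimum area never increases the ROI count", {
  g <- make_grid_frame(8, kind = "colony", seed = 5)
  counts <- vapply(c(1L, 10L, 40L, 200L), function(a)
    length(segmentFrame(g$frame, SegmenterParams(minAreaPx = a))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("concentration conversion follows the imaged-volume geometry", {
  expect_equal(estimateConcentration(1, 725 * 545, 200),
               1 / (725 * 545 * 200 * 1e-12), tolerance = 1e-12)
  expect_equal(estimateConcentration(1), 12655, tolerance = 0.01)
  expect_equal(estimateConcentration(0), 0)
  expect_equal(estimateConcentration(3, depthUm = 400),
               estimateConcentration(3, depthUm = 200) / 2)
  expect_error(estimateConcentration(1, fovUm2 = 0))
  expect_error(estimateConcentration(1, depthUm = -5))
})
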