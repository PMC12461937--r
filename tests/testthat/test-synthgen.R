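test_that("sprite rasterisation respects the stated pixel geometry", {
  # 5 um disk at 1.55 um/px: mask diameter ~ 3.2 px
  s <- makeSprite(SpriteSpec("disk", diameterUm = 5), umPerPx = 1.55,
                  seed = 1)
  row_widths <- rowSums(s$mask)
  expect_equal(max(row_widths), 3.2, tolerance = 0.4)
  # patch extent scales with diameter
  s2 <- makeSprite(SpriteSpec("disk", diameterUm = 10), umPerPx = 1.55,
                   seed = 1)
  expect_gt(sum(s2$mask), sum(s$mask))
  # area-equivalence across shape kinds (within rasterisation error)
  for (kind in c("disk", "ellipse", "filament", "colony")) {
    sk <- makeSprite(SpriteSpec(kind, diameterUm = 12), seed = 3)
    expect_equal(sum(sk$mask), pi * (12 / 1.55 / 2)^2, tolerance = 0.35)
  }
  expect_error(makeSprite(SpriteSpec("disk", diameterUm = -1)))
})

test_that("blur and contrast behave as identity/invisibility limits", {
  sharp <- makeSprite(SpriteSpec("ellipse", blurSigmaPx = 0), seed = 5)
  sharp2 <- makeSprite(SpriteSpec("ellipse", blurSigmaPx = 0), seed = 5)
  expect_identical(sharp$patch, sharp2$patch)   # blur 0 = raw raster
  expect_identical(sharp$patch != 0, sharp$mask)
  zero <- makeSprite(SpriteSpec("disk", intensityContrast = 0), seed = 5)
  expect_true(all(zero$patch == 0))             # invisible
  expect_true(any(zero$mask))                   # mask still defined
})

test_that("rendered sequences are deterministic and fully ground-truthed", {
  cfg <- SceneConfig(nFrames = 4, nTargetsPerFrame = 10, nBackground = 3,
                     seed = 99)
  sc1 <- renderSequence(cfg)
  sc2 <- renderSequence(cfg)
  expect_identical(frames(sc1), frames(sc2))
  expect_identical(groundTruth(sc1)$x, groundTruth(sc2)$x)
  tr <- groundTruth(sc1)
  # 13 records per frame
  expect_equal(as.numeric(table(tr$frame)), rep(13, 4))
  # background ids recur in every frame; target ids occur exactly once
  bg_ids <- unique(tr$particle_id[tr$is_background])
  for (id in bg_ids)
    expect_equal(sum(tr$particle_id == id), 4)
  tg <- table(tr$particle_id[!tr$is_background])
  expect_true(all(tg == 1))
})

test_that("background jitter is bounded and zero jitter freezes positions", {
  cfg0 <- SceneConfig(nFrames = 5, nTargetsPerFrame = 0, nBackground = 4,
                      maxJitterPx = 0, seed = 12)
  tr0 <- groundTruth(renderSequence(cfg0))
  for (id in unique(tr0$particle_id)) {
    p <- tr0[tr0$particle_id == id, ]
    expect_equal(length(unique(p$x)), 1)
    expect_equal(length(unique(p$y)), 1)
  }
  cfgJ <- SceneConfig(nFrames = 8, nTargetsPerFrame = 0, nBackground = 6,
                      maxJitterPx = 12, seed = 13)
  trJ <- groundTruth(renderSequence(cfgJ))
  for (id in unique(trJ$particle_id)) {
    p <- trJ[trJ$particle_id == id, ]
    # all positions lie within radius maxJitterPx of the (unobserved) base,
    # so pairwise distances are bounded by twice the cap plus rounding
    dmax <- max(dist(cbind(p$x, p$y)))
    expect_lte(dmax, 2 * 12 + sqrt(2))
  }
})

test_that("fov coverage matches analytic values and is monotone", {
  cfg <- SceneConfig(nFrames = 2, nTargetsPerFrame = 0, nBackground = 0,
                     seed = 1)
  sc <- renderSequence(cfg)
  expect_equal(fovCoverage(groundTruth(sc), cfg), 0)
  # one disk of ~1185 um^2 in the 725x545 um field -> ~0.3%
  d_um <- 2 * sqrt(1185 / pi)
  cfg1 <- SceneConfig(nFrames = 1, nTargetsPerFrame = 1, nBackground = 0,
                      diameterRangeUm = c(d_um, d_um), seed = 2)
  sc1 <- renderSequence(cfg1)
  cov1 <- fovCoverage(groundTruth(sc1), cfg1)
  expect_equal(cov1, 100 * 1185 / (725 * 545), tolerance = 0.1)
  # permutation invariance of particle ids
  tr <- groundTruth(sc1)
  trp <- tr[sample(nrow(tr)), ]
  expect_equal(fovCoverage(trp, cfg1), cov1)
  # adding a particle never decreases coverage
  cfg2 <- SceneConfig(nFrames = 1, nTargetsPerFrame = 2, nBackground = 0,
                      diameterRangeUm = c(d_um, d_um), seed = 2)
  sc2 <- renderSequence(cfg2)
  expect_gte(fovCoverage(groundTruth(sc2), cfg2), cov1 - 1e-9)
  expect_error(fovCoverage("nonsense", cfg1))
})

test_that("default densities reproduce the stated coverage fractions", {
  # 10+3, 15+5, 25+8 particles per frame -> ~0.3, 0.5, 0.8% coverage
  expected <- c(0.3, 0.5, 0.8)
  dens <- list(c(10, 3), c(15, 5), c(25, 8))
  for (i in 1:3) {
    cfg <- SceneConfig(nFrames = 3, nTargetsPerFrame = dens[[i]][1],
                       nBackground = dens[[i]][2], seed = 20 + i)
    cov <- fovCoverage(groundTruth(renderSequence(cfg)), cfg)
    expect_equal(cov, expected[i], tolerance = 0.2 / expected[i])
  }
})

test_that("focus pairs are balanced, blur-ordered and reproducible", {
  fp <- makeFocusPairs(30, seed = 4)
  expect_equal(nrow(fp), 60)
  expect_equal(as.numeric(table(fp$label)), c(30, 30))
  # blurred member has strictly lower max gradient than its sharp twin
  grad_max <- function(crop) {
    gx <- fimpipe:::.conv3(crop, fimpipe:::.sobel_x)
    gy <- fimpipe:::.conv3(crop, fimpipe:::.sobel_y)
    max(sqrt(gx^2 + gy^2))
  }
  for (i in seq_len(30)) {
    p <- fp[fp$pair_id == i, ]
    expect_lt(grad_max(p$crop[[which(p$label == "out_of_focus")]]),
              grad_max(p$crop[[which(p$label == "in_focus")]]))
  }
  fp2 <- makeFocusPairs(30, seed = 4)
  expect_identical(fp$crop, fp2$crop)
})

test_that("scenes round-trip through the on-disk format", {
  dir <- tempfile("scene")
  cfg <- SceneConfig(nFrames = 2, nTargetsPerFrame = 3, nBackground = 1,
                     seed = 31)
  sc <- renderSequence(cfg)
  writeScene(sc, dir)
  expect_length(list.files(dir, pattern = "frame_\\d+\\.png"), 2)
  frs <- readFrames(dir)
  # 8-bit quantisation error only
  expect_lt(max(abs(frs[[1]] - frames(sc)[[1]])), 1 / 255)
  jl <- readLines(file.path(dir, "truth.jsonl"))
  expect_length(jl, nrow(groundTruth(sc)))
  rec <- jsonlite::fromJSON(jl[1])
  expect_true(all(c("frame", "particle_id", "x", "y", "is_background")
                  %in% names(rec)))
})
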