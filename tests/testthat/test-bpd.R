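test_that("position clustering follows DBSCAN semantics", {
  p <- bpd_table_params(eps = 10)
  # three sightings of one particle displaced within eps pairwise
  tab <- particle_table(frame = 1:3, cx = c(100, 104, 99),
                        cy = c(50, 53, 47))
  cl <- clusterByPosition(tab, p)
  expect_equal(length(unique(cl)), 1)
  expect_true(all(cl == cl[1]) && cl[1] > 0)
  # a lone particle with nothing within eps is noise
  tab2 <- rbind(tab, particle_table(2L, 300, 300))
  expect_equal(clusterByPosition(tab2, p)[4], 0L)
  # two stationary particles 5 eps apart form two clusters of three
  tab3 <- rbind(particle_table(1:3, cx = c(50, 51, 49), cy = 50),
                particle_table(1:3, cx = c(100, 101, 99), cy = 50))
  cl3 <- clusterByPosition(tab3, p)
  expect_equal(length(setdiff(unique(cl3), 0L)), 2)
  expect_equal(as.numeric(table(cl3)), c(3, 3))
  # brute-force check: members of one cluster chain within eps
  d <- as.matrix(dist(cbind(tab3$cx, tab3$cy)))
  for (k in setdiff(unique(cl3), 0L)) {
    idx <- which(cl3 == k)
    expect_true(all(apply(d[idx, idx, drop = FALSE], 1,
                          function(r) sum(r <= 10) >= 2)))
  }
  expect_length(clusterByPosition(particle_table(integer(0), numeric(0),
                                                 numeric(0)), p), 0)
})

test_that("feature sub-clustering separates co-located movers", {
  p <- bpd_table_params(tol = 0.3)
  # identical copies form one sub-cluster
  same <- particle_table(1:3, cx = 10, cy = 10, area = 50, inten = 0.3)
  expect_equal(length(unique(subclusterByFeatures(same, p))), 1)
  # a co-located mover with 10x area splits off
  mix <- rbind(particle_table(1:2, cx = 10, cy = 10, area = 50),
               particle_table(2L, cx = 12, cy = 10, area = 500))
  sub <- subclusterByFeatures(mix, p)
  expect_equal(length(unique(sub)), 2)
  expect_equal(sub[1], sub[2])
  expect_false(sub[3] == sub[1])
  # infinite tolerance degenerates to the position cluster
  pInf <- bpd_table_params(tol = Inf)
  expect_equal(length(unique(subclusterByFeatures(mix, pInf))), 1)
  expect_error(subclusterByFeatures(mix[, c("frame", "cx", "cy")], p),
               "schema")
})

test_that("the two-of-three rule flags recurrence across distinct frames only", {
  # members in frames t and t+2 -> both flagged
  fr <- c(1L, 3L)
  expect_true(all(flagBackground(fr, c(1L, 1L), c(1L, 1L))))
  # a sub-cluster entirely within one frame flags nothing
  expect_false(any(flagBackground(c(2L, 2L), c(1L, 1L), c(1L, 1L))))
  # noise particles are never flagged
  expect_false(any(flagBackground(1:3, c(0L, 0L, 0L), c(0L, 0L, 0L))))
})

test_that("windowed BPD handles boundaries, degenerate input and clean scenes", {
  p <- bpd_table_params(eps = 15)
  expect_error(runBpd(particle_table(1:2, c(1, 2), c(1, 2)), p),
               "3 frames")
  # exactly three frames equals a single window
  tab <- rbind(particle_table(1:3, cx = c(50, 52, 48), cy = 50),
               particle_table(1:3, cx = c(200, 260, 320), cy = 200))
  flags <- runBpd(tab, p)
  win <- fimpipe:::.flag_window(tab, p)
  expect_identical(flags, win)
  expect_identical(flags, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # all-unique well-separated particles: zero flags
  set.seed(21)
  uniq <- particle_table(rep(1:5, each = 4),
                         cx = seq(10, 770, by = 40),
                         cy = rep(c(10, 200, 400, 600), 5),
                         area = seq(20, 400, by = 20))
  expect_false(any(runBpd(uniq, p)))
})

test_that("windowed BPD agrees with the brute-force oracle on well-separated scenes", {
  set.seed(22)
  eps <- 20
  # 6 stationary particles (displacement < eps/2), 12 one-off particles
  # all mutual distances > 2 eps by grid construction
  tabs <- list()
  grid <- expand.grid(x = seq(60, 560, by = 100),
                      y = seq(60, 460, by = 100))
  stopifnot(nrow(grid) >= 18)
  for (i in 1:6) {
    tabs[[i]] <- particle_table(1:6,
      cx = grid$x[i] + runif(6, -eps / 5, eps / 5),
      cy = grid$y[i] + runif(6, -eps / 5, eps / 5),
      area = 30 + 7 * i, inten = 0.2 + 0.02 * i)
  }
  for (i in 7:18) {
    tabs[[i]] <- particle_table(sample(1:6, 1), cx = grid$x[i],
                                cy = grid$y[i], area = 400 + 13 * i,
                                inten = 0.5 + 0.01 * i)
  }
  tab <- do.call(rbind, tabs)
  tab <- tab[order(tab$frame), ]
  p <- bpd_table_params(eps = eps)
  expect_identical(runBpd(tab, p), bpd_oracle(tab, eps))
  # stationary sightings all flagged, one-off all clear
  expect_true(all(runBpd(tab, p)[tab$area < 300]))
  expect_false(any(runBpd(tab, p)[tab$area >= 300]))
})

test_that("removing flagged particles leaves nothing new to flag", {
  set.seed(23)
  tab <- rbind(
    particle_table(rep(1:5, each = 2),
                   cx = rep(c(100, 300), 5) + runif(10, -3, 3),
                   cy = rep(c(100, 200), 5) + runif(10, -3, 3),
                   area = rep(c(40, 80), 5)),
    particle_table(1:5, cx = seq(500, 540, 10) + 40 * (1:5),
                   cy = 400, area = 25 + 15 * (1:5)))
  p <- bpd_table_params()
  flags <- runBpd(tab, p)
  survivors <- tab[!flags, ]
  if (length(unique(survivors$frame)) >= 3)
    expect_false(any(runBpd(survivors, p)))
})

test_that("label scoring arithmetic is exact", {
  perfect <- evaluateBpd(c(TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$false_positives + perfect$false_negatives, 0)
  # the all-valid predictor scores (N - b) / N
  isbg <- c(rep(TRUE, 3), rep(FALSE, 7))
  naive <- evaluateBpd(rep(FALSE, 10), isbg)
  expect_equal(naive$accuracy, 7 / 10)
  expect_equal(naive$false_negatives, 3)
})

test_that("end-to-end scene labelling transfers ROI flags to ground truth", {
  cfg <- SceneConfig(nFrames = 6, nTargetsPerFrame = 8, nBackground = 3,
                     seed = 77)
  res <- runBpdScene(renderSequence(cfg))
  expect_equal(nrow(res$truth), 6 * 11)
  ev <- evaluateBpdParticles(res$truth)
  expect_gt(ev$accuracy, 0.9)
  # background ids dominate the flags
  tr <- res$truth
  expect_gt(mean(tr$predicted_background[tr$is_background]), 0.8)
})
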