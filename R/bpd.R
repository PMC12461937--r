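# Background-particle detection (BPD): a stationary particle stuck in the
# flow cell is re-imaged in successive frames at nearly the same position
# with nearly identical features, causing duplicate counts. The two-stage
# algorithm clusters particles of three consecutive frames by x-y position
# (DBSCAN), sub-clusters each position cluster by feature agreement, and
# flags a particle as background only when its sub-cluster recurs in at
# least two of the three frames.

#' Stage 1: DBSCAN position clustering of a three-frame window
#'
#' @param particles data.frame with columns `frame`, `cx`, `cy` (and any
#'   feature columns) for the particles of up to three consecutive frames.
#' @param params a [BpdParams-class]; `distanceThresholdPx` is the DBSCAN
#'   neighbourhood radius, `minClusterSize` the minimum points (the point
#'   itself counts).
#' @return integer cluster labels, 0 = noise.
#' @export
clusterByPosition <- function(particles, params = BpdParams()) {
  validObject(params)
  if (nrow(particles) == 0L) return(integer(0))
  .dbscan(cbind(particles$cx, particles$cy),
          eps = params@distanceThresholdPx,
          minPts = params@minClusterSize)
}

# relative difference: |a-b| / max(|a|,|b|,eps)
.rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-9)

#' Stage 2: sub-cluster a position cluster by feature agreement
#'
#' Two members link when every feature in `params@featureSubset` agrees
#' within the relative tolerance; sub-clusters are the connected components
#' of that link graph (single linkage). Singleton sub-clusters are allowed.
#'
#' @param members data.frame of one position cluster's particles carrying
#'   the feature columns.
#' @param params a [BpdParams-class].
#' @return integer sub-cluster ids (1-based within the cluster).
#' @export
subclusterByFeatures <- function(members, params = BpdParams()) {
  n <- nrow(members)
  if (n == 0L) return(integer(0))
  missing_cols <- setdiff(params@featureSubset, names(members))
  if (length(missing_cols))
    stop("schema error: missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  if (n == 1L) return(1L)
  if (is.infinite(params@featureTolerance)) return(rep(1L, n))
  adj <- matrix(TRUE, n, n)
  for (f in params@featureSubset) {
    v <- members[[f]]
    rd <- .rel_diff(outer(v, rep(1, n)) , outer(rep(1, n), v))
    adj <- adj & (rd <= params@featureTolerance)
  }
  .graph_components(adj)
}

#' Apply the two-of-three flagging rule
#'
#' A particle is flagged as background iff its sub-cluster contains members
#' from at least two distinct frames of the window; noise particles (outside
#' any position cluster) are never flagged.
#'
#' @param frameIdx integer frame index per particle.
#' @param clusters stage-1 labels (0 = noise).
#' @param subclusters stage-2 ids within each cluster.
#' @return logical background flags.
#' @export
flagBackground <- function(frameIdx, clusters, subclusters) {
  flags <- logical(length(frameIdx))
  for (cl in setdiff(unique(clusters), 0L)) {
    idx <- which(clusters == cl)
    for (sc in unique(subclusters[idx])) {
      sidx <- idx[subclusters[idx] == sc]
      if (length(sidx) >= 2L &&
          length(unique(frameIdx[sidx])) >= 2L)
        flags[sidx] <- TRUE
    }
  }
  flags
}

# run both stages on one window's particles; returns logical flags
.flag_window <- function(win, params) {
  cl <- clusterByPosition(win, params)
  sub <- integer(nrow(win))
  for (k in setdiff(unique(cl), 0L)) {
    idx <- which(cl == k)
    sub[idx] <- subclusterByFeatures(win[idx, , drop = FALSE], params)
  }
  flagBackground(win$frame, cl, sub)
}

#' Run background-particle detection over a frame sequence
#'
#' Slides a three-consecutive-frame window over the sequence and combines
#' per-window flags by OR: a particle is background if any window flags it.
#'
#' @param particles data.frame with columns `frame`, `cx`, `cy` and the
#'   feature columns named in `params@featureSubset` — one row per detected
#'   particle per frame.
#' @param params a [BpdParams-class].
#' @return logical vector of background flags aligned with `particles`.
#' @export
runBpd <- function(particles, params = BpdParams()) {
  validObject(params)
  fr <- sort(unique(particles$frame))
  if (length(fr) < 3L) stop("need at least 3 frames")
  flags <- logical(nrow(particles))
  for (t in seq_len(length(fr) - 2L)) {
    wf <- fr[t:(t + 2L)]
    idx <- which(particles$frame %in% wf)
    if (!length(idx)) next
    flags[idx] <- flags[idx] |
      .flag_window(particles[idx, , drop = FALSE], params)
  }
  flags
}

#' Score background labels against ground truth
#'
#' @param predicted logical predicted background flags.
#' @param isBackground logical ground-truth background status, aligned.
#' @return list with `accuracy` (fraction of correctly labelled particles),
#'   `false_positives` (valid particles flagged), `false_negatives`
#'   (background particles missed) and `n`.
#' @export
evaluateBpd <- function(predicted, isBackground) {
  stopifnot(length(predicted) == length(isBackground))
  list(accuracy = mean(predicted == isBackground),
       false_positives = sum(predicted & !isBackground),
       false_negatives = sum(!predicted & isBackground),
       n = length(predicted))
}

#' Per-particle scoring of background labels
#'
#' Aggregates instance flags to the particle level before scoring: a
#' background particle (which recurs across frames under one id) counts as
#' detected when any of its sightings is flagged; each target sighting is
#' its own particle. This matches the ground-truth model in which a
#' background id spans the sequence while a target id occurs once.
#'
#' @param truth ground-truth table carrying `particle_id`, `is_background`
#'   and `predicted_background` (see [runBpdScene()]).
#' @return list as in [evaluateBpd()].
#' @export
evaluateBpdParticles <- function(truth) {
  pred <- tapply(truth$predicted_background, truth$particle_id, any)
  isbg <- tapply(truth$is_background, truth$particle_id, any)
  evaluateBpd(as.logical(pred), as.logical(isbg))
}

#' Segment a scene, run BPD, and label the ground-truth particles
#'
#' Convenience wrapper for synthetic evaluation: segments every frame,
#' computes the stage-2 feature subset per ROI, runs [runBpd()], and
#' transfers each ROI's flag to the ground-truth particles whose centre it
#' contains. Truth particles missed by segmentation count as unflagged.
#'
#' @param scene a [SyntheticScene-class].
#' @param params a [BpdParams-class].
#' @param segParams a [SegmenterParams-class].
#' @return list with `truth` (ground-truth table plus a `predicted_background`
#'   column), `particles` (the detected-particle table), `flags` (per-ROI
#'   flags).
#' @export
runBpdScene <- function(scene, params = BpdParams(),
                        segParams = SegmenterParams()) {
  set <- segmentFrames(scene, segParams)
  feats <- featureTable(set, features = params@featureSubset)
  particles <- cbind(roiTable(set)[, c("frame", "roi_id", "cx", "cy")],
                     feats[, params@featureSubset, drop = FALSE])
  flags <- runBpd(particles, params)
  truth <- groundTruth(scene)
  pred <- logical(nrow(truth))
  roi <- roiTable(set)
  for (t in unique(truth$frame)) {
    tidx <- which(truth$frame == t)
    ridx <- which(roi$frame == t)
    for (q in tidx) {
      x <- round(truth$x[q]); y <- round(truth$y[q])
      hit <- ridx[roi$x0[ridx] <= x & x < roi$x1[ridx] &
                  roi$y0[ridx] <= y & y < roi$y1[ridx]]
      if (length(hit) > 1L) {   # prefer a mask hit over a bbox hit
        inmask <- vapply(hit, function(i) {
          m <- roiMasks(set)[[i]]
          yy <- y - roi$y0[i] + 1L; xx <- x - roi$x0[i] + 1L
          yy >= 1L && yy <= nrow(m) && xx >= 1L && xx <= ncol(m) &&
            m[yy, xx]
        }, TRUE)
        hit <- if (any(inmask)) hit[which(inmask)[1L]] else hit[1L]
      }
      if (length(hit) == 1L) pred[q] <- flags[hit]
    }
  }
  truth$predicted_background <- pred
  list(truth = truth, particles = particles, flags = flags)
}

#' Detection-rate curve versus controlled displacement
#'
#' Calibration experiment for the distance threshold: renders sequences in
#' which every background particle travels exactly `d` pixels per frame
#' along a fixed direction, runs the full detection path, and records the
#' fraction of background particles flagged (a particle counts as detected
#' when any of its sightings is flagged), for each `d` on the grid.
#'
#' @param displacements pixel displacements to test (default 0 to 20).
#' @param params a [BpdParams-class].
#' @param segParams a [SegmenterParams-class].
#' @param nMin minimum number of background particles per displacement
#'   (default 200).
#' @param config template [SceneConfig-class]; its jitter settings are
#'   overridden per displacement.
#' @param seed base seed; each rendered sequence increments it.
#' @return data.frame with `displacement_px`, `detection_rate`, `n`.
#' @export
calibrateTolerance <- function(displacements = seq(0, 20, by = 2),
                               params = BpdParams(),
                               segParams = SegmenterParams(),
                               nMin = 200L, config = NULL, seed = 1L) {
  out <- lapply(displacements, function(d) {
    hits <- 0L; total <- 0L; s <- seed
    while (total < nMin) {
      cfg <- SceneConfig(nFrames = 6L, nTargetsPerFrame = 5L,
                         nBackground = 10L, jitterMode = "linear",
                         displacementPx = d, seed = s)
      if (!is.null(config)) {
        cfg@frameWidthPx <- config@frameWidthPx
        cfg@frameHeightPx <- config@frameHeightPx
        cfg@umPerPx <- config@umPerPx
        cfg@backgroundLevel <- config@backgroundLevel
        cfg@noiseSigma <- config@noiseSigma
        cfg@diameterRangeUm <- config@diameterRangeUm
        cfg@contrastRange <- config@contrastRange
      }
      res <- runBpdScene(renderSequence(cfg), params, segParams)
      tr <- res$truth[res$truth$is_background, ]
      det <- tapply(tr$predicted_background, tr$particle_id, any)
      hits <- hits + sum(det)
      total <- total + length(det)
      s <- s + 1L
    }
    data.frame(displacement_px = d, detection_rate = hits / total,
               n = total)
  })
  do.call(rbind, out)
}
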