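# Object detection: threshold-plus-connected-components segmentation of
# widefield frames into particle ROIs, and the five-category scoring scheme
# (true positive / false positive / false negative / merge / split) used to
# evaluate detections against ground truth.

#' Five-category object-detection evaluation result
#'
#' @slot truePositive,falsePositive,falseNegative,merge,split counts.
#' @slot accuracy `truePositive / nTruth`.
#' @slot nTruth number of ground-truth particles scored.
#' @export
setClass("OdaEvalResult", representation(
  truePositive = "integer", falsePositive = "integer",
  falseNegative = "integer", merge = "integer", split = "integer",
  accuracy = "numeric", nTruth = "integer"
))

setMethod("show", "OdaEvalResult", function(object) {
  cat(sprintf(
    "OdaEvalResult: TP=%d FP=%d FN=%d merge=%d split=%d (accuracy %.3f on %d particles)\n",
    object@truePositive, object@falsePositive, object@falseNegative,
    object@merge, object@split, object@accuracy, object@nTruth))
})

#' Segment one widefield frame into particle ROIs
#'
#' Foreground is the set of pixels deviating from the background estimate by
#' more than `thresholdOffset` (in either direction). After an optional
#' morphological closing (square structuring element), connected components
#' (8-connectivity) within the `[minAreaPx, maxAreaPx]` area range become
#' ROIs; crops are padded by `padPx` and clipped to the frame.
#'
#' @param frame numeric matrix (rows = y, columns = x), intensities in
#'   `[0, 1]`.
#' @param params a [SegmenterParams-class].
#' @param frameIndex integer frame index recorded in the ROI table.
#' @return a [ParticleSet-class].
#' @export
segmentFrame <- function(frame, params = SegmenterParams(),
                         frameIndex = 1L) {
  validObject(params)
  if (length(frame) == 0L) stop("frame is empty")
  rng <- range(frame)
  if (diff(rng) < 1e-12) {
    warning("constant or saturated frame; returning no ROIs")
    return(ParticleSet(roi = .empty_roi()))
  }
  bg <- switch(params@backgroundEstimation,
    flat = matrix(median(frame), nrow(frame), ncol(frame)),
    median = {
      img <- EBImage::Image(t(frame))
      t(EBImage::imageData(EBImage::medianFilter(img,
                                                 params@medianRadiusPx)))
    })
  fg <- abs(frame - bg) > params@thresholdOffset
  if (params@closingRadiusPx > 0L) {
    r <- params@closingRadiusPx
    fg <- .erode_cheb(.dilate_cheb(fg, r), r)
  }
  lab <- .label_components8(matrix(as.integer(fg), nrow(fg), ncol(fg)))
  .extract_rois(frame, lab, params, frameIndex)
}

.empty_roi <- function() {
  data.frame(frame = integer(), roi_id = character(), x0 = integer(),
             y0 = integer(), x1 = integer(), y1 = integer(),
             cx = numeric(), cy = numeric(), area_px = integer(),
             crop_x0 = integer(), crop_y0 = integer(),
             stringsAsFactors = FALSE)
}

.extract_rois <- function(frame, lab, params, frameIndex) {
  H <- nrow(frame); W <- ncol(frame)
  ind <- which(lab > 0L)
  if (!length(ind)) return(ParticleSet(roi = .empty_roi()))
  lv <- lab[ind]
  rr <- (ind - 1L) %% H + 1L
  cc <- (ind - 1L) %/% H + 1L
  pieces <- split(seq_along(ind), lv)
  rois <- list(); masks <- list(); crops <- list()
  k <- 0L
  for (p in pieces) {
    area <- length(p)
    if (area < params@minAreaPx || area > params@maxAreaPx) next
    k <- k + 1L
    ys <- rr[p]; xs <- cc[p]
    y0 <- min(ys); y1 <- max(ys); x0 <- min(xs); x1 <- max(xs)
    mask <- matrix(FALSE, y1 - y0 + 1L, x1 - x0 + 1L)
    mask[cbind(ys - y0 + 1L, xs - x0 + 1L)] <- TRUE
    pad <- params@padPx
    cy0 <- max(1L, y0 - pad); cy1 <- min(H, y1 + pad)
    cx0 <- max(1L, x0 - pad); cx1 <- min(W, x1 + pad)
    rois[[k]] <- data.frame(
      frame = frameIndex, roi_id = sprintf("f%04d_r%04d", frameIndex, k),
      x0 = x0 - 1L, y0 = y0 - 1L, x1 = x1, y1 = y1,   # half-open, 0-based
      cx = mean(xs) - 1, cy = mean(ys) - 1, area_px = area,
      crop_x0 = cx0 - 1L, crop_y0 = cy0 - 1L,
      stringsAsFactors = FALSE)
    masks[[k]] <- mask
    crops[[k]] <- frame[cy0:cy1, cx0:cx1, drop = FALSE]
  }
  if (k == 0L) return(ParticleSet(roi = .empty_roi()))
  ParticleSet(roi = do.call(rbind, rois), masks = masks, crops = crops)
}

#' Segment every frame of a sequence
#'
#' @param x a [SyntheticScene-class] or a list of frame matrices.
#' @param params a [SegmenterParams-class].
#' @return a [ParticleSet-class] covering all frames.
#' @export
segmentFrames <- function(x, params = SegmenterParams()) {
  frs <- if (is(x, "SyntheticScene")) frames(x) else x
  sets <- lapply(seq_along(frs), function(t)
    segmentFrame(frs[[t]], params, frameIndex = t))
  sets <- sets[vapply(sets, length, 1L) > 0L]
  if (!length(sets)) return(ParticleSet(roi = .empty_roi()))
  do.call(c, sets)
}

#' Score detections against ground truth in five categories
#'
#' Each ROI receives exactly one category. An ROI is matched to a truth
#' particle when it contains at least half of that particle's mask pixels.
#' A truth particle overlapping two or more ROIs (at least 5% of its mask in
#' each) is a split; an ROI matched to two or more particles is a merge; an
#' ROI matched to exactly one particle is a true positive when the particle
#' lies entirely inside it and a false negative otherwise ("particle not
#' entirely in ROI"); an ROI matched to nothing is a false positive.
#' Accuracy is `TP / (number of ground-truth particles)`.
#'
#' @param set a [ParticleSet-class].
#' @param truth ground-truth table from [renderSequence()].
#' @return an [OdaEvalResult-class].
#' @export
evaluateOda <- function(set, truth) {
  roi <- roiTable(set)
  if (nrow(roi) > 0 && nrow(truth) > 0 &&
      !any(roi$frame %in% truth$frame))
    stop("frame-index mismatch between ROIs and ground truth")
  n_truth <- nrow(truth)
  tp <- fp <- fn <- mg <- sp <- 0L
  for (t in sort(unique(c(roi$frame, truth$frame)))) {
    ridx <- which(roi$frame == t)
    tidx <- which(truth$frame == t)
    # canvas big enough for everything on this frame
    maxx <- max(c(1L, roi$x1[ridx],
                  truth$x0[tidx] + vapply(truth$mask[tidx], ncol, 1L)))
    maxy <- max(c(1L, roi$y1[ridx],
                  truth$y0[tidx] + vapply(truth$mask[tidx], nrow, 1L)))
    canvas <- matrix(0L, maxy + 1L, maxx + 1L)
    for (j in seq_along(ridx)) {
      i <- ridx[j]
      m <- roiMasks(set)[[i]]
      ys <- (roi$y0[i] + 1L):(roi$y1[i])
      xs <- (roi$x0[i] + 1L):(roi$x1[i])
      sub <- canvas[ys, xs, drop = FALSE]
      sub[m] <- j
      canvas[ys, xs] <- sub
    }
    # overlap fractions per truth particle
    part_rois <- vector("list", length(tidx))
    full_in <- logical(length(tidx))
    for (q in seq_along(tidx)) {
      i <- tidx[q]
      m <- truth$mask[[i]]
      ys <- truth$y0[i] + seq_len(nrow(m))
      xs <- truth$x0[i] + seq_len(ncol(m))
      keepy <- ys >= 1L & ys <= nrow(canvas)
      keepx <- xs >= 1L & xs <= ncol(canvas)
      labs <- canvas[ys[keepy], xs[keepx], drop = FALSE][
        m[keepy, keepx, drop = FALSE]]
      tot <- sum(m)
      tb <- table(labs[labs > 0L])
      fracs <- as.numeric(tb) / tot
      names(fracs) <- names(tb)
      part_rois[[q]] <- fracs
      full_in[q] <- length(fracs) == 1L && fracs[1] >= 1 - 1e-9
    }
    is_split <- vapply(part_rois, function(f) sum(f >= 0.05) >= 2L, TRUE)
    sp <- sp + sum(is_split)
    split_rois <- unique(unlist(lapply(which(is_split), function(q)
      names(part_rois[[q]]))))
    # ROI-level assignment over non-split particles
    matched <- vector("list", length(ridx))
    for (q in seq_along(tidx)) {
      if (is_split[q]) next
      f <- part_rois[[q]]
      hit <- names(f)[f >= 0.5]
      if (length(hit) == 1L) {
        j <- as.integer(hit)
        matched[[j]] <- c(matched[[j]], q)
      }
    }
    for (j in seq_along(ridx)) {
      if (as.character(j) %in% split_rois) next  # consumed by a split
      nm <- length(matched[[j]])
      if (nm >= 2L) mg <- mg + 1L
      else if (nm == 1L) {
        if (full_in[matched[[j]]]) tp <- tp + 1L else fn <- fn + 1L
      } else fp <- fp + 1L
    }
  }
  new("OdaEvalResult", truePositive = tp, falsePositive = fp,
      falseNegative = fn, merge = mg, split = sp,
      accuracy = if (n_truth > 0) tp / n_truth else NA_real_,
      nTruth = n_truth)
}

#' Convert a mean per-frame particle count to a concentration
#'
#' Uses the imaged volume per frame: field-of-view area times the flow-cell
#' channel depth.
#'
#' @param meanParticlesPerFrame mean detected particles per frame.
#' @param fovUm2 field-of-view area in square microns (default 725 x 545).
#' @param depthUm flow-channel depth in microns (default 200).
#' @return particles per millilitre.
#' @examples
#' estimateConcentration(1)  # ~1.27e4 per mL
#' @export
estimateConcentration <- function(meanParticlesPerFrame,
                                  fovUm2 = 725 * 545, depthUm = 200) {
  if (fovUm2 <= 0 || depthUm <= 0) stop("geometry must be positive")
  if (meanParticlesPerFrame < 0) stop("count must be non-negative")
  meanParticlesPerFrame / (fovUm2 * depthUm * 1e-12)
}
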