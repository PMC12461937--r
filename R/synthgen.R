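# Synthetic widefield scene generator.
#
# Reproduces the evaluation protocol used to validate the pipeline without
# any instrument data: blank frames at the instrument geometry are seeded
# with freshly placed target particles and with stationary background
# particles whose identical copies are re-rendered in every frame at a
# jittered position.

# ---- sprite rasterisation ---------------------------------------------------

# Raster one sprite; returns list(patch, mask). `patch` is the relative
# intensity deviation (fraction of background level), `mask` the unblurred
# support. Shape-specific randomness (aspect, orientation, colony layout,
# blob texture) is drawn from the current RNG stream.
.raster_sprite <- function(spec, umPerPx) {
  r <- (spec@diameterUm / umPerPx) / 2   # area-equivalent radius in px
  kind <- spec@shapeKind
  aspect <- switch(kind,
    disk = 1, ellipse = runif(1, 1.8, 3), filament = runif(1, 8, 15),
    colony = 1, debris = 1, ring = 1)
  theta <- runif(1, 0, pi)
  half <- switch(kind,
    disk = r,
    ellipse = r * sqrt(aspect),
    filament = sqrt(pi * r^2 / aspect) * aspect / 2,
    colony = 1.6 * r,
    debris = 1.8 * r,
    ring = r / sqrt(1 - 0.36))
  P <- 2L * as.integer(ceiling(half + 3 * spec@blurSigmaPx + 1)) + 1L
  c0 <- (P + 1L) / 2                      # centre pixel (1-based)
  xx <- matrix(rep(seq_len(P) - c0, each = P), P, P)   # column offsets
  yy <- matrix(rep(seq_len(P) - c0, times = P), P, P)  # row offsets
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  mask <- switch(kind,
    disk = (xx^2 + yy^2) <= r^2,
    ellipse = {
      a <- r * sqrt(aspect); b <- r / sqrt(aspect)
      (u / a)^2 + (v / b)^2 <= 1
    },
    filament = {
      w <- sqrt(pi * r^2 / aspect); L <- aspect * w
      abs(u) <= L / 2 & abs(v) <= w / 2
    },
    colony = {
      # connected aggregate: each cell is attached to an existing one
      k <- sample(4:9, 1)
      rc <- r / sqrt(k)
      centers <- matrix(0, k, 2)
      for (i in seq_len(k)[-1]) {
        repeat {
          anchor <- centers[sample(i - 1L, 1), ]
          ang <- runif(1, 0, 2 * pi)
          cand <- anchor + runif(1, 1.2, 1.8) * rc * c(cos(ang), sin(ang))
          if (sqrt(sum(cand^2)) <= 1.6 * r - rc) { centers[i, ] <- cand; break }
        }
      }
      m <- matrix(FALSE, P, P)
      for (i in seq_len(k))
        m <- m | ((xx - centers[i, 1])^2 + (yy - centers[i, 2])^2 <= rc^2)
      m
    },
    debris = {
      noise <- .gauss_blur(matrix(rnorm(P * P), P, P), max(1, r / 2))
      noise <- noise - 0.002 * (xx^2 + yy^2) / max(1, r)  # keep blob central
      target <- pi * r^2
      thr <- quantile(noise, probs = 1 - min(0.9, target / (P * P)))
      noise >= thr
    },
    ring = {
      a <- r / 0.8
      rho2 <- xx^2 + yy^2
      rho2 <= a^2 & rho2 >= (0.6 * a)^2
    })
  if (!any(mask)) mask[round(c0), round(c0)] <- TRUE
  patch <- spec@intensityContrast * (mask * 1)
  if (spec@blurSigmaPx > 0) patch <- .gauss_blur(patch, spec@blurSigmaPx)
  idx <- which(mask, arr.ind = TRUE)
  list(patch = patch, mask = mask,
       mcx = mean(idx[, 2]) - 1, mcy = mean(idx[, 1]) - 1,  # 0-based
       area = nrow(idx))
}

#' Rasterise one sprite
#'
#' Renders the sprite described by a [SpriteSpec-class] into a small image
#' patch (relative intensity deviation, as a fraction of the background
#' level) and a binary support mask. Blur is applied after rasterisation, so
#' the mask always marks the sharp support.
#'
#' @param spec a [SpriteSpec-class].
#' @param umPerPx sampling resolution in microns per pixel.
#' @param seed optional integer; when given, shape randomness is drawn from
#'   a local RNG stream and the caller's RNG state is untouched.
#' @return list with elements `patch` (numeric matrix) and `mask` (logical
#'   matrix of the same size).
#' @examples
#' s <- makeSprite(SpriteSpec("disk", diameterUm = 5), umPerPx = 1.55, seed = 1)
#' sum(s$mask)
#' @export
makeSprite <- function(spec, umPerPx = 1.55, seed = NULL) {
  validObject(spec)
  if (spec@diameterUm <= 0) stop("diameterUm must be positive")
  .with_seed(seed, .raster_sprite(spec, umPerPx))
}

# ---- sequence rendering -----------------------------------------------------

.sample_spec <- function(config, blur = NULL) {
  SpriteSpec(
    shapeKind = sample(config@shapeKinds, 1L),
    diameterUm = runif(1, config@diameterRangeUm[1], config@diameterRangeUm[2]),
    intensityContrast = runif(1, config@contrastRange[1],
                              config@contrastRange[2]),
    blurSigmaPx = if (is.null(blur))
      runif(1, config@blurSigmaRangePx[1], config@blurSigmaRangePx[2])
      else blur)
}

# jitter displacement (dx, dy) for one frame
.jitter_offset <- function(config) {
  mag <- switch(config@jitterMode,
    uniform = runif(1, 0, config@maxJitterPx),
    tnorm = {
      m <- -1
      while (m < 0 || m > 50) m <- rnorm(1, config@jitterMeanPx,
                                         config@jitterSdPx)
      m
    },
    linear = stop("linear mode handled separately"))
  ang <- runif(1, 0, 2 * pi)
  c(mag * cos(ang), mag * sin(ang))
}

#' Render a synthetic frame sequence with ground truth
#'
#' Background particles are rendered once and re-placed in every frame with
#' a bounded random jitter (or an exact per-frame travel in `"linear"` mode);
#' target particles are drawn fresh at random positions in each frame.
#' Additive Gaussian noise emulates sensor noise. The same configuration
#' (including seed) always yields bitwise-identical output.
#'
#' @param config a [SceneConfig-class].
#' @return a [SyntheticScene-class] holding the frames, the per-particle
#'   ground-truth table and the configuration.
#' @examples
#' sc <- renderSequence(SceneConfig(nFrames = 3, nTargetsPerFrame = 5,
#'                                  nBackground = 2, seed = 7))
#' table(groundTruth(sc)$is_background)
#' @export
renderSequence <- function(config) {
  validObject(config)
  set.seed(config@seed)
  W <- config@frameWidthPx; H <- config@frameHeightPx
  nF <- config@nFrames
  bg <- config@backgroundLevel

  place_margin <- function(P, slack) (P - 1L) / 2 + slack + 1
  # background sprites: one raster, re-used in every frame
  bgs <- vector("list", config@nBackground)
  for (j in seq_len(config@nBackground)) {
    spec <- .sample_spec(config)
    spr <- .raster_sprite(spec, config@umPerPx)
    P <- nrow(spr$patch)
    slack <- switch(config@jitterMode,
                    uniform = config@maxJitterPx,
                    tnorm = 50,
                    linear = 0)
    m <- place_margin(P, slack)
    if (2 * m >= W || 2 * m >= H)
      stop("placement error: sprite plus jitter margin exceeds frame")
    if (config@jitterMode == "linear") {
      d <- config@displacementPx
      ok <- FALSE
      for (try in 1:100) {
        ang <- runif(1, 0, 2 * pi)
        travel <- (nF - 1) * d * c(cos(ang), sin(ang))
        lox <- m + max(0, -travel[1]); hix <- W - 1 - m - max(0, travel[1])
        loy <- m + max(0, -travel[2]); hiy <- H - 1 - m - max(0, travel[2])
        if (lox < hix && loy < hiy) {
          base <- c(runif(1, lox, hix), runif(1, loy, hiy))
          dirv <- c(cos(ang), sin(ang))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("placement error: linear path does not fit the frame")
      bgs[[j]] <- list(spec = spec, spr = spr, base = base, dir = dirv)
    } else {
      base <- c(runif(1, m, W - 1 - m), runif(1, m, H - 1 - m))
      bgs[[j]] <- list(spec = spec, spr = spr, base = base, dir = c(0, 0))
    }
  }

  frames <- vector("list", nF)
  nrec <- nF * (config@nBackground + config@nTargetsPerFrame)
  rec <- list(frame = integer(nrec), particle_id = character(nrec),
              x = numeric(nrec), y = numeric(nrec),
              is_background = logical(nrec), shape_kind = character(nrec),
              diameter_um = numeric(nrec), contrast = numeric(nrec),
              blur_sigma = numeric(nrec), area_px = integer(nrec),
              class_label = character(nrec), x0 = integer(nrec),
              y0 = integer(nrec))
  rec_masks <- vector("list", nrec)
  ri <- 0L
  tgt_counter <- 0L
  for (t in seq_len(nF)) {
    fr <- matrix(bg, H, W)
    blit <- function(fr, spr, cx, cy) {
      # cx, cy: 0-based integer centre placement of the patch centre pixel
      P <- nrow(spr$patch)
      h <- (P - 1L) / 2
      xs <- (cx - h):(cx + h) + 1L     # 1-based columns
      ys <- (cy - h):(cy + h) + 1L
      keepx <- xs >= 1L & xs <= W; keepy <- ys >= 1L & ys <= H
      fr[ys[keepy], xs[keepx]] <- fr[ys[keepy], xs[keepx]] +
        bg * spr$patch[keepy, keepx, drop = FALSE]
      fr
    }
    add_record <- function(id, spec, spr, cx, cy, is_bg) {
      P <- nrow(spr$patch)
      h <- (P - 1L) / 2
      ri <<- ri + 1L
      rec$frame[ri] <<- t
      rec$particle_id[ri] <<- id
      rec$x[ri] <<- spr$mcx + cx - h   # 0-based mask centroid in frame
      rec$y[ri] <<- spr$mcy + cy - h
      rec$is_background[ri] <<- is_bg
      rec$shape_kind[ri] <<- spec@shapeKind
      rec$diameter_um[ri] <<- spec@diameterUm
      rec$contrast[ri] <<- spec@intensityContrast
      rec$blur_sigma[ri] <<- spec@blurSigmaPx
      rec$area_px[ri] <<- spr$area
      rec$class_label[ri] <<- spec@shapeKind
      rec$x0[ri] <<- cx - h
      rec$y0[ri] <<- cy - h
      rec_masks[[ri]] <<- spr$mask
    }
    for (j in seq_len(config@nBackground)) {
      b <- bgs[[j]]
      pos <- if (config@jitterMode == "linear")
        b$base + (t - 1) * config@displacementPx * b$dir
      else b$base + .jitter_offset(config)
      cx <- as.integer(round(pos[1])); cy <- as.integer(round(pos[2]))
      fr <- blit(fr, b$spr, cx, cy)
      add_record(sprintf("bg%03d", j), b$spec, b$spr, cx, cy, TRUE)
    }
    for (k in seq_len(config@nTargetsPerFrame)) {
      spec <- .sample_spec(config)
      spr <- .raster_sprite(spec, config@umPerPx)
      P <- nrow(spr$patch)
      m <- place_margin(P, 0)
      if (2 * m >= W || 2 * m >= H)
        stop("placement error: target sprite exceeds frame")
      tgt_counter <- tgt_counter + 1L
      cx <- as.integer(round(runif(1, m, W - 1 - m)))
      cy <- as.integer(round(runif(1, m, H - 1 - m)))
      fr <- blit(fr, spr, cx, cy)
      add_record(sprintf("tg%05d", tgt_counter), spec, spr, cx, cy, FALSE)
    }
    if (config@noiseSigma > 0)
      fr <- fr + matrix(rnorm(H * W, 0, config@noiseSigma), H, W)
    frames[[t]] <- pmin(pmax(fr, 0), 1)
  }
  truth <- as.data.frame(rec, stringsAsFactors = FALSE)
  truth$mask <- rec_masks
  new("SyntheticScene", frames = frames, truth = truth, config = config)
}

#' Field-of-view coverage of a rendered scene
#'
#' Percent of the frame surface occupied by the union of the particle masks,
#' averaged over frames. Overlapping particles are counted once (union), so
#' adding a particle can never decrease coverage.
#'
#' @param truth ground-truth table from [renderSequence()] (must carry the
#'   `mask`, `x0`, `y0` columns).
#' @param config the [SceneConfig-class] of the scene.
#' @return coverage in percent.
#' @export
fovCoverage <- function(truth, config) {
  validObject(config)
  if (config@nFrames < 1L) stop("undefined input: no frames")
  if (!is.data.frame(truth))
    stop("undefined input: truth must be a data.frame")
  W <- config@frameWidthPx; H <- config@frameHeightPx
  cov <- numeric(config@nFrames)
  for (t in seq_len(config@nFrames)) {
    idx <- which(truth$frame == t)
    if (!length(idx)) next
    occ <- matrix(FALSE, H, W)
    for (i in idx) {
      m <- truth$mask[[i]]
      P <- nrow(m)
      xs <- truth$x0[i] + seq_len(P) # 1-based columns (x0 is 0-based)
      ys <- truth$y0[i] + seq_len(P)
      keepx <- xs >= 1L & xs <= W; keepy <- ys >= 1L & ys <= H
      occ[ys[keepy], xs[keepx]] <-
        occ[ys[keepy], xs[keepx]] | m[keepy, keepx, drop = FALSE]
    }
    cov[t] <- 100 * sum(occ) / (H * W)
  }
  mean(cov)
}

# embed a patch in a noisy uniform-background crop
.embed_crop <- function(patch, bgLevel, noiseSigma, pad = 3L) {
  P <- nrow(patch)
  side <- P + 2L * pad
  crop <- matrix(bgLevel, side, side)
  crop[(pad + 1L):(pad + P), (pad + 1L):(pad + P)] <-
    bgLevel * (1 + patch)
  if (noiseSigma > 0)
    crop <- crop + matrix(rnorm(side * side, 0, noiseSigma), side, side)
  pmin(pmax(crop, 0), 1)
}

.pad_mask <- function(mask, pad = 3L) {
  P <- nrow(mask)
  m <- matrix(FALSE, P + 2L * pad, P + 2L * pad)
  m[(pad + 1L):(pad + P), (pad + 1L):(pad + P)] <- mask
  m
}

#' Generate labelled in-focus / out-of-focus crop pairs
#'
#' Training fixture generator for the focus classifier. Each pair renders
#' the same sprite twice: once sharp (`blurSigmaPx = 0`) and once blurred
#' with a sigma drawn uniformly from `blurRange`.
#'
#' @param n number of pairs.
#' @param blurRange range of blur sigmas (pixels) for the defocused member.
#' @param config a [SceneConfig-class] supplying sprite and noise settings.
#' @param seed integer seed.
#' @return data.frame with `pair_id`, `label` (`"in_focus"` /
#'   `"out_of_focus"`), `blur_sigma` and list columns `crop`, `mask`.
#' @export
makeFocusPairs <- function(n, blurRange = c(2, 5), config = SceneConfig(),
                           seed = 1L) {
  stopifnot(n > 0)
  .with_seed(seed, {
    rows <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      spec <- .sample_spec(config, blur = 0)
      spr <- .raster_sprite(spec, config@umPerPx)
      sig <- runif(1, blurRange[1], blurRange[2])
      # blur the same rasterisation; pad first so blur is not clipped
      extra <- as.integer(ceiling(3 * sig))
      pp <- nrow(spr$patch)
      padp <- matrix(0, pp + 2L * extra, pp + 2L * extra)
      padp[(extra + 1L):(extra + pp), (extra + 1L):(extra + pp)] <- spr$patch
      blurred <- .gauss_blur(padp, sig)
      noise <- config@noiseSigma
      rows[[2L * i - 1L]] <- list(
        pair_id = i, label = "in_focus", blur_sigma = 0,
        crop = .embed_crop(spr$patch, config@backgroundLevel, noise),
        mask = .pad_mask(spr$mask))
      rows[[2L * i]] <- list(
        pair_id = i, label = "out_of_focus", blur_sigma = sig,
        crop = .embed_crop(blurred, config@backgroundLevel, noise),
        mask = .pad_mask(spr$mask, extra + 3L))
    }
    out <- data.frame(
      pair_id = vapply(rows, `[[`, 1L, "pair_id"),
      label = vapply(rows, `[[`, "", "label"),
      blur_sigma = vapply(rows, `[[`, 1.0, "blur_sigma"),
      stringsAsFactors = FALSE)
    out$crop <- lapply(rows, `[[`, "crop")
    out$mask <- lapply(rows, `[[`, "mask")
    out
  })
}

#' Generate a labelled sprite crop dataset for classifier experiments
#'
#' Renders `nPerClass` crops for each requested shape class; the shape kind
#' is the class label. Used for closed-set training and, with the `"debris"`
#' and `"ring"` kinds, as out-of-distribution material.
#'
#' @param nPerClass crops per class.
#' @param classes shape kinds to render.
#' @param config a [SceneConfig-class] supplying sprite and noise settings.
#' @param blurRange range of blur sigmas applied to the crops (default none).
#' @param seed integer seed.
#' @return list with `crops` (list of matrices), `labels` (character).
#' @export
makeSpriteDataset <- function(nPerClass,
                              classes = c("disk", "ellipse", "filament",
                                          "colony"),
                              config = SceneConfig(), blurRange = c(0, 0),
                              seed = 1L) {
  .with_seed(seed, {
    crops <- list(); labels <- character()
    for (cl in classes) {
      for (i in seq_len(nPerClass)) {
        spec <- SpriteSpec(
          shapeKind = cl,
          diameterUm = runif(1, config@diameterRangeUm[1],
                             config@diameterRangeUm[2]),
          intensityContrast = runif(1, config@contrastRange[1],
                                    config@contrastRange[2]),
          blurSigmaPx = runif(1, blurRange[1], blurRange[2]))
        spr <- .raster_sprite(spec, config@umPerPx)
        crops[[length(crops) + 1L]] <-
          .embed_crop(spr$patch, config@backgroundLevel, config@noiseSigma)
        labels <- c(labels, cl)
      }
    }
    list(crops = crops, labels = labels)
  })
}

# ---- on-disk scene format ---------------------------------------------------

#' Write a scene to disk (PNG frames + JSON-lines ground truth)
#'
#' Frames are written as 8-bit grayscale PNG files with zero-padded indices
#' (`frame_0001.png`, ...); the quantisation step (1/255) is an order of
#' magnitude below the default noise floor. Ground truth goes to
#' `truth.jsonl`, one JSON record per particle per frame (masks are not
#' serialised; the mask area is).
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(scene@frames)) {
    img <- EBImage::Image(t(scene@frames[[t]]))  # EBImage is (x, y)
    EBImage::writeImage(img, file.path(dir, sprintf("frame_%04d.png", t)))
  }
  truth <- scene@truth
  truth$mask <- NULL
  con <- file(file.path(dir, "truth.jsonl"), open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(truth)))
    writeLines(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(dir)
}

#' Read frames written by [writeScene()]
#'
#' @param dir directory of `frame_*.png` files.
#' @return list of numeric matrices (rows = y, columns = x).
#' @export
readFrames <- function(dir) {
  fs <- sort(list.files(dir, pattern = "^frame_\\d+\\.(png|tif|tiff)$",
                        full.names = TRUE))
  lapply(fs, function(f) t(EBImage::imageData(EBImage::readImage(f))))
}
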