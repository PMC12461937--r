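# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# frame with sprites placed on a regular grid (guaranteed separation);
# returns frame, 0-based centers, per-sprite masks and offsets
make_grid_frame <- function(n, kind = "disk", diameterUm = 12,
                            spacing = 60L, seed = 1L, noise = 0.01,
                            bg = 0.5, blur = 0) {
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n))
  W <- spacing * ncol_grid + spacing
  H <- spacing * ceiling(n / ncol_grid) + spacing
  frame <- matrix(bg, H, W)
  centers <- matrix(0, n, 2)
  masks <- list(); offs <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    gx <- (i - 1L) %% ncol_grid
    gy <- (i - 1L) %/% ncol_grid
    cx <- spacing * gx + spacing         # 0-based
    cy <- spacing * gy + spacing
    spr <- makeSprite(SpriteSpec(kind, diameterUm = diameterUm,
                                 intensityContrast = -0.5,
                                 blurSigmaPx = blur))
    P <- nrow(spr$patch); h <- (P - 1L) / 2
    ys <- (cy - h):(cy + h) + 1L; xs <- (cx - h):(cx + h) + 1L
    frame[ys, xs] <- frame[ys, xs] + bg * spr$patch
    idx <- which(spr$mask, arr.ind = TRUE)
    centers[i, ] <- c(mean(idx[, 2]) - 1 + cx - h,
                      mean(idx[, 1]) - 1 + cy - h)
    masks[[i]] <- spr$mask
    offs[i, ] <- c(cx - h, cy - h)
  }
  frame <- pmin(pmax(frame + matrix(rnorm(H * W, 0, noise), H, W), 0), 1)
  list(frame = frame, centers = centers, masks = masks, offsets = offs,
       n = n)
}

# grid frame as a ground-truth table compatible with evaluateOda
grid_truth <- function(g, frame = 1L) {
  data.frame(frame = frame, particle_id = sprintf("p%03d", seq_len(g$n)),
             x = g$centers[, 1], y = g$centers[, 2],
             is_background = FALSE, stringsAsFactors = FALSE,
             x0 = g$offsets[, 1], y0 = g$offsets[, 2]) -> tr
  tr$mask <- g$masks
  tr
}

# particle table for table-level BPD tests: one row per sighting, with
# constant per-particle features
particle_table <- function(frame, cx, cy, area = 50, inten = 0.3) {
  n <- length(frame)
  data.frame(frame = frame, roi_id = sprintf("r%03d", seq_len(n)),
             cx = cx, cy = cy, area = rep_len(area, n),
             mean_intensity = rep_len(inten, n),
             stringsAsFactors = FALSE)
}

bpd_table_params <- function(eps = 25, tol = 0.12)
  BpdParams(distanceThresholdPx = eps, featureTolerance = tol,
            featureSubset = c("area", "mean_intensity"))

# brute-force BPD oracle: flag any sighting that has a neighbour within eps
# in another frame at most two frames away whose features agree exactly
bpd_oracle <- function(tab, eps) {
  n <- nrow(tab)
  flags <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    df <- abs(tab$frame[i] - tab$frame[j])
    if (df < 1 || df > 2) next
    d <- sqrt((tab$cx[i] - tab$cx[j])^2 + (tab$cy[i] - tab$cy[j])^2)
    if (d <= eps && tab$area[i] == tab$area[j] &&
        tab$mean_intensity[i] == tab$mean_intensity[j])
      flags[i] <- TRUE
  }
  flags
}

# small cached sprite dataset + trained closed-set model for reuse
sprite_data_small <- function() fixture("sprite_small", function()
  makeSpriteDataset(40, seed = 7))

cnn_model_small <- function() fixture("cnn_small", function() {
  ds <- sprite_data_small()
  sp <- splitDataset(ds$crops, ds$labels, seed = 7)
  list(split = sp,
       model = trainClosedSet(sp$train, sp$val,
                              CnnConfig(seed = 7, epochs = 6L)))
})
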