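# Morphometric / intensity / edge-statistic feature catalog computed per
# ROI, plus Pearson-correlation pruning and impurity-based importance
# ranking of the catalog.

.catalog_shape <- c(
  "area", "perimeter", "equivalent_diameter", "major_axis_length",
  "minor_axis_length", "eccentricity", "orientation", "solidity",
  "extent", "circularity", "convexity", "aspect_ratio", "convex_area",
  "convex_perimeter", "bbox_width", "bbox_height", "compactness",
  "radius_mean", "radius_sd", "radius_max", "radius_min")
.catalog_intensity <- c(
  "mean_intensity", "max_intensity", "min_intensity", "sd_intensity",
  "median_intensity", "mad_intensity", "intensity_range",
  "integrated_intensity", "q05_intensity", "q95_intensity",
  "skewness_intensity", "kurtosis_intensity", "contrast_vs_border",
  "cv_intensity")
.catalog_edge <- c(
  "edge_noise_gradient", "edge_noise_laplacian", "edge_gradient_max",
  "edge_laplacian_max", "mean_gradient", "max_gradient", "sd_gradient",
  "mean_laplacian_abs", "max_laplacian_abs", "sd_laplacian",
  "gradient_energy", "laplacian_energy")

#' The morphometric feature catalog
#'
#' Ordered names of the 47 per-ROI features: 21 shape descriptors computed
#' from the binary mask, 14 intensity statistics over the masked crop, and
#' 12 gradient/Laplacian edge statistics. The edge-noise features are the
#' mean absolute Sobel gradient magnitude and mean absolute Laplacian
#' response on a 2-pixel band around the mask boundary; both collapse as a
#' particle defocuses, which is what makes them informative for focus
#' classification.
#'
#' @return character vector of 47 feature names (`catalog_version`
#'   attribute: `"reconstructed-v1"`).
#' @export
fimFeatureCatalog <- function() {
  out <- c(.catalog_shape, .catalog_intensity, .catalog_edge)
  attr(out, "catalog_version") <- "reconstructed-v1"
  out
}

.sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
.sobel_y <- t(.sobel_x)
.lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)

.skewness <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) return(0)
  mean(((v - mean(v)) / s)^3)
}
.kurtosis <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) return(0)
  mean(((v - mean(v)) / s)^4) - 3
}

# shape features from a logical mask
.shape_features <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  ys <- idx[, 1]; xs <- idx[, 2]
  bw <- diff(range(xs)) + 1L; bh <- diff(range(ys)) + 1L
  cx <- mean(xs); cy <- mean(ys)
  # second central moments with the 1/12 per-pixel correction
  mu20 <- mean((xs - cx)^2) + 1 / 12
  mu02 <- mean((ys - cy)^2) + 1 / 12
  mu11 <- mean((xs - cx) * (ys - cy))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- sqrt(max(0, 1 - l2 / l1))
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  # boundary pixels: any 4-neighbour outside the mask
  padm <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  inner <- padm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] &
    padm[1:nrow(mask), 2:(ncol(mask) + 1L)] &
    padm[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)] &
    padm[2:(nrow(mask) + 1L), 1:ncol(mask)] &
    padm[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  boundary <- mask & !inner
  bidx <- which(boundary, arr.ind = TRUE)
  per <- max(1L, nrow(bidx))
  radii <- sqrt((bidx[, 2] - cx)^2 + (bidx[, 1] - cy)^2)
  if (!length(radii)) radii <- 0
  # convex hull over the corners of the boundary pixels
  px <- rep(bidx[, 2], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  py <- rep(bidx[, 1], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  hull <- grDevices::chull(px, py)
  if (length(hull) >= 3L) {
    hx <- px[hull]; hy <- py[hull]
    carea <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    cper <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  } else {
    carea <- area; cper <- per
  }
  carea <- max(carea, area)
  c(area = area, perimeter = per,
    equivalent_diameter = 2 * sqrt(area / pi),
    major_axis_length = major, minor_axis_length = minor,
    eccentricity = ecc, orientation = orient,
    solidity = area / carea, extent = area / (bw * bh),
    circularity = 4 * pi * area / per^2,
    convexity = min(cper / per, 10),
    aspect_ratio = major / minor, convex_area = carea,
    convex_perimeter = cper, bbox_width = bw, bbox_height = bh,
    compactness = per^2 / area,
    radius_mean = mean(radii), radius_sd = if (length(radii) > 1) sd(radii) else 0,
    radius_max = max(radii), radius_min = min(radii))
}

.intensity_features <- function(crop, mask) {
  v <- crop[mask]
  m <- mean(v); s <- if (length(v) > 1) sd(v) else 0
  band_out <- .dilate_cheb(mask, 2L) & !mask
  border_mean <- if (any(band_out)) mean(crop[band_out]) else m
  q <- quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
  c(mean_intensity = m, max_intensity = max(v), min_intensity = min(v),
    sd_intensity = s, median_intensity = q[2],
    mad_intensity = stats::mad(v), intensity_range = max(v) - min(v),
    integrated_intensity = sum(v), q05_intensity = q[1],
    q95_intensity = q[3], skewness_intensity = .skewness(v),
    kurtosis_intensity = .kurtosis(v),
    contrast_vs_border = m - border_mean,
    cv_intensity = if (abs(m) > 1e-12) s / m else 0)
}

.edge_features <- function(crop, mask) {
  gx <- .conv3(crop, .sobel_x); gy <- .conv3(crop, .sobel_y)
  gmag <- sqrt(gx^2 + gy^2)
  lap <- abs(.conv3(crop, .lap_k))
  padm <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  inner <- padm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] &
    padm[1:nrow(mask), 2:(ncol(mask) + 1L)] &
    padm[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)] &
    padm[2:(nrow(mask) + 1L), 1:ncol(mask)] &
    padm[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  boundary <- mask & !inner
  band <- .dilate_cheb(boundary, 2L)
  if (!any(band)) band <- mask
  gi <- gmag[mask]; li <- lap[mask]
  c(edge_noise_gradient = mean(gmag[band]),
    edge_noise_laplacian = mean(lap[band]),
    edge_gradient_max = max(gmag[band]),
    edge_laplacian_max = max(lap[band]),
    mean_gradient = mean(gi), max_gradient = max(gi),
    sd_gradient = if (length(gi) > 1) sd(gi) else 0,
    mean_laplacian_abs = mean(li), max_laplacian_abs = max(li),
    sd_laplacian = if (length(li) > 1) sd(li) else 0,
    gradient_energy = mean(gi^2), laplacian_energy = mean(li^2))
}

#' Compute the feature catalog for one ROI
#'
#' @param crop numeric image patch.
#' @param mask logical matrix of the same dimensions marking the particle.
#' @param features subset of [fimFeatureCatalog()] to compute (computing
#'   only cheap subsets skips the hull and convolution work).
#' @return named numeric vector in catalog order; all values finite.
#' @export
computeRoiFeatures <- function(crop, mask, features = fimFeatureCatalog()) {
  if (!any(mask)) stop("mask is empty")
  if (!all(dim(crop) == dim(mask)))
    stop("crop and mask dimensions differ")
  out <- numeric(0)
  if (any(features %in% .catalog_shape))
    out <- c(out, .shape_features(mask))
  if (any(features %in% .catalog_intensity))
    out <- c(out, .intensity_features(crop, mask))
  if (any(features %in% .catalog_edge))
    out <- c(out, .edge_features(crop, mask))
  out <- out[features[features %in% names(out)]]
  out[!is.finite(out)] <- 0
  out
}

# align a bbox-sized ROI mask into its padded crop
.mask_in_crop <- function(set, i) {
  roi <- roiTable(set)[i, ]
  crop <- roiCrops(set)[[i]]
  m <- matrix(FALSE, nrow(crop), ncol(crop))
  oy <- roi$y0 - roi$crop_y0   # >= 0
  ox <- roi$x0 - roi$crop_x0
  mm <- roiMasks(set)[[i]]
  m[oy + seq_len(nrow(mm)), ox + seq_len(ncol(mm))] <- mm
  m
}

#' Feature table for a ParticleSet
#'
#' @param set a [ParticleSet-class].
#' @param features features to compute (see [computeRoiFeatures()]).
#' @return data.frame with `roi_id`, `frame` and one column per feature, in
#'   catalog order.
#' @export
featureTable <- function(set, features = fimFeatureCatalog()) {
  n <- length(set)
  roi <- roiTable(set)
  vals <- matrix(0, n, length(features),
                 dimnames = list(NULL, features))
  for (i in seq_len(n))
    vals[i, ] <- computeRoiFeatures(roiCrops(set)[[i]],
                                    .mask_in_crop(set, i), features)
  cbind(data.frame(roi_id = roi$roi_id, frame = roi$frame,
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}

#' Feature table for focus-pair fixtures
#'
#' @param pairs output of [makeFocusPairs()].
#' @param features features to compute.
#' @return data.frame of features with a `label` column.
#' @export
focusPairFeatures <- function(pairs, features = fimFeatureCatalog()) {
  vals <- t(vapply(seq_len(nrow(pairs)), function(i)
    computeRoiFeatures(pairs$crop[[i]], pairs$mask[[i]], features),
    numeric(length(features))))
  colnames(vals) <- features
  out <- as.data.frame(vals)
  out$label <- pairs$label
  out
}

#' Greedy Pearson-correlation pruning of a feature table
#'
#' Walks feature pairs in catalog order; whenever a pair correlates with
#' `|r| >= rThreshold` the later-ranked member is dropped. Zero-variance
#' features are treated as perfectly self-correlated and dropped with a
#' warning. The retained set is returned in catalog order; pruning a pruned
#' table removes nothing further.
#'
#' @param table data.frame or matrix of feature columns (non-feature columns
#'   `roi_id`, `frame`, `label` are ignored).
#' @param rThreshold correlation magnitude threshold in `(0, 1]`.
#' @return character vector of retained feature names.
#' @export
pruneCorrelated <- function(table, rThreshold = 0.99) {
  stopifnot(rThreshold > 0, rThreshold <= 1)
  tab <- as.data.frame(table)
  tab <- tab[, !(names(tab) %in% c("roi_id", "frame", "label")),
             drop = FALSE]
  if (nrow(tab) < 2L) stop("need at least 2 samples")
  vars <- vapply(tab, stats::var, 1.0)
  if (any(vars < 1e-24)) {
    warning("dropping zero-variance feature(s): ",
            paste(names(tab)[vars < 1e-24], collapse = ", "))
    tab <- tab[, vars >= 1e-24, drop = FALSE]
  }
  nm <- names(tab)
  p <- length(nm)
  if (p < 2L) return(nm)
  r <- abs(cor(as.matrix(tab)))
  keep <- rep(TRUE, p)
  for (i in seq_len(p - 1L)) {
    if (!keep[i]) next
    for (j in seq((i + 1L), p)) {
      if (keep[j] && r[i, j] >= rThreshold - 1e-12) keep[j] <- FALSE
    }
  }
  nm[keep]
}

#' Rank features by ensemble impurity decrease
#'
#' Trains a random forest on the feature table and ranks features by mean
#' decrease in Gini impurity; ties break in catalog order. Deterministic
#' given `seed`.
#'
#' @param table feature data.frame (non-feature columns ignored).
#' @param labels class labels (two or more classes).
#' @param seed integer seed.
#' @param ntree forest size.
#' @return feature names ordered from most to least important.
#' @export
rankImportance <- function(table, labels, seed = 1L, ntree = 200L) {
  tab <- as.data.frame(table)
  tab <- tab[, !(names(tab) %in% c("roi_id", "frame", "label")),
             drop = FALSE]
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  fit <- .with_seed(seed,
    randomForest::randomForest(x = tab, y = labels, ntree = ntree,
                               importance = FALSE))
  imp <- fit$importance[, "MeanDecreaseGini"]
  names(tab)[order(-imp, seq_along(imp))]
}
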