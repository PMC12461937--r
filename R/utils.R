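# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Separable Gaussian blur with zero padding; sigma in pixels.
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  # rows then columns
  tmp <- matrix(0, nr + 2L * r, nc)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * pad[, (i):(i + nc - 1L), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * tmp[(i):(i + nr - 1L), , drop = FALSE]
  out
}

# 3x3 convolution with replicate padding (for gradient/Laplacian features;
# replicate padding keeps derivatives of a constant image exactly zero).
.conv3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  pad[1L, 2:(nc + 1L)] <- m[1L, ]; pad[nr + 2L, 2:(nc + 1L)] <- m[nr, ]
  pad[, 1L] <- pad[, 2L]; pad[, nc + 2L] <- pad[, nc + 1L]
  out <- matrix(0, nr, nc)
  for (dy in 0:2) for (dx in 0:2) {
    w <- k[dy + 1L, dx + 1L]
    if (w != 0)
      out <- out + w * pad[(1L + dy):(nr + dy), (1L + dx):(nc + dx)]
  }
  out
}

# Binary dilation of a logical matrix by a square structuring element of
# Chebyshev radius r.
.dilate_cheb <- function(mask, r) {
  if (r <= 0) return(mask)
  .binary_dilate_cpp(mask, as.integer(r))
}

.erode_cheb <- function(mask, r) !.dilate_cheb(!mask, r)

# Textbook DBSCAN over a Euclidean point set (n small). Returns integer
# cluster ids, 0 = noise. minPts counts the point itself.
.dbscan <- function(xy, eps, minPts) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(xy))
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbr, length, 1L) >= minPts
  labels <- integer(n)          # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr[[i]], i)
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, setdiff(nbr[[j]], j))
      }
    }
  }
  labels
}

# Connected components of an undirected adjacency matrix (logical).
.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (comp[j] != 0L) next
      comp[j] <- cur
      queue <- c(queue, which(adj[j, ] & comp == 0L))
    }
  }
  comp
}
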