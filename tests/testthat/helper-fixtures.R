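# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (brute-force loops) and independent of the implementation they check.

grid_from <- function(m, dx = 1, ...) raster_grid(as.matrix(m), cell_dx = dx, ...)

# one-layer stack on an n x n grid with seeded uniform noise
noise_stack <- function(n = 10, layers = 2, seed = 1, named = NULL) {
  ls <- withr::with_seed(seed, lapply(seq_len(layers), function(i) {
    grid_from(matrix(runif(n * n), n, n))
  }))
  names(ls) <- named %||% paste0("cov", seq_len(layers))
  covariate_stack(ls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Mann-Whitney AUC by exhaustive pairwise comparison
auc_oracle <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force Youden threshold: scan every observed score
threshold_oracle <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  best <- -Inf; best_t <- NA
  for (t in cand) {
    j <- mean(pos >= t) + mean(neg < t)
    if (j > best + 1e-15) { best <- j; best_t <- t }
  }
  best_t
}

# brute-force per-cell distance scan for the buffer mask
range_oracle <- function(occ, radius, grid) {
  v <- grid$values
  out <- matrix(0, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    cx <- grid$origin_x + (j - 0.5) * grid$cell_dx
    cy <- grid$origin_y + (i - 0.5) * grid$cell_dy
    d <- sqrt((occ$lon - cx)^2 + (occ$lat - cy)^2)
    out[i, j] <- as.numeric(min(d) <= radius)
  }
  out
}

# independent ray-casting point-in-polygon (counts boundary as inside via
# an explicit vertex/edge distance check)
pip_oracle <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  on_edge <- function(x, y) {
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1 else k + 1
      ax <- px[k]; ay <- py[k]; bx <- px[k2]; by <- py[k2]
      L2 <- (bx - ax)^2 + (by - ay)^2
      t <- if (L2 == 0) 0 else ((x - ax) * (bx - ax) + (y - ay) * (by - ay)) / L2
      t <- min(max(t, 0), 1)
      d2 <- (x - (ax + t * (bx - ax)))^2 + (y - (ay + t * (by - ay)))^2
      if (d2 < 1e-20) return(TRUE)
    }
    FALSE
  }
  if (on_edge(x, y)) return(TRUE)
  inside <- FALSE
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    if ((py[k] > y) != (py[k2] > y)) {
      xint <- px[k] + (y - py[k]) * (px[k2] - px[k]) / (py[k2] - py[k])
      if (x < xint) inside <- !inside
    }
  }
  inside
}

# lag-1 Moran's I with rook neighbours
morans_i <- function(m) {
  z <- m - mean(m)
  num <- 0; w <- 0
  nr <- nrow(m); nc <- ncol(m)
  num <- sum(z[-nr, ] * z[-1, ]) * 2 + sum(z[, -nc] * z[, -1]) * 2
  w <- 2 * (nr - 1) * nc + 2 * nr * (nc - 1)
  (num / w) / (sum(z^2) / length(z))
}

# tiny forced-binary map on a shared 1-km grid
bmap_from <- function(m) sdmelect::binarize(grid_from(m), 0.5)
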