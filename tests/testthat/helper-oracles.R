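# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / closed forms, sharing no code with the implementation.

# iterated 2x2 dilation == Minkowski sum with the {0..n} x {0..n} square
oracle_dilate <- function(grid, turns) {
  nr <- nrow(grid); nc <- ncol(grid)
  out <- matrix(FALSE, nr, nc)
  fg <- which(grid, arr.ind = TRUE)
  if (nrow(fg) == 0 || turns < 0) return(if (turns >= 0) grid else out)
  if (turns == 0) return(grid)
  for (p in seq_len(nrow(fg)))
    for (dr in 0:turns)
      for (dc in 0:turns) {
        r <- fg[p, 1] + dr; c <- fg[p, 2] + dc
        if (r <= nr && c <= nc) out[r, c] <- TRUE
      }
  out
}

# double-loop symmetric pair-counting GLCM, normalized
oracle_glcm <- function(level_img, mask, offset, levels) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(level_img); nc <- ncol(level_img)
  for (r in seq_len(nr))
    for (c in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r, c] || !mask[r2, c2]) next
      i <- level_img[r, c]; j <- level_img[r2, c2]
      if (is.na(i) || is.na(j)) next
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# naive double-sum Haralick features
oracle_glcm_features <- function(p) {
  L <- nrow(p)
  energy <- entropy <- contrast <- homog <- idm <- 0
  mu_i <- mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + i * p[i, j]
    mu_j <- mu_j + j * p[i, j]
  }
  var_i <- var_j <- covar <- 0
  for (i in 1:L) for (j in 1:L) {
    v <- p[i, j]
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log(v)
    contrast <- contrast + (i - j)^2 * v
    homog <- homog + v / (1 + abs(i - j))
    idm <- idm + v / (1 + (i - j)^2)
    var_i <- var_i + (i - mu_i)^2 * v
    var_j <- var_j + (j - mu_j)^2 * v
    covar <- covar + (i - mu_i) * (j - mu_j) * v
  }
  corr <- if (var_i > 0 && var_j > 0) covar / sqrt(var_i * var_j) else 0
  c(energy = energy, entropy = entropy, contrast = contrast,
    correlation = corr, homogeneity = homog, IDM = idm)
}

# explicit Relief pass: range-normalise, then for every sample take the k
# nearest hits and per-class misses by Manhattan distance (ties by index)
oracle_relieff <- function(x, y, k) {
  x <- as.matrix(x); n <- nrow(x); y <- as.character(y)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  xn <- x
  for (f in seq_len(ncol(x)))
    xn[, f] <- if (hi[f] > lo[f]) (x[, f] - lo[f]) / (hi[f] - lo[f]) else 0
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    for (cl in unique(y)) {
      cand <- setdiff(which(y == cl), i)
      kk <- min(k, length(cand))
      if (kk < 1) next
      d <- sapply(cand, function(j) sum(abs(xn[i, ] - xn[j, ])))
      nb <- cand[order(d, cand)][1:kk]
      md <- colMeans(abs(xn[nb, , drop = FALSE] -
                           matrix(xn[i, ], kk, ncol(x), byrow = TRUE)))
      if (cl == y[i]) w <- w - md / n
      else {
        p_cl <- mean(y == cl); p_i <- mean(y == y[i])
        w <- w + p_cl / (1 - p_i) * md / n
      }
    }
  }
  stats::setNames(w, colnames(x))
}

# random star-ish test mask
random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
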