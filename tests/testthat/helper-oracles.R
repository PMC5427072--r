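# Independent oracles used to cross-check the package implementations.
# Each one is written from first principles and shares no code with R/.

# Kendall's W by explicit rank counting: the rank of x_i within its series is
# 1 + #{j: x_j < x_i} + (#{j != i: x_j == x_i}) / 2  (mid-ranks).
kcc_bruteforce <- function(mat) {
  K <- nrow(mat)
  n <- ncol(mat)
  ranks <- matrix(0, K, n)
  for (k in seq_len(K)) {
    for (i in seq_len(n)) {
      ranks[k, i] <- 1 + sum(mat[k, ] < mat[k, i]) +
        (sum(mat[k, ] == mat[k, i]) - 1) / 2
    }
  }
  R_i <- colSums(ranks)
  sum((R_i - mean(R_i))^2) * 12 / (K^2 * (n^3 - n))
}

# breadth-first flood fill over a 3-D binary array
floodfill_labels <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0L, d)
  sizes <- integer(0)
  nxt <- 0L
  todo <- which(bin)
  for (v0 in todo) {
    if (lab[v0] != 0L) next
    nxt <- nxt + 1L
    queue <- v0
    lab[v0] <- nxt
    sz <- 0L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      sz <- sz + 1L
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        p <- ijk + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        u <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (bin[u] && lab[u] == 0L) {
          lab[u] <- nxt
          queue <- c(queue, u)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  list(labels = lab, sizes = sizes)
}

# fALFF of a single time series straight from the definition: amplitude =
# sqrt of the power spectrum, half-open bins, DC excluded
falff_oracle <- function(x, tr_s, num = c(0.01, 0.08), den = c(0.01, 0.25)) {
  n <- length(x)
  x <- x - mean(x)
  a <- abs(fft(x))
  j <- seq_len(floor(n / 2))           # positive-frequency bins (0-based j)
  f <- j / (n * tr_s)
  sum(a[j + 1][f >= num[1] & f < num[2]]) /
    sum(a[j + 1][f >= den[1] & f < den[2]])
}

# partial correlation by double residualization
partial_cor_resid <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Direct, self-contained Monte-Carlo simulation of the minimum cluster extent
# for an unsmoothed null field: white noise in the mask, within-mask
# standardization, two-tailed threshold, flood-fill clustering.
alphasim_oracle <- function(mask, voxel_alpha, corrected_alpha, n_iter, seed,
                            connectivity = 26L) {
  set.seed(seed)
  vox <- which(mask)
  zthr <- qnorm(1 - voxel_alpha / 2)
  mx <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    x <- rnorm(length(vox))
    z <- (x - mean(x)) / sd(x)
    bin <- array(FALSE, dim(mask))
    bin[vox] <- abs(z) > zthr
    mx[it] <- if (any(bin)) max(floodfill_labels(bin, connectivity)$sizes) else 0L
  }
  for (k in seq_len(max(mx) + 1L)) {
    if (mean(mx >= k) <= corrected_alpha) return(k)
  }
  NA_integer_
}

# small white-noise volume_series for tests
noise_series <- function(dims = c(8, 8, 8), nt = 64, tr_s = 2, seed = 1,
                         mask = NULL) {
  set.seed(seed)
  volume_series(array(rnorm(prod(dims) * nt), c(dims, nt)),
                mask %||% array(TRUE, dims), tr_s = tr_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-voxel sinusoid volume: every in-mask voxel carries the same waveform
sinusoid_series <- function(freq_hz, dims = c(6, 6, 6), nt = 240, tr_s = 2,
                            amp = 1) {
  t <- (seq_len(nt) - 1) * tr_s
  w <- amp * sin(2 * pi * freq_hz * t)
  arr <- array(rep(w, each = prod(dims)), c(dims, nt))
  volume_series(arr, array(TRUE, dims), tr_s = tr_s)
}

# voxels of reg whose full 27-neighbourhood lies inside reg
erode27 <- function(reg) {
  d <- dim(reg)
  out <- array(FALSE, d)
  idx <- which(reg)
  for (v in idx) {
    p <- arrayInd(v, d)
    if (any(p == 1) || any(p == d)) next
    nb <- as.matrix(expand.grid(p[1] + (-1:1), p[2] + (-1:1), p[3] + (-1:1)))
    out[v] <- all(reg[nb])
  }
  out
}

dice_coef <- function(a, b) {
  a <- which(a)
  b <- which(b)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
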