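# Independent reference implementations used as oracles. These are written
# as literal double loops over the definitions and share no code with the
# package internals they check.

# Non-local-means reference: for every pixel p, weights over the search
# window with similarity-patch averaged squared distances (offsets truncated
# so both p+o and q+o stay in bounds); weights shared across channels.
oracle_nlm <- function(img, patch_r, search_r, h) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- array(0, dim = dim(img))
  for (ph in seq_len(H)) for (pw in seq_len(W)) {
    wsum <- 0; acc <- numeric(C)
    for (qh in max(1, ph - search_r):min(H, ph + search_r)) {
      for (qw in max(1, pw - search_r):min(W, pw + search_r)) {
        d2 <- 0; no <- 0
        for (oi in -patch_r:patch_r) for (oj in -patch_r:patch_r) {
          ah <- ph + oi; aw <- pw + oj; bh <- qh + oi; bw <- qw + oj
          if (ah < 1 || ah > H || aw < 1 || aw > W) next
          if (bh < 1 || bh > H || bw < 1 || bw > W) next
          d2 <- d2 + sum((img[ah, aw, ] - img[bh, bw, ])^2)
          no <- no + 1
        }
        if (no > 0) d2 <- d2 / no
        w <- exp(-d2 / h^2)
        wsum <- wsum + w
        acc <- acc + w * img[qh, qw, ]
      }
    }
    out[ph, pw, ] <- acc / wsum
  }
  out
}

# Otsu reference: exhaustive scan of all 255 split points, minimising the
# within-class variance; smallest minimiser on ties.
oracle_otsu <- function(counts) {
  levels <- 0:255
  n <- sum(counts)
  best_t <- NA_integer_; best_w <- Inf
  for (t in 0:254) {
    lo <- counts[1:(t + 1)]; hi <- counts[(t + 2):256]
    w0 <- sum(lo) / n; w1 <- sum(hi) / n
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(lo * levels[1:(t + 1)]) / sum(lo)
    m1 <- sum(hi * levels[(t + 2):256]) / sum(hi)
    v0 <- sum(lo * (levels[1:(t + 1)] - m0)^2) / sum(lo)
    v1 <- sum(hi * (levels[(t + 2):256] - m1)^2) / sum(hi)
    wcv <- w0 * v0 + w1 * v1
    if (wcv < best_w - 1e-12) { best_w <- wcv; best_t <- t }
  }
  best_t
}

# Probability-map reference: per-pixel max over all patches containing it.
oracle_map <- function(origins, p, preds, H, W) {
  vals <- matrix(0, H, W); cov <- matrix(0L, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    best <- 0; k_in <- 0L
    for (k in seq_len(nrow(origins))) {
      r <- origins[k, 1]; c <- origins[k, 2]
      if (x - 1 >= r && x - 1 < r + p && y - 1 >= c && y - 1 < c + p) {
        k_in <- k_in + 1L
        if (preds[k] > best) best <- preds[k]
      }
    }
    vals[x, y] <- if (k_in > 0) best else 0
    cov[x, y] <- k_in
  }
  list(values = vals, coverage = cov)
}

# Pairwise AUC reference: ties counted 1/2.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Direct-summation 'same' 3x3 convolution reference.
oracle_conv2d <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(W)[4]
  out <- array(0, dim = c(H, Wd, Cout))
  for (co in seq_len(Cout)) for (hh in seq_len(H)) for (ww in seq_len(Wd)) {
    s <- b[co]
    for (ci in seq_len(Cin)) for (i in 1:3) for (j in 1:3) {
      hi <- hh + i - 2; wi <- ww + j - 2
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd)
        s <- s + x[hi, wi, ci] * W[i, j, ci, co]
    }
    out[hh, ww, co] <- s
  }
  out
}

# Inference-mode batch norm reference (per channel over the 3rd dim).
oracle_bn <- function(x, bn) {
  out <- x
  for (c in seq_len(dim(x)[3]))
    out[, , c] <- (x[, , c] - bn$running_mean[c]) /
      sqrt(bn$running_var[c] + 1e-5) * bn$gamma[c] + bn$beta[c]
  out
}

# Small random test images
rand_img <- function(H, W, C = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(H * W * C), dim = c(H, W, C))
}

# Synthetic separable patch set: healthy = noisy background, diseased =
# background + intensity shift. Returns [p, p, 3, 2n] and labels.
make_patch_set <- function(n_per_class, p = 32L, shift = 0.3, sd = 0.05,
                           seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(0, dim = c(p, p, 3, n))
  labels <- rep(c(0L, 1L), each = n_per_class)
  base <- c(0.8, 0.62, 0.52)
  for (i in seq_len(n)) {
    img <- array(rep(base, each = p * p), dim = c(p, p, 3)) +
      array(stats::rnorm(p * p * 3, 0, sd), dim = c(p, p, 3))
    if (labels[i] == 1L) img <- img + shift
    x[, , , i] <- pmin(pmax(img, 0), 1)
  }
  ord <- sample.int(n)
  list(x = x[, , , ord, drop = FALSE], labels = labels[ord])
}

# Relative gradient agreement: |num - ana| within tol relative to magnitude,
# with an absolute floor for near-zero gradients (finite-difference noise).
grad_agrees <- function(num, ana, tol = 1e-4, floor = 1e-7) {
  abs(num - ana) <= pmax(tol * pmax(abs(num), abs(ana)), floor)
}
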