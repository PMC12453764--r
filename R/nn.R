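# Neural-network primitives. Feature maps travel as (H*W*N) x C matrices
# (channel-last layout, row index h + H*(w + W*n)) so that convolution is a
# single im2col + BLAS gemm with the bias folded in, and batch normalisation
# is plain column arithmetic -- no array transposition anywhere on the hot
# path. Kernels are stored as [kh, kw, Cin, Cout] arrays at the API surface
# and flattened to (kh*kw*Cin) x Cout matrices internally.

nnLeakySlope <- 0.01

heUniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# [p, p, C, N] array (public patch layout) -> channel-last matrix + dims
mapEnter <- function(x) {
  d <- dim(x)
  list(m = matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3]),
       H = d[1], W = d[2], N = d[4])
}

# ---- 2-D convolution (channel-last, 'same' semantics via pad) ------------

conv2dForward <- function(xm, H, W, N, W_arr, b, pad = 1L, stride = 1L,
                          keep = TRUE) {
  kd <- dim(W_arr)
  cols <- cpp_im2col_nc(xm, H, W, N, kd[1], kd[2], pad, stride, TRUE)
  Wb <- rbind(matrix(W_arr, nrow = kd[1] * kd[2] * kd[3]), b)
  out <- cols %*% Wb
  Ho <- (H + 2L * pad - kd[1]) %/% stride + 1L
  Wo <- (W + 2L * pad - kd[2]) %/% stride + 1L
  list(out = out, H = Ho, W = Wo, N = N,
       cache = if (keep)
         list(cols = cols, H = H, W = W, N = N, pad = pad,
              stride = stride, kd = kd))
}

conv2dBackward <- function(dout, W_arr, cache, need_dx = TRUE) {
  kd <- cache$kd
  dWb <- crossprod(cache$cols, dout)
  nr <- kd[1] * kd[2] * kd[3]
  dW <- array(dWb[seq_len(nr), , drop = FALSE], dim = kd)
  db <- dWb[nr + 1L, ]
  dx <- NULL
  if (need_dx) {
    Wm <- matrix(W_arr, nrow = nr)
    dcols <- tcrossprod(dout, Wm)
    dx <- cpp_col2im_nc(dcols, cache$H, cache$W, cache$N, kd[3],
                        kd[1], kd[2], cache$pad, cache$stride)
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalisation (columns = channels) ----------------------------
# Training uses batch statistics (population variance) and updates running
# moments with momentum 0.1; inference uses the running moments.

bnEps <- 1e-5
bnMomentum <- 0.1

bnForwardMat <- function(m, bn, training, momentum = bnMomentum) {
  if (training) {
    mom <- cpp_col_moments(m)
    mu <- mom$mean
    v <- mom$meansq - mu^2
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  ivar <- 1 / sqrt(v + bnEps)
  xhat <- cpp_affine_cols(m, ivar, -mu * ivar)
  out <- cpp_affine_cols(xhat, bn$gamma, bn$beta)
  list(out = out, bn = bn, cache = list(xhat = xhat, ivar = ivar, training = training))
}

bnBackwardMat <- function(dout, bn, cache) {
  bw <- cpp_bn_bwd(dout, cache$xhat, bn$gamma, cache$ivar, cache$training)
  list(dm = bw$dm, dgamma = bw$dgamma, dbeta = bw$dbeta)
}

bnInit <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       running_mean = rep(0, C), running_var = rep(1, C))
}

# ---- pooling -------------------------------------------------------------

maxpoolForward <- function(xm, H, W, N) {
  mp <- cpp_maxpool_nc(xm, H, W, N)
  list(out = mp$out, idx = mp$idx, H = mp$dim[1], W = mp$dim[2], N = N,
       in_rows = nrow(xm))
}

maxpoolBackward <- function(dout, pool) {
  cpp_maxpool_bwd_nc(dout, pool$idx, pool$in_rows)
}

# global average pooling: (H*W*N) x C -> C x N
gapForward <- function(m, H, W, N) {
  t(colMeans(array(m, dim = c(H * W, N, ncol(m)))))
}

gapBackward <- function(dgap, H, W, N) {
  # dgap: C x N -> (H*W*N) x C, each spatial cell gets dgap / (H*W)
  t(dgap)[rep(seq_len(N), each = H * W), , drop = FALSE] / (H * W)
}

# ---- activations ---------------------------------------------------------

reluForward <- function(x) {
  if (!is.matrix(x)) return(cpp_relu(matrix(x, nrow = length(x))))
  cpp_relu(x)
}
reluBackward <- function(dout, mask) cpp_mask_mul(dout, mask, 0)
leakyForward <- function(x, slope = nnLeakySlope) {
  if (!is.matrix(x)) return(cpp_leaky(matrix(x, nrow = length(x)), slope))
  cpp_leaky(x, slope)
}
leakyBackward <- function(dout, mask, slope = nnLeakySlope)
  cpp_mask_mul(dout, mask, slope)

# ---- softmax cross-entropy ----------------------------------------------
# logits: C x N; labels: integer 0..C-1. Returns mean loss, probabilities
# and the gradient of the mean loss w.r.t. the logits.

softmaxProbs <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

crossEntropy <- function(logits, labels) {
  probs <- softmaxProbs(logits)
  n <- ncol(logits)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}

# ---- Adam ----------------------------------------------------------------
# params/grads are nested lists of numeric arrays with identical shape.
# Batch-norm running moments receive zero gradients and therefore never move.

adamInit <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      upd <- Map(walk, p, g, m, v)
      list(p = lapply(upd, `[[`, "p"), m = lapply(upd, `[[`, "m"),
           v = lapply(upd, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  upd <- walk(params, grads, state$m, state$v)
  list(params = upd$p, state = list(m = upd$m, v = upd$v, t = state$t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
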