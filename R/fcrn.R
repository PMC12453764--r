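#' FCRN architecture specification
#'
#' The patch-level fully convolutional residual network: a 3x3 convolution
#' (64 filters, stride 1, leaky-ReLU), a residual block at the same width, a
#' 2x2 stride-2 max pool, a second residual block, a 3x3 convolution with 128
#' filters, global average pooling, and a 1x1 convolutional head with one
#' filter per class (C = 2) followed by softmax. Each residual block applies
#' ReLU(BN(W2 . ReLU(BN(W1 . x))) + x) with 'same' padding. There are no
#' dense layers, so the forward pass accepts any input of at least
#' \code{input_size} pixels without rebuilding.
#'
#' @param input_size expected patch side during training; default 32.
#' @param width filters of the stem convolution and residual blocks
#'   (default 64).
#' @param width2 filters of the post-block convolution (default 128).
#' @param n_classes output classes; default 2 (healthy, diseased).
#' @param leaky_slope negative slope of the leaky-ReLU used outside the
#'   residual blocks; default 0.01.
#' @return list of class \code{fcrnSpec}; serialises round-trip stably.
#' @export
fcrnSpec <- function(input_size = 32L, width = 64L, width2 = 128L,
                     n_classes = 2L, leaky_slope = 0.01) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  structure(list(input_size = as.integer(input_size), width = as.integer(width),
                 width2 = as.integer(width2), n_classes = as.integer(n_classes),
                 leaky_slope = leaky_slope),
            class = "fcrnSpec")
}

#' Initialise FCRN parameters
#'
#' He-uniform kernel initialisation, zero biases, unit batch-norm scale. The
#' current RNG state controls the draw; seed it for reproducibility.
#'
#' @param spec a \code{\link{fcrnSpec}}.
#' @return nested parameter list (kernels, biases, batch-norm states).
#' @export
initFcrn <- function(spec = fcrnSpec()) {
  w <- spec$width; w2 <- spec$width2
  blk <- function(cin) list(
    Wa = heUniform(c(3, 3, cin, cin), 9 * cin), ba = rep(0, cin), bna = bnInit(cin),
    Wb = heUniform(c(3, 3, cin, cin), 9 * cin), bb = rep(0, cin), bnb = bnInit(cin))
  list(conv1 = list(W = heUniform(c(3, 3, 3, w), 27), b = rep(0, w)),
       block1 = blk(w),
       block2 = blk(w),
       conv2 = list(W = heUniform(c(3, 3, w, w2), 9 * w), b = rep(0, w2)),
       head = list(W = heUniform(c(w2, spec$n_classes), w2),
                   b = rep(0, spec$n_classes)))
}

# Residual block forward: ReLU(BN(Wb . ReLU(BN(Wa . x))) + x).
# xm: channel-last matrix; H, W, N spatial/batch dims.
residualBlockForward <- function(xm, H, W, N, blk, training = FALSE,
                                 keep = training, momentum = bnMomentum) {
  if (dim(blk$Wa)[3] != ncol(xm))
    stop(sprintf("channel mismatch: block expects %d, input has %d",
                 dim(blk$Wa)[3], ncol(xm)))
  ca <- conv2dForward(xm, H, W, N, blk$Wa, blk$ba, keep = keep)
  fa <- bnForwardMat(ca$out, blk$bna, training, momentum)
  ra <- reluForward(fa$out)
  cb <- conv2dForward(ra$out, H, W, N, blk$Wb, blk$bb, keep = keep)
  fb <- bnForwardMat(cb$out, blk$bnb, training, momentum)
  z <- fb$out + xm
  rb <- reluForward(z)
  list(out = rb$out,
       blk = { b <- blk; b$bna <- fa$bn; b$bnb <- fb$bn; b },
       cache = list(ca = ca, fa = fa, ra = ra, cb = cb, fb = fb,
                    mask_out = rb$mask))
}

residualBlockBackward <- function(dout, blk, cache) {
  dz <- reluBackward(dout, cache$mask_out)
  bnb <- bnBackwardMat(dz, blk$bnb, cache$fb$cache)
  cbb <- conv2dBackward(bnb$dm, blk$Wb, cache$cb$cache)
  dra <- reluBackward(cbb$dx, cache$ra$mask)
  bna <- bnBackwardMat(dra, blk$bna, cache$fa$cache)
  cab <- conv2dBackward(bna$dm, blk$Wa, cache$ca$cache)
  grads <- list(Wa = cab$dW, ba = cab$db,
                bna = list(gamma = bna$dgamma, beta = bna$dbeta,
                           running_mean = 0 * blk$bna$running_mean,
                           running_var = 0 * blk$bna$running_var),
                Wb = cbb$dW, bb = cbb$db,
                bnb = list(gamma = bnb$dgamma, beta = bnb$dbeta,
                           running_mean = 0 * blk$bnb$running_mean,
                           running_var = 0 * blk$bnb$running_var))
  list(dx = cab$dx + dz, grads = grads)
}

#' Residual block (inference)
#'
#' Exposes the FCRN residual block as a standalone operation: returns
#' ReLU(BN(W2 . ReLU(BN(W1 . x))) + x) with the block's stored batch-norm
#' mode ('same' padding, spatial dims preserved).
#'
#' @param x feature map array [H, W, C, N] (a single [H, W, C] map is
#'   promoted to N = 1).
#' @param block block parameter list (elements Wa, ba, bna, Wb, bb, bnb, as
#'   built by \code{\link{initFcrn}}).
#' @param training use batch statistics (TRUE) or running moments (FALSE).
#' @return feature map with the same spatial dimensions as x.
#' @export
residualBlock <- function(x, block, training = FALSE) {
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  e <- mapEnter(x)
  rb <- residualBlockForward(e$m, e$H, e$W, e$N, block, training)
  aperm(array(rb$out, dim = c(e$H, e$W, e$N, ncol(rb$out))), c(1, 2, 4, 3))
}

# Full forward pass. x: [H, W, 3, N]. Returns logits (C x N), probabilities,
# updated params (running BN moments) and caches when training.
fcrnForwardFull <- function(x, params, spec, training = FALSE,
                            keep_cache = training, momentum = bnMomentum) {
  slope <- spec$leaky_slope
  e <- mapEnter(x)
  H <- e$H; W <- e$W; N <- e$N
  c1 <- conv2dForward(e$m, H, W, N, params$conv1$W, params$conv1$b,
                      keep = keep_cache)
  l1 <- leakyForward(c1$out, slope)
  b1 <- residualBlockForward(l1$out, H, W, N, params$block1, training,
                             keep = keep_cache, momentum = momentum)
  mp <- maxpoolForward(b1$out, H, W, N)
  Hp <- mp$H; Wp <- mp$W
  b2 <- residualBlockForward(mp$out, Hp, Wp, N, params$block2, training,
                             keep = keep_cache, momentum = momentum)
  c2 <- conv2dForward(b2$out, Hp, Wp, N, params$conv2$W, params$conv2$b,
                      keep = keep_cache)
  l2 <- leakyForward(c2$out, slope)
  gap <- gapForward(l2$out, Hp, Wp, N)             # width2 x N
  logits <- crossprod(params$head$W, gap) + params$head$b
  params$block1 <- b1$blk
  params$block2 <- b2$blk
  list(logits = logits, probs = softmaxProbs(logits), params = params,
       cache = if (keep_cache)
         list(c1 = c1, l1 = l1, b1 = b1, mp = mp, b2 = b2, c2 = c2, l2 = l2,
              gap = gap, H = H, W = W, Hp = Hp, Wp = Wp, N = N))
}

fcrnBackwardFull <- function(dlogits, params, spec, cache) {
  slope <- spec$leaky_slope
  dhead_W <- cache$gap %*% t(dlogits)
  dhead_b <- rowSums(dlogits)
  dgap <- params$head$W %*% dlogits                # width2 x N
  dl2 <- gapBackward(dgap, cache$Hp, cache$Wp, cache$N)
  dc2 <- leakyBackward(dl2, cache$l2$mask, slope)
  g2 <- conv2dBackward(dc2, params$conv2$W, cache$c2$cache)
  rb2 <- residualBlockBackward(g2$dx, params$block2, cache$b2$cache)
  dpool <- maxpoolBackward(rb2$dx, cache$mp)
  rb1 <- residualBlockBackward(dpool, params$block1, cache$b1$cache)
  dc1 <- leakyBackward(rb1$dx, cache$l1$mask, slope)
  g1 <- conv2dBackward(dc1, params$conv1$W, cache$c1$cache, need_dx = FALSE)
  list(conv1 = list(W = g1$dW, b = g1$db),
       block1 = rb1$grads,
       block2 = rb2$grads,
       conv2 = list(W = g2$dW, b = g2$db),
       head = list(W = dhead_W, b = dhead_b))
}

#' FCRN forward pass
#'
#' Runs a patch (or batch of patches) through the network in inference mode
#' (running batch-norm moments; deterministic). Any input of at least 32x32
#' pixels is accepted: global average pooling collapses the spatial grid to
#' 1x1 before the convolutional head.
#'
#' @param patch numeric array [p, p, 3] or batch [p, p, 3, N] in \code{[0,1]}.
#' @param model a \linkS4class{FcrnModel}, or a bare parameter list (then
#'   \code{spec} is required).
#' @param spec optional \code{\link{fcrnSpec}} when \code{model} is a bare
#'   parameter list.
#' @return list with \code{logits} (C x N) and \code{probs} (C x N, columns
#'   sum to 1); row 2 is the diseased-class probability.
#' @export
fcrnForward <- function(patch, model, spec = NULL) {
  if (is(model, "FcrnModel")) { params <- model@params; spec <- model@spec }
  else params <- model
  if (is.null(spec)) stop("spec required with a bare parameter list")
  if (length(dim(patch)) == 3L) patch <- array(patch, dim = c(dim(patch), 1L))
  d <- dim(patch)
  if (d[3] != 3L || d[1] < spec$input_size || d[2] < spec$input_size)
    stop(sprintf("patch must be at least %dx%dx3, got %dx%dx%d",
                 spec$input_size, spec$input_size, d[1], d[2], d[3]))
  N <- d[4]
  chunks <- split(seq_len(N), ceiling(seq_len(N) / 64))
  logits <- matrix(0, spec$n_classes, N)
  for (s in chunks) {
    fw <- fcrnForwardFull(patch[, , , s, drop = FALSE], params, spec,
                          training = FALSE)
    logits[, s] <- fw$logits
  }
  list(logits = logits, probs = softmaxProbs(logits))
}

# Mean cross-entropy of a batch under given parameters (training-mode BN).
# Used by tests for finite-difference gradient checks.
fcrnLoss <- function(x, labels, params, spec, training = TRUE) {
  fw <- fcrnForwardFull(x, params, spec, training)
  crossEntropy(fw$logits, labels)$loss
}

#' Train the patch-level FCRN
#'
#' Minimises mean cross-entropy with Adam (learning rate 0.001 by default,
#' mini-batches of 32). Records per-epoch training and validation loss and
#' accuracy, keeps the best-validation checkpoint, and stops early when
#' validation loss has not improved for \code{patience} epochs. With
#' \code{epochs = 0} the returned parameters equal the seeded initialisation.
#'
#' @param x patch batch array [p, p, 3, N].
#' @param labels integer 0/1 vector (0 healthy, 1 diseased), length N.
#' @param spec a \code{\link{fcrnSpec}}.
#' @param epochs training epochs; default 20.
#' @param lr Adam learning rate; default 0.001.
#' @param batch_size mini-batch size; default 32.
#' @param val_frac fraction held out for validation when \code{x_val} is
#'   NULL; default 0.2 (stratified).
#' @param x_val,labels_val optional explicit validation set.
#' @param patience early-stopping patience in epochs; default 10.
#' @param seed RNG seed controlling initialisation and shuffling.
#' @param verbose print per-epoch progress.
#' @return a \linkS4class{FcrnModel} holding the best-validation parameters
#'   and the training history.
#' @export
trainFcrn <- function(x, labels, spec = fcrnSpec(), epochs = 20L, lr = 1e-3,
                      batch_size = 32L, val_frac = 0.2, x_val = NULL,
                      labels_val = NULL, patience = 10L, seed = 1L,
                      verbose = FALSE) {
  labels <- as.integer(labels)
  n <- dim(x)[4]
  if (n < 1L || length(labels) != n) stop("labels must match the patch count")
  if (length(unique(labels)) < 2L)
    stop("training requires at least one patch per class")
  set.seed(seed)
  params <- initFcrn(spec)
  if (is.null(x_val)) {
    sp <- stratifiedSplit(labels, c(1 - val_frac, val_frac, 0), seed = seed + 1L)
    tr <- sp$train; va <- sp$val
    x_val <- x[, , , va, drop = FALSE]; labels_val <- labels[va]
    x <- x[, , , tr, drop = FALSE]; labels <- labels[tr]
    n <- length(tr)
  }
  opt <- adamInit(params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  evalSet <- function(p, xs, ys) {
    nn <- dim(xs)[4]; tot <- 0; hit <- 0
    for (s in split(seq_len(nn), ceiling(seq_len(nn) / 64))) {
      fw <- fcrnForwardFull(xs[, , , s, drop = FALSE], p, spec, training = FALSE)
      ce <- crossEntropy(fw$logits, ys[s])
      tot <- tot + ce$loss * length(s)
      hit <- hit + sum(max.col(t(fw$logits)) - 1L == ys[s])
    }
    c(loss = tot / nn, acc = hit / nn)
  }
  best <- list(params = params, val_loss = Inf)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; hit <- 0
    for (s in split(ord, ceiling(seq_along(ord) / batch_size))) {
      xb <- x[, , , s, drop = FALSE]
      fw <- fcrnForwardFull(xb, params, spec, training = TRUE)
      params <- fw$params
      ce <- crossEntropy(fw$logits, labels[s])
      tot <- tot + ce$loss * length(s)
      hit <- hit + sum(max.col(t(fw$logits)) - 1L == labels[s])
      grads <- fcrnBackwardFull(ce$dlogits, params, spec, fw$cache)
      up <- adamStep(params, grads, opt, lr = lr)
      # keep freshly-updated BN running moments, Adam leaves them unmoved
      params <- up$params
      opt <- up$state
    }
    vm <- evalSet(params, x_val, labels_val)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / n,
                                   train_acc = hit / n, val_loss = vm["loss"],
                                   val_acc = vm["acc"]))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      ep, tot / n, hit / n, vm["loss"], vm["acc"]))
    if (vm["loss"] < best$val_loss - 1e-9) {
      best <- list(params = params, val_loss = vm["loss"])
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  rownames(hist) <- NULL
  final <- if (epochs > 0L && is.finite(best$val_loss)) best$params else params
  if (epochs > 0L) final <- fcrnRefreshBn(final, x, spec)
  methods::new("FcrnModel", spec = unclass(spec), params = final,
               history = hist)
}

# Re-estimate batch-norm running moments under the final parameters: the
# training-time exponential average lags the weights it was collected under,
# which mis-calibrates inference after short runs on small sets. One pass
# over the training patches with cumulative-mean updates replaces the EMA
# with the population moments of the final network.
fcrnRefreshBn <- function(params, x, spec, chunk = 64L) {
  nn <- dim(x)[4]
  k <- 0L
  for (s in split(seq_len(nn), ceiling(seq_len(nn) / chunk))) {
    k <- k + 1L
    fw <- fcrnForwardFull(x[, , , s, drop = FALSE], params, spec,
                          training = TRUE, keep_cache = FALSE,
                          momentum = 1 / k)
    params <- fw$params
  }
  params
}
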