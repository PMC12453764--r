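#' Fusion network specification
#'
#' The multimodal classifier that combines reduced high-risk map regions
#' with the encoded clinical vector. The default 1-D convolutional branch
#' applies 16 then 32 kernels of size 3 (stride 1, 'same' padding, batch
#' norm, ReLU) along the length-32 region profiles, treating the N region
#' rows as independent sequences; global average pooling over rows and
#' positions yields a 32-vector, concatenated with the clinical vector (fused
#' length 32 + d). A 2-D branch variant (3x3 convolutions with 64 then 128
#' filters over the stacked regions) is selectable. The dense head has 128
#' and 64 leaky-ReLU neurons with dropout 0.1, then a 2-class softmax.
#'
#' @param d_clinical dimension d of the encoded clinical vector (0 for an
#'   image-only model).
#' @param branch "conv1d" (default) or "conv2d".
#' @param n_regions tensor row count N; default 8.
#' @param region_len region profile length; default 32.
#' @param dropout dropout rate on the dense layers; default 0.1.
#' @param leaky_slope leaky-ReLU negative slope; default 0.01.
#' @param n_classes output classes; default 2.
#' @return list of class \code{fusionSpec}.
#' @export
fusionSpec <- function(d_clinical, branch = c("conv1d", "conv2d"),
                       n_regions = 8L, region_len = 32L, dropout = 0.1,
                       leaky_slope = 0.01, n_classes = 2L) {
  branch <- match.arg(branch)
  if (d_clinical < 0L) stop("d_clinical must be >= 0")
  structure(list(dClinical = as.integer(d_clinical), branch = branch,
                 nRegions = as.integer(n_regions),
                 regionLen = as.integer(region_len), dropout = dropout,
                 leaky_slope = leaky_slope, n_classes = as.integer(n_classes)),
            class = "fusionSpec")
}

#' Initialise fusion-network parameters
#'
#' @param spec a \code{\link{fusionSpec}}. RNG-state controlled; seed for
#'   reproducibility.
#' @return nested parameter list.
#' @export
initFusion <- function(spec) {
  gapWidth <- if (spec$branch == "conv1d") 32L else 128L
  dIn <- gapWidth + spec$dClinical
  br <- if (spec$branch == "conv1d") {
    list(W1 = heUniform(c(3, 1, 16), 3), b1 = rep(0, 16), bn1 = bnInit(16),
         W2 = heUniform(c(3, 16, 32), 48), b2 = rep(0, 32), bn2 = bnInit(32))
  } else {
    list(W1 = heUniform(c(3, 3, 1, 64), 9), b1 = rep(0, 64), bn1 = bnInit(64),
         W2 = heUniform(c(3, 3, 64, 128), 9 * 64), b2 = rep(0, 128),
         bn2 = bnInit(128))
  }
  list(branch = br,
       dense1 = list(W = heUniform(c(dIn, 128), dIn), b = rep(0, 128)),
       dense2 = list(W = heUniform(c(128, 64), 128), b = rep(0, 64)),
       out = list(W = heUniform(c(64, spec$n_classes), 64),
                  b = rep(0, spec$n_classes)))
}

# ---- 1-D convolution over region profiles -------------------------------
# x: [L, Cin, M] (M sequences); kernels [3, Cin, Cout]; 'same' padding.

conv1dForward <- function(x, W, b) {
  d <- dim(x); L <- d[1]; Cin <- d[2]; M <- d[3]
  Cout <- dim(W)[3]
  xp <- array(0, dim = c(L + 2, Cin, M))
  xp[2:(L + 1), , ] <- x
  cols <- matrix(0, 3 * Cin, L * M)
  for (t in 1:3)
    cols[(t - 1) * Cin + seq_len(Cin), ] <-
      matrix(aperm(xp[t:(t + L - 1), , , drop = FALSE], c(2, 1, 3)), Cin, L * M)
  Wm <- matrix(aperm(W, c(2, 1, 3)), 3 * Cin, Cout)
  out_mat <- sweep(crossprod(cols, Wm), 2L, b, "+")   # (L*M) x Cout
  out <- aperm(array(out_mat, dim = c(L, M, Cout)), c(1, 3, 2))
  list(out = out, cache = list(cols = cols, xdim = d))
}

conv1dBackward <- function(dout, W, cache) {
  d <- cache$xdim; L <- d[1]; Cin <- d[2]; M <- d[3]
  Cout <- dim(W)[3]
  dmat <- matrix(aperm(dout, c(1, 3, 2)), L * M, Cout)
  dWm <- cache$cols %*% dmat
  dW <- aperm(array(dWm, dim = c(Cin, 3, Cout)), c(2, 1, 3))
  db <- colSums(dmat)
  Wm <- matrix(aperm(W, c(2, 1, 3)), 3 * Cin, Cout)
  dcols <- tcrossprod(Wm, dmat)                       # (3*Cin) x (L*M)
  dxp <- array(0, dim = c(L + 2, Cin, M))
  for (t in 1:3)
    dxp[t:(t + L - 1), , ] <- dxp[t:(t + L - 1), , , drop = FALSE] +
      aperm(array(dcols[(t - 1) * Cin + seq_len(Cin), , drop = FALSE],
                  dim = c(Cin, L, M)), c(2, 1, 3))
  list(dx = dxp[2:(L + 1), , , drop = FALSE], dW = dW, db = db)
}

# ---- full fusion forward/backward ---------------------------------------
# regions: [nsamp, N, L]; clinical: nsamp x d matrix (0 columns allowed).

fusionForwardFull <- function(regions, clinical, params, spec,
                              training = FALSE, dropmask = NULL,
                              momentum = bnMomentum) {
  ns <- dim(regions)[1]; N <- dim(regions)[2]; L <- dim(regions)[3]
  slope <- spec$leaky_slope
  if (spec$branch == "conv1d") {
    # rows become a batch of M = ns*N single-channel sequences
    x <- array(aperm(regions, c(3, 1, 2)), dim = c(L, ns, N))   # L x ns x N
    x <- array(aperm(x, c(1, 3, 2)), dim = c(L, 1, N * ns))     # seq per (row, sample)
    cv1 <- conv1dForward(x, params$branch$W1, params$branch$b1)
    f1 <- bnForwardMat(matrix(aperm(cv1$out, c(1, 3, 2)), ncol = 16),
                       params$branch$bn1, training, momentum)
    r1 <- reluForward(f1$out)
    a1 <- aperm(array(r1$out, dim = c(L, N * ns, 16)), c(1, 3, 2))
    cv2 <- conv1dForward(a1, params$branch$W2, params$branch$b2)
    f2 <- bnForwardMat(matrix(aperm(cv2$out, c(1, 3, 2)), ncol = 32),
                       params$branch$bn2, training, momentum)
    r2 <- reluForward(f2$out)
    # r2$out rows ordered (l, seq) with seq = row-major (N rows per sample)
    a2 <- array(r2$out, dim = c(L, N, ns, 32))
    gap <- t(apply(a2, c(3, 4), mean))                # 32 x ns
    params$branch$bn1 <- f1$bn; params$branch$bn2 <- f2$bn
    branch_cache <- list(cv1 = cv1, f1 = f1, r1 = r1, cv2 = cv2, f2 = f2,
                         r2 = r2, L = L, N = N, ns = ns)
  } else {
    xm <- matrix(aperm(regions, c(2, 3, 1)), ncol = 1)  # (N*L*ns) x 1
    cv1 <- conv2dForward(xm, N, L, ns, params$branch$W1, params$branch$b1)
    f1 <- bnForwardMat(cv1$out, params$branch$bn1, training, momentum)
    r1 <- reluForward(f1$out)
    cv2 <- conv2dForward(r1$out, N, L, ns, params$branch$W2, params$branch$b2)
    f2 <- bnForwardMat(cv2$out, params$branch$bn2, training, momentum)
    r2 <- reluForward(f2$out)
    gap <- gapForward(r2$out, N, L, ns)               # 128 x ns
    params$branch$bn1 <- f1$bn; params$branch$bn2 <- f2$bn
    branch_cache <- list(cv1 = cv1, f1 = f1, r1 = r1, cv2 = cv2, f2 = f2,
                         r2 = r2, H = N, W = L, ns = ns)
  }
  fused <- rbind(gap, t(clinical))                    # (gap + d) x ns
  z1 <- sweep(crossprod(params$dense1$W, fused), 1L, params$dense1$b, "+")
  h1 <- leakyForward(z1, slope)
  o1 <- h1$out
  if (training) {
    if (is.null(dropmask))
      dropmask <- list(m1 = matrix(stats::rbinom(128 * ns, 1, 1 - spec$dropout),
                                   128, ns) / (1 - spec$dropout),
                       m2 = matrix(stats::rbinom(64 * ns, 1, 1 - spec$dropout),
                                   64, ns) / (1 - spec$dropout))
    o1 <- o1 * dropmask$m1
  }
  z2 <- sweep(crossprod(params$dense2$W, o1), 1L, params$dense2$b, "+")
  h2 <- leakyForward(z2, slope)
  o2 <- h2$out
  if (training) o2 <- o2 * dropmask$m2
  logits <- sweep(crossprod(params$out$W, o2), 1L, params$out$b, "+")
  list(logits = logits, probs = softmaxProbs(logits), params = params,
       cache = list(branch = branch_cache, fused = fused, h1 = h1, h2 = h2,
                    o1 = o1, o2 = o2, gapWidth = nrow(gap),
                    dropmask = if (training) dropmask))
}

fusionBackwardFull <- function(dlogits, params, spec, cache) {
  slope <- spec$leaky_slope
  dout_W <- cache$o2 %*% t(dlogits)
  dout_b <- rowSums(dlogits)
  do2 <- params$out$W %*% dlogits
  if (!is.null(cache$dropmask)) do2 <- do2 * cache$dropmask$m2
  dz2 <- leakyBackward(do2, cache$h2$mask, slope)
  dd2_W <- cache$o1 %*% t(dz2)
  dd2_b <- rowSums(dz2)
  do1 <- params$dense2$W %*% dz2
  if (!is.null(cache$dropmask)) do1 <- do1 * cache$dropmask$m1
  dz1 <- leakyBackward(do1, cache$h1$mask, slope)
  dd1_W <- cache$fused %*% t(dz1)
  dd1_b <- rowSums(dz1)
  dfused <- params$dense1$W %*% dz1
  gw <- cache$gapWidth
  dgap <- dfused[seq_len(gw), , drop = FALSE]
  bc <- cache$branch
  if (spec$branch == "conv1d") {
    L <- bc$L; N <- bc$N; ns <- bc$ns
    da2 <- array(0, dim = c(L, N, ns, 32))
    sc <- 1 / (L * N)
    for (s in seq_len(ns))
      da2[, , s, ] <- rep(dgap[, s] * sc, each = L * N)
    dr2 <- matrix(da2, ncol = 32)
    df2 <- reluBackward(dr2, bc$r2$mask)
    bn2 <- bnBackwardMat(df2, params$branch$bn2, bc$f2$cache)
    dcv2 <- aperm(array(bn2$dm, dim = c(L, N * ns, 32)), c(1, 3, 2))
    g2 <- conv1dBackward(dcv2, params$branch$W2, bc$cv2$cache)
    dr1 <- matrix(aperm(g2$dx, c(1, 3, 2)), ncol = 16)
    df1 <- reluBackward(dr1, bc$r1$mask)
    bn1 <- bnBackwardMat(df1, params$branch$bn1, bc$f1$cache)
    dcv1 <- aperm(array(bn1$dm, dim = c(L, N * ns, 16)), c(1, 3, 2))
    g1 <- conv1dBackward(dcv1, params$branch$W1, bc$cv1$cache)
  } else {
    da2 <- gapBackward(dgap, bc$H, bc$W, bc$ns)
    df2 <- reluBackward(da2, bc$r2$mask)
    bn2 <- bnBackwardMat(df2, params$branch$bn2, bc$f2$cache)
    g2 <- conv2dBackward(bn2$dm, params$branch$W2, bc$cv2$cache)
    df1 <- reluBackward(g2$dx, bc$r1$mask)
    bn1 <- bnBackwardMat(df1, params$branch$bn1, bc$f1$cache)
    g1 <- conv2dBackward(bn1$dm, params$branch$W1, bc$cv1$cache,
                         need_dx = FALSE)
  }
  zero_bn <- function(bn, d) list(gamma = d$dgamma, beta = d$dbeta,
                                  running_mean = 0 * bn$running_mean,
                                  running_var = 0 * bn$running_var)
  list(branch = list(W1 = g1$dW, b1 = g1$db,
                     bn1 = zero_bn(params$branch$bn1, bn1),
                     W2 = g2$dW, b2 = g2$db,
                     bn2 = zero_bn(params$branch$bn2, bn2)),
       dense1 = list(W = dd1_W, b = dd1_b),
       dense2 = list(W = dd2_W, b = dd2_b),
       out = list(W = dout_W, b = dout_b))
}

.region_input <- function(regions) {
  if (is(regions, "RegionTensor")) regions <- regions@data
  if (length(dim(regions)) == 3L && dim(regions)[2] == 1L)
    regions <- array(regions, dim = c(1L, dim(regions)[1], dim(regions)[3]))
  regions
}

#' Fusion network forward pass
#'
#' Inference-mode (dropout off, running batch-norm moments; deterministic).
#'
#' @param regions a \linkS4class{RegionTensor} (one sample), or an array
#'   [nsamp, N, L] for a batch.
#' @param clinical numeric vector of length d (one sample) or nsamp x d
#'   matrix; use a 0-column matrix for an image-only model.
#' @param model a \linkS4class{FusionModel}, or bare parameters (then
#'   \code{spec} required).
#' @param spec optional \code{\link{fusionSpec}}.
#' @return list with \code{logits} and \code{probs} (C x nsamp; row 2 is the
#'   diseased probability).
#' @export
fusionForward <- function(regions, clinical, model, spec = NULL) {
  if (is(model, "FusionModel")) { params <- model@params; spec <- model@spec }
  else params <- model
  if (is.null(spec)) stop("spec required with a bare parameter list")
  regions <- .region_input(regions)
  if (is.null(dim(clinical))) clinical <- matrix(clinical, nrow = dim(regions)[1])
  if (ncol(clinical) != spec$dClinical)
    stop(sprintf("clinical vector length %d does not match fitted d = %d",
                 ncol(clinical), spec$dClinical))
  if (dim(regions)[2] != spec$nRegions || dim(regions)[3] != spec$regionLen)
    stop(sprintf("region tensor shape (%d, 1, %d) does not match spec (%d, 1, %d)",
                 dim(regions)[2], dim(regions)[3], spec$nRegions, spec$regionLen))
  fw <- fusionForwardFull(regions, clinical, params, spec, training = FALSE)
  list(logits = fw$logits, probs = fw$probs)
}

fusionLoss <- function(regions, clinical, labels, params, spec,
                       training = TRUE, dropmask = NULL) {
  fw <- fusionForwardFull(regions, clinical, params, spec, training, dropmask)
  crossEntropy(fw$logits, labels)$loss
}

#' Train the multimodal fusion network
#'
#' Cross-entropy loss with Adam (learning rate 0.001), mini-batches of 16,
#' 10 epochs by default; per-epoch history and best-validation checkpoint as
#' in \code{\link{trainFcrn}}.
#'
#' @param regions array [nsamp, N, L] of region tensors.
#' @param clinical nsamp x d matrix (0 columns for image-only).
#' @param labels integer 0/1 image labels.
#' @param spec a \code{\link{fusionSpec}}; defaults to one matching the
#'   inputs.
#' @param epochs default 10.
#' @param lr default 0.001.
#' @param batch_size default 16.
#' @param val_frac held-out fraction when no explicit validation set is
#'   given; default 0.2.
#' @param regions_val,clinical_val,labels_val optional validation set.
#' @param patience early-stopping patience; default 10.
#' @param seed RNG seed.
#' @param verbose print per-epoch progress.
#' @return a \linkS4class{FusionModel}.
#' @export
trainFusion <- function(regions, clinical, labels, spec = NULL, epochs = 10L,
                        lr = 1e-3, batch_size = 16L, val_frac = 0.2,
                        regions_val = NULL, clinical_val = NULL,
                        labels_val = NULL, patience = 10L, seed = 1L,
                        verbose = FALSE) {
  regions <- .region_input(regions)
  labels <- as.integer(labels)
  ns <- dim(regions)[1]
  if (length(labels) != ns) stop("labels must match sample count")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(dim(clinical))) clinical <- matrix(clinical, nrow = ns)
  if (is.null(spec))
    spec <- fusionSpec(d_clinical = ncol(clinical), n_regions = dim(regions)[2],
                       region_len = dim(regions)[3])
  set.seed(seed)
  params <- initFusion(spec)
  if (is.null(regions_val)) {
    sp <- stratifiedSplit(labels, c(1 - val_frac, val_frac, 0), seed = seed + 1L)
    regions_val <- regions[sp$val, , , drop = FALSE]
    clinical_val <- clinical[sp$val, , drop = FALSE]
    labels_val <- labels[sp$val]
    regions <- regions[sp$train, , , drop = FALSE]
    clinical <- clinical[sp$train, , drop = FALSE]
    labels <- labels[sp$train]
    ns <- length(sp$train)
  }
  opt <- adamInit(params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  evalSet <- function(p, rs, cs, ys) {
    fw <- fusionForwardFull(rs, cs, p, spec, training = FALSE)
    ce <- crossEntropy(fw$logits, ys)
    c(loss = ce$loss, acc = mean(max.col(t(fw$logits)) - 1L == ys))
  }
  best <- list(params = params, val_loss = Inf)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ns)
    tot <- 0; hit <- 0
    for (s in split(ord, ceiling(seq_along(ord) / batch_size))) {
      rb <- regions[s, , , drop = FALSE]
      cb <- clinical[s, , drop = FALSE]
      fw <- fusionForwardFull(rb, cb, params, spec, training = TRUE)
      params <- fw$params
      ce <- crossEntropy(fw$logits, labels[s])
      tot <- tot + ce$loss * length(s)
      hit <- hit + sum(max.col(t(fw$logits)) - 1L == labels[s])
      grads <- fusionBackwardFull(ce$dlogits, params, spec, fw$cache)
      up <- adamStep(params, grads, opt, lr = lr)
      params <- up$params
      opt <- up$state
    }
    vm <- evalSet(params, regions_val, clinical_val, labels_val)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / ns,
                                   train_acc = hit / ns, val_loss = vm["loss"],
                                   val_acc = vm["acc"]))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      ep, tot / ns, hit / ns, vm["loss"], vm["acc"]))
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
  if (epochs > 0L) {
    # re-estimate branch batch-norm moments under the final weights
    dmask <- list(m1 = matrix(1, 128, ns), m2 = matrix(1, 64, ns))
    fw <- fusionForwardFull(regions, clinical, final, spec, training = TRUE,
                            dropmask = dmask, momentum = 1)
    final <- fw$params
  }
  methods::new("FusionModel", spec = unclass(spec), params = final,
               history = hist)
}

#' End-to-end prediction for one image
#'
#' Composes the full pipeline: preprocess, patch extraction at the map
#' stride, FCRN patch probabilities, max-aggregated probability map, top
#' high-risk regions, region tensor, and fusion with the encoded clinical
#' record. Deterministic given fixed artifacts.
#'
#' @param image H x W x 3 array (raw intensities).
#' @param clinical_record one-row data.frame of the clinical schema, or NULL
#'   for an image-only fusion model.
#' @param fcrn a trained \linkS4class{FcrnModel}.
#' @param fusion a trained \linkS4class{FusionModel}.
#' @param encoder a fitted \linkS4class{ClinicalEncoder} (NULL if image-only).
#' @param preprocess a \code{\link{preprocessConfig}} or NULL to use the image
#'   as-is (already clean).
#' @param map_stride patch stride for map aggregation; default half the patch
#'   size.
#' @param top_n regions kept; defaults to the fusion spec's N.
#' @param threshold region mean threshold; default 0.
#' @param mask apply Otsu masking during preprocessing.
#' @return list with \code{probs} (length-C, names healthy/diseased),
#'   \code{map} (the \linkS4class{ProbMap}) and \code{regions}.
#' @export
predictImage <- function(image, clinical_record, fcrn, fusion, encoder = NULL,
                         preprocess = NULL, map_stride = NULL, top_n = NULL,
                         threshold = 0, mask = TRUE) {
  stopifnot(is(fcrn, "FcrnModel"), is(fusion, "FusionModel"))
  p <- fcrn@spec$input_size
  clean <- if (is.null(preprocess)) .as_image3(image)
           else preprocessImage(image, preprocess, mask = mask)$pixels
  if (dim(clean)[1] < p || dim(clean)[2] < p)
    stop(sprintf("patching stage: image %dx%d smaller than patch size %d",
                 dim(clean)[1], dim(clean)[2], p))
  if (is.null(map_stride)) map_stride <- max(p %/% 2L, 1L)
  if (is.null(top_n)) top_n <- fusion@spec$nRegions
  grid <- extractPatches(clean, p = p, stride = map_stride)
  pred <- fcrnForward(patchPixels(grid), fcrn)
  pm <- aggregateMap(grid, pred$probs[2, ])
  regs <- topRegions(pm, n = top_n, threshold = threshold, windowSize = p)
  tens <- regionsToTensor(regs, n_slots = fusion@spec$nRegions)
  cvec <- if (is.null(encoder)) matrix(0, 1, 0)
          else transformClinical(clinical_record, encoder)
  fw <- fusionForward(tens, cvec, fusion)
  probs <- drop(fw$probs)
  names(probs) <- c("healthy", "diseased")[seq_along(probs)]
  list(probs = probs, map = pm, regions = regs)
}
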