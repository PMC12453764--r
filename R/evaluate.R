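#' Stratified train/validation/test split
#'
#' Allocates indices to three parts with per-class largest-remainder
#' allocation, so each part's class proportions match the global proportions
#' within one sample. Deterministic under the seed.
#'
#' @param labels vector of class labels.
#' @param fractions length-3 non-negative fractions summing to 1; default
#'   c(0.70, 0.15, 0.15).
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test}, plus \code{labels} and \code{seed}.
#' @export
stratifiedSplit <- function(labels, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative values summing to 1")
  if (length(unique(labels)) < 2L)
    stop("stratification impossible: only one class present")
  set.seed(seed)
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    ideal <- fractions * n
    sizes <- floor(ideal)
    rem <- n - sum(sizes)
    if (rem > 0) {
      frac_part <- ideal - sizes
      give <- order(-frac_part, seq_along(frac_part))[seq_len(rem)]
      sizes[give] <- sizes[give] + 1L
    }
    bounds <- cumsum(sizes)
    parts$train <- c(parts$train, idx[seq_len(sizes[1])])
    if (sizes[2] > 0)
      parts$val <- c(parts$val, idx[(bounds[1] + 1):bounds[2]])
    if (sizes[3] > 0)
      parts$test <- c(parts$test, idx[(bounds[2] + 1):bounds[3]])
  }
  list(train = sort(parts$train), val = sort(parts$val),
       test = sort(parts$test), labels = labels, seed = seed)
}

#' Stratified k-fold plan
#'
#' Shuffles each class under the seed and deals indices round-robin, so the
#' folds partition all indices and each class is balanced across folds within
#' one sample.
#'
#' @param labels vector of class labels.
#' @param k number of folds; default 5.
#' @param seed RNG seed.
#' @return list with \code{folds} (list of k test-index vectors), \code{k},
#'   \code{seed}.
#' @export
kFold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop("need at least k samples")
  for (cl in unique(labels))
    if (sum(labels == cl) < k)
      stop(sprintf("class '%s' has fewer than k = %d samples", cl, k))
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    f <- rep_len(seq_len(k), length(idx))
    for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[f == j])
  }
  list(folds = lapply(folds, sort), k = k, seed = seed)
}

#' Confusion-matrix metrics and rank-based AUC
#'
#' Computes TP/FP/TN/FN (class 1 = positive/diseased), accuracy, sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), F1, and AUC as
#' the Mann-Whitney rank statistic of the scores (ties counted 1/2) --
#' identical to the trapezoidal area under the threshold-swept ROC in the
#' absence of ties. Ratios with zero denominators are NA, never silent 0.
#' ROC points are swept over the unique score thresholds (plus sentinels), so
#' the curve runs from (0,0) to (1,1).
#'
#' @param labels integer 0/1 truth.
#' @param predicted integer 0/1 predictions.
#' @param scores numeric diseased-class scores (optional; AUC/ROC are NA /
#'   empty without them).
#' @return a \linkS4class{MetricsReport}.
#' @examples
#' computeMetrics(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0.1, 0.35, 0.4, 0.8))
#' @export
computeMetrics <- function(labels, predicted, scores = NULL) {
  labels <- as.integer(labels)
  predicted <- as.integer(predicted)
  if (length(labels) != length(predicted))
    stop("labels and predictions must have equal length")
  if (!all(labels %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1")
  tp <- sum(labels == 1L & predicted == 1L)
  fp <- sum(labels == 0L & predicted == 1L)
  tn <- sum(labels == 0L & predicted == 0L)
  fn <- sum(labels == 1L & predicted == 0L)
  n <- length(labels)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  acc <- div(tp + tn, n)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  auc <- NA_real_
  roc <- data.frame(threshold = numeric(0), fpr = numeric(0), tpr = numeric(0))
  if (!is.null(scores)) {
    if (length(scores) != n) stop("scores must match labels in length")
    npos <- sum(labels == 1L); nneg <- n - npos
    if (npos > 0 && nneg > 0) {
      r <- rank(scores)                      # midranks handle ties as 1/2
      auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
      thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
      roc <- data.frame(threshold = thr,
                        fpr = vapply(thr, function(t) sum(scores >= t & labels == 0L) / nneg, 0),
                        tpr = vapply(thr, function(t) sum(scores >= t & labels == 1L) / npos, 0))
    }
  }
  methods::new("MetricsReport",
               counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
               metrics = c(accuracy = acc, sensitivity = sens,
                           specificity = spec, precision = prec, f1 = f1,
                           auc = auc),
               roc = roc)
}

#' Default hyperparameter search grid
#'
#' The fully crossed tuning space used by the experimental protocol:
#' learning rate \{0.01, 0.001, 0.0005\}, batch size \{8, 16, 32\}, dropout
#' \{0.1, 0.2, 0.3\}, activation \{relu, leaky_relu, tanh\}, patch size
#' \{16, 32, 64\} -- 243 cells.
#'
#' @return named list of value vectors.
#' @export
defaultGrid <- function() {
  list(learning_rate = c(0.01, 0.001, 0.0005),
       batch_size = c(8L, 16L, 32L),
       dropout = c(0.1, 0.2, 0.3),
       activation = c("relu", "leaky_relu", "tanh"),
       patch_size = c(16L, 32L, 64L))
}

#' Grid search over a hyperparameter space
#'
#' Evaluates every combination of the grid with a user-supplied training
#' function and returns the configuration maximising the validation metric,
#' with deterministic first-in-grid-order tie-breaking. A failing cell is
#' recorded (metric NA, error message kept) and the search continues.
#'
#' @param space named list of value vectors (fully crossed).
#' @param train_fn function(config_row_as_list) returning a numeric metric
#'   (higher is better).
#' @param metric_name label for the metric column; default "metric".
#' @return list with \code{best} (list of winning values), \code{best_metric},
#'   and \code{table} (one row per cell, grid order, with metric and error
#'   columns).
#' @export
gridSearch <- function(space, train_fn, metric_name = "metric") {
  if (!length(space)) stop("empty grid")
  tab <- expand.grid(space, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  metrics <- rep(NA_real_, nrow(tab))
  errors <- rep(NA_character_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cfg <- as.list(tab[i, , drop = FALSE])
    res <- tryCatch(train_fn(cfg), error = function(e) e)
    if (inherits(res, "error")) errors[i] <- conditionMessage(res)
    else metrics[i] <- as.numeric(res)
  }
  tab[[metric_name]] <- metrics
  tab$error <- errors
  if (all(is.na(metrics))) stop("all grid cells failed")
  best_i <- which(metrics == max(metrics, na.rm = TRUE))[1]
  list(best = as.list(tab[best_i, seq_along(space), drop = FALSE]),
       best_metric = metrics[best_i], best_index = best_i, table = tab)
}

#' Region tensors for every image of a cohort
#'
#' Runs the trained FCRN over each image's patch grid, aggregates the
#' probability map, extracts the top high-risk windows and reduces them to
#' fusion input profiles.
#'
#' @param cohort a \linkS4class{SynthCohort}.
#' @param fcrn a trained \linkS4class{FcrnModel}.
#' @param map_stride patch stride for map aggregation; default half the patch
#'   size.
#' @param n_slots tensor rows N per image; default 8.
#' @param threshold region mean threshold; default 0.
#' @return numeric array [n_images, n_slots, patch_size].
#' @export
cohortRegionTensors <- function(cohort, fcrn, map_stride = NULL, n_slots = 8L,
                                threshold = 0) {
  p <- fcrn@spec$input_size
  if (is.null(map_stride)) map_stride <- max(p %/% 2L, 1L)
  n <- nSamples(cohort)
  out <- array(0, dim = c(n, n_slots, p))
  for (i in seq_len(n)) {
    grid <- extractPatches(cohort@images[[i]], p = p, stride = map_stride)
    pred <- fcrnForward(patchPixels(grid), fcrn)
    pm <- aggregateMap(grid, pred$probs[2, ])
    regs <- topRegions(pm, n = n_slots, threshold = threshold, windowSize = p)
    out[i, , ] <- regionsToTensor(regs, n_slots = n_slots)@data[, 1, ]
  }
  out
}

# Clinical-only MLP baseline: dense 64 and 32 leaky-ReLU layers on the
# encoded clinical vector. Reuses the fusion machinery with a frozen
# all-zero region tensor so only the clinical pathway carries signal.
trainClinicalMlp <- function(clinical, labels, epochs = 30L, lr = 1e-3,
                             batch_size = 16L, seed = 1L, val_frac = 0.2,
                             clinical_val = NULL, labels_val = NULL) {
  labels <- as.integer(labels)
  set.seed(seed)
  d <- ncol(clinical)
  params <- list(dense1 = list(W = heUniform(c(d, 64), d), b = rep(0, 64)),
                 dense2 = list(W = heUniform(c(64, 32), 64), b = rep(0, 32)),
                 out = list(W = heUniform(c(32, 2), 32), b = rep(0, 2)))
  if (is.null(clinical_val)) {
    sp <- stratifiedSplit(labels, c(1 - val_frac, val_frac, 0), seed = seed + 1L)
    clinical_val <- clinical[sp$val, , drop = FALSE]
    labels_val <- labels[sp$val]
    clinical <- clinical[sp$train, , drop = FALSE]
    labels <- labels[sp$train]
  }
  ns <- nrow(clinical)
  fwd <- function(p, cm) {
    z1 <- sweep(crossprod(p$dense1$W, t(cm)), 1L, p$dense1$b, "+")
    h1 <- leakyForward(z1)
    z2 <- sweep(crossprod(p$dense2$W, h1$out), 1L, p$dense2$b, "+")
    h2 <- leakyForward(z2)
    logits <- sweep(crossprod(p$out$W, h2$out), 1L, p$out$b, "+")
    list(logits = logits, h1 = h1, h2 = h2, cm = cm)
  }
  opt <- adamInit(params)
  best <- list(params = params, val_loss = Inf)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ns)
    for (s in split(ord, ceiling(seq_along(ord) / batch_size))) {
      fw <- fwd(params, clinical[s, , drop = FALSE])
      ce <- crossEntropy(fw$logits, labels[s])
      do <- ce$dlogits
      g_out <- list(W = fw$h2$out %*% t(do), b = rowSums(do))
      dh2 <- leakyBackward(params$out$W %*% do, fw$h2$mask)
      g_d2 <- list(W = fw$h1$out %*% t(dh2), b = rowSums(dh2))
      dh1 <- leakyBackward(params$dense2$W %*% dh2, fw$h1$mask)
      g_d1 <- list(W = t(fw$cm) %*% t(dh1), b = rowSums(dh1))
      up <- adamStep(params, list(dense1 = g_d1, dense2 = g_d2, out = g_out),
                     opt, lr = lr)
      params <- up$params
      opt <- up$state
    }
    fwv <- fwd(params, clinical_val)
    vl <- crossEntropy(fwv$logits, labels_val)$loss
    if (vl < best$val_loss - 1e-9) best <- list(params = params, val_loss = vl)
  }
  pp <- best$params
  list(params = pp,
       predict = function(cm) {
         softmaxProbs(fwd(pp, cm)$logits)
       })
}

#' Three-variant experiment: image-only, clinical-only, fused
#'
#' Runs the full protocol on a cohort: a stratified 70/15/15 split by image,
#' FCRN patch training on the training images, probability-map region
#' tensors for every image, then three classifiers trained on the same
#' split -- image-only (fusion network with a zero-length clinical vector),
#' clinical-only (MLP on the encoded clinical vector), and the fused model.
#' Reports validation-set metrics per variant.
#'
#' @param cohort a \linkS4class{SynthCohort}.
#' @param seed global seed.
#' @param fcrn_spec a \code{\link{fcrnSpec}}.
#' @param fcrn_epochs FCRN epochs; default 2 (the patch task is deliberately
#'   easy at synthetic effect sizes).
#' @param fusion_epochs fusion epochs; default 10.
#' @param patch_stride stride of the patch-training grid; default half the
#'   patch size (lesion-centred coverage).
#' @param max_train_patches cap on FCRN training patches after class
#'   balancing; default 1500.
#' @param n_slots region tensor rows; default 8.
#' @param eval_on evaluate on "val" (default) or "test".
#' @return list with \code{metrics} (named list of
#'   \linkS4class{MetricsReport}: image_only, clinical_only, fused),
#'   \code{split}, \code{fcrn}, and \code{models}.
#' @export
runExperiment <- function(cohort, seed = 42L, fcrn_spec = fcrnSpec(),
                          fcrn_epochs = 2L, fusion_epochs = 10L,
                          patch_stride = NULL, max_train_patches = 1500L,
                          n_slots = 8L, eval_on = c("val", "test")) {
  stopifnot(is(cohort, "SynthCohort"))
  eval_on <- match.arg(eval_on)
  labels <- cohortLabels(cohort)
  if (length(unique(labels)) < 2L)
    stop("degenerate cohort: both classes required")
  p <- fcrn_spec$input_size
  if (is.null(patch_stride)) patch_stride <- max(p %/% 2L, 1L)
  split <- stratifiedSplit(labels, c(0.70, 0.15, 0.15), seed = seed)

  # --- FCRN on training-image patches, labelled by lesion-mask coverage
  tr_patch <- collectPatches(cohort, split$train, p, patch_stride)
  va_patch <- collectPatches(cohort, split$val, p, patch_stride)
  keep <- balancePatchIndices(tr_patch$labels, max_train_patches, seed)
  fcrn <- trainFcrn(tr_patch$pixels[, , , keep, drop = FALSE],
                    tr_patch$labels[keep], spec = fcrn_spec,
                    epochs = fcrn_epochs, batch_size = 32L,
                    x_val = va_patch$pixels, labels_val = va_patch$labels,
                    seed = seed)

  # --- region tensors + clinical encoding for all images
  regions <- cohortRegionTensors(cohort, fcrn, map_stride = patch_stride,
                                 n_slots = n_slots)
  enc <- fitClinicalEncoder(cohortClinical(cohort)[split$train, , drop = FALSE])
  cvec <- transformClinical(cohortClinical(cohort), enc)

  ev <- split[[eval_on]]
  tr <- split$train
  none <- matrix(0, nSamples(cohort), 0)

  img_model <- trainFusion(regions[tr, , , drop = FALSE], none[tr, , drop = FALSE],
                           labels[tr], epochs = fusion_epochs, seed = seed,
                           regions_val = regions[ev, , , drop = FALSE],
                           clinical_val = none[ev, , drop = FALSE],
                           labels_val = labels[ev])
  fus_model <- trainFusion(regions[tr, , , drop = FALSE], cvec[tr, , drop = FALSE],
                           labels[tr], epochs = fusion_epochs, seed = seed,
                           regions_val = regions[ev, , , drop = FALSE],
                           clinical_val = cvec[ev, , drop = FALSE],
                           labels_val = labels[ev])
  mlp <- trainClinicalMlp(cvec[tr, , drop = FALSE], labels[tr], seed = seed,
                          clinical_val = cvec[ev, , drop = FALSE],
                          labels_val = labels[ev])

  scoreOf <- function(model, cl) {
    fw <- fusionForward(regions[ev, , , drop = FALSE], cl, model)
    fw$probs[2, ]
  }
  s_img <- scoreOf(img_model, none[ev, , drop = FALSE])
  s_fus <- scoreOf(fus_model, cvec[ev, , drop = FALSE])
  s_mlp <- mlp$predict(cvec[ev, , drop = FALSE])[2, ]
  rep_of <- function(s) computeMetrics(labels[ev], as.integer(s >= 0.5), s)

  list(metrics = list(image_only = rep_of(s_img),
                      clinical_only = rep_of(s_mlp),
                      fused = rep_of(s_fus)),
       split = split, fcrn = fcrn,
       models = list(image_only = img_model, fused = fus_model,
                     clinical_only = mlp))
}

#' Collect mask-labelled patches from cohort images
#'
#' Extracts the patch grid of every selected image and labels each patch by
#' lesion-mask coverage (see \code{\link{labelPatches}}).
#'
#' @param cohort a \linkS4class{SynthCohort}.
#' @param idx integer indices of the images to use.
#' @param p patch size.
#' @param stride patch stride.
#' @return list with \code{pixels} ([p, p, 3, total]) and \code{labels}.
#' @export
collectPatches <- function(cohort, idx, p, stride) {
  pix <- vector("list", length(idx))
  labs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    grid <- extractPatches(cohort@images[[i]], p = p, stride = stride)
    pix[[j]] <- patchPixels(grid)
    labs[[j]] <- labelPatches(grid, cohort@masks[[i]])
  }
  nper <- vapply(pix, function(a) dim(a)[4], 0L)
  all <- array(0, dim = c(p, p, 3, sum(nper)))
  at <- 0L
  for (j in seq_along(pix)) {
    all[, , , at + seq_len(nper[j])] <- pix[[j]]
    at <- at + nper[j]
  }
  list(pixels = all, labels = unlist(labs))
}

# Balanced subsample of patch indices: all of the minority class, an equal
# number of the majority, capped at max_total.
balancePatchIndices <- function(labels, max_total, seed) {
  set.seed(seed + 7L)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg))
    stop("patch labelling produced a single class; lesions too small for the patch grid")
  take <- min(length(pos), length(neg), max_total %/% 2L)
  c(sample(pos, take), sample(neg, take))
}
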