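test_that("stratified splits honour fractions and class balance", {
  labels <- rep(c(0L, 1L), each = 50)
  sp <- stratifiedSplit(labels, c(0.70, 0.15, 0.15), seed = 1)
  expect_length(sp$train, 70)
  expect_equal(sum(labels[sp$train]), 35)
  expect_equal(length(sp$val) + length(sp$test), 30)
  for (part in list(sp$val, sp$test)) {
    expect_true(length(part) %in% 14:16)
    expect_true(sum(labels[part]) %in% 7:8)
  }
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
  expect_identical(sp, stratifiedSplit(labels, c(0.70, 0.15, 0.15), seed = 1))
  expect_error(stratifiedSplit(rep(1L, 10)), "one class")
})

test_that("split invariants hold across random label vectors", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    sp <- stratifiedSplit(labels, seed = i)
    idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(idx), seq_len(n))          # partition
    for (part in sp[c("train", "val", "test")]) {
      for (cl in 0:1) {
        got <- sum(labels[part] == cl)
        ideal <- sum(labels == cl) * length(part) / n
        expect_lt(abs(got - ideal), 1 + 1e-9)    # within one sample
      }
    }
  }
})

test_that("k-fold plans are stratified partitions with the remainder rule", {
  labels <- rep(c(0L, 1L), each = 5)
  kf <- kFold(labels, k = 5, seed = 3)
  for (f in kf$folds) {
    expect_length(f, 2)
    expect_equal(sum(labels[f]), 1)              # one per class per fold
  }
  expect_equal(sort(unlist(kf$folds)), seq_along(labels))

  kf11 <- kFold(rep(0:1, c(5, 6)), k = 5, seed = 4)
  expect_equal(sort(lengths(kf11$folds), decreasing = TRUE), c(3, 2, 2, 2, 2))
  expect_error(kFold(rep(0:1, c(3, 9)), k = 5), "fewer than")
})

test_that("metrics match their closed-form definitions", {
  labels <- c(rep(1, 100), rep(0, 100))
  pred <- c(rep(1, 90), rep(0, 10), rep(1, 5), rep(0, 95))
  m <- metricValues(computeMetrics(labels, pred))
  expect_equal(m[["sensitivity"]], 0.90)
  expect_equal(m[["specificity"]], 0.95)
  expect_equal(m[["accuracy"]], 0.925)
  expect_equal(m[["precision"]], 18 / 19)
  expect_equal(m[["f1"]], 2 * (18 / 19) * 0.9 / (18 / 19 + 0.9))
  expect_equal(round(m[["precision"]], 4), 0.9474)
  expect_equal(round(m[["f1"]], 4), 0.9231)
})

test_that("AUC is the pairwise rank statistic with half-ties", {
  r <- computeMetrics(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0.1, 0.35, 0.4, 0.8))
  expect_equal(metricValues(r)[["auc"]], 0.75)
  # ties counted one half
  rt <- computeMetrics(c(0, 1), c(0, 1), c(0.5, 0.5))
  expect_equal(metricValues(rt)[["auc"]], 0.5)
  # perfect separation: AUC 1 and unit trapezoidal ROC area
  rp <- computeMetrics(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(metricValues(rp)[["auc"]], 1)
  roc <- rocPoints(rp)
  area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(area, 1)
})

test_that("metrics equal brute-force oracles on random instances", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)                  # induces ties
    pred <- as.integer(scores >= 0.5)
    m <- computeMetrics(labels, pred, scores)
    expect_equal(metricValues(m)[["auc"]], oracle_auc(labels, scores))
    cm <- confusionCounts(m)
    expect_equal(cm[["TP"]], sum(labels & pred))
    expect_equal(sum(cm), n)
    expect_equal(metricValues(m)[["accuracy"]], mean(labels == pred))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  labels <- rbinom(50, 1, 0.5)
  scores <- rnorm(50)
  a0 <- metricValues(computeMetrics(labels, labels, scores))[["auc"]]
  for (f in list(function(s) 3 * s + 2, exp, function(s) atan(s) - 5))
    expect_equal(metricValues(computeMetrics(labels, labels, f(scores)))[["auc"]], a0)
})

test_that("undefined ratios are NA, never silent zeros", {
  m <- metricValues(computeMetrics(c(1, 1), c(0, 0)))   # no negatives, no predicted positives
  expect_true(is.na(m[["specificity"]]))
  expect_true(is.na(m[["precision"]]))
  expect_equal(m[["sensitivity"]], 0)
})

test_that("grid search enumerates the full grid with deterministic ties", {
  one <- gridSearch(list(a = 1), function(cfg) 0.5)
  expect_equal(one$best$a, 1)

  space <- list(learning_rate = c(0.01, 0.001, 0.0005), batch = c(8, 16, 32))
  gs <- gridSearch(space, function(cfg) cfg$learning_rate * 0 + 0.7)
  expect_equal(nrow(gs$table), 9)
  expect_equal(gs$best_index, 1L)               # tie -> first in grid order

  gs2 <- gridSearch(space, function(cfg) {
    if (cfg$batch == 16) stop("boom")
    as.numeric(cfg$learning_rate == 0.001)
  })
  expect_equal(sum(!is.na(gs2$table$error)), 3)  # failures recorded
  expect_match(gs2$table$error[!is.na(gs2$table$error)][1], "boom")
  expect_equal(gs2$best$learning_rate, 0.001)
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  set.seed(9)
  labels <- rbinom(60, 1, 0.5)
  scores <- round(runif(60), 2)               # ties present
  a <- metricValues(computeMetrics(labels, labels, scores))[["auc"]]
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a, ref)
})

test_that("the three-variant experiment reports a full metrics table", {
  co <- generateCohort(synthConfig(n_images = 40, image_size = c(64, 64),
                                   lesion_intensity_shift = 0.3,
                                   clinical_effect_beta = 1, seed = 21))
  res <- runExperiment(co, seed = 21,
                       fcrn_spec = fcrnSpec(width = 8L, width2 = 12L),
                       fcrn_epochs = 1L, fusion_epochs = 2L,
                       max_train_patches = 200L)
  expect_setequal(names(res$metrics),
                  c("image_only", "clinical_only", "fused"))
  for (m in res$metrics) {
    expect_s4_class(m, "MetricsReport")
    expect_length(metricValues(m), 6)
  }
  expect_setequal(c(res$split$train, res$split$val, res$split$test),
                  seq_len(40))
  one_class <- generateCohort(synthConfig(n_images = 10, prevalence = 0,
                                          seed = 3))
  expect_error(runExperiment(one_class), "both classes")
})
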