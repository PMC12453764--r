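test_that("the fused vector length is GAP width plus clinical dimension", {
  for (d in c(0L, 3L, 12L)) {
    sp <- fusionSpec(d_clinical = d)
    pars <- initFusion(sp)
    expect_equal(nrow(pars$dense1$W), 32L + d)
    set.seed(1)
    regions <- array(runif(2 * 8 * 32), dim = c(2, 8, 32))
    clin <- matrix(rnorm(2 * d), 2, d)
    out <- fusionForward(regions, clin, pars, sp)
    expect_equal(dim(out$probs), c(2L, 2L))
    expect_lt(max(abs(colSums(out$probs) - 1)), 1e-6)
  }
  sp <- fusionSpec(d_clinical = 4)
  pars <- initFusion(sp)
  expect_error(fusionForward(array(0.1, dim = c(1, 8, 32)), matrix(0, 1, 2),
                             pars, sp), "does not match fitted")
  expect_error(fusionForward(array(0.1, dim = c(1, 4, 32)), matrix(0, 1, 4),
                             pars, sp), "region tensor shape")
})

test_that("GAP passes constant branch activations through unchanged", {
  sp <- fusionSpec(d_clinical = 0)
  pars <- initFusion(sp)
  # zero kernels + bias c: every branch activation is c, BN at identity state
  # maps it to c, ReLU keeps it, so F_gap is c in every channel
  pars$branch$W1[] <- 0; pars$branch$b1[] <- 0.3
  pars$branch$W2[] <- 0; pars$branch$b2[] <- 0.7
  pars$branch$bn1$running_var[] <- 1 - 1e-5
  pars$branch$bn1$running_mean[] <- 0
  pars$branch$bn2$running_var[] <- 1 - 1e-5
  pars$branch$bn2$running_mean[] <- 0
  set.seed(2)
  regions <- array(runif(8 * 32), dim = c(1, 8, 32))
  fw <- dermapatch:::fusionForwardFull(regions, matrix(0, 1, 0), pars, sp,
                                       training = FALSE)
  gap <- fw$cache$fused[1:32, 1]
  expect_equal(gap, rep(0.7, 32), tolerance = 1e-9)
})

test_that("region-row permutations leave the pooled branch output unchanged", {
  sp <- fusionSpec(d_clinical = 0)
  set.seed(3)
  pars <- initFusion(sp)
  # width-1 identity first kernel: center tap passes the sequence through
  pars$branch$W1[] <- 0
  pars$branch$W1[2, 1, 1] <- 1
  regions <- array(runif(1 * 8 * 32), dim = c(1, 8, 32))
  perm <- regions[, sample(8), , drop = FALSE]
  f1 <- dermapatch:::fusionForwardFull(regions, matrix(0, 1, 0), pars, sp, FALSE)
  f2 <- dermapatch:::fusionForwardFull(perm, matrix(0, 1, 0), pars, sp, FALSE)
  expect_equal(f1$cache$fused[1:32, 1], f2$cache$fused[1:32, 1],
               tolerance = 1e-12)
})

test_that("inference is deterministic with dropout off", {
  sp <- fusionSpec(d_clinical = 5)
  set.seed(4)
  pars <- initFusion(sp)
  regions <- array(runif(3 * 8 * 32), dim = c(3, 8, 32))
  clin <- matrix(rnorm(15), 3, 5)
  a <- fusionForward(regions, clin, pars, sp)
  b <- fusionForward(regions, clin, pars, sp)
  expect_identical(a$probs, b$probs)
})

test_that("zero epochs return the seeded initialisation for the fusion net", {
  set.seed(5)
  regions <- array(runif(12 * 8 * 32), dim = c(12, 8, 32))
  clin <- matrix(rnorm(24), 12, 2)
  y <- rep(c(0L, 1L), 6)
  m <- trainFusion(regions, clin, y, epochs = 0L, seed = 9)
  set.seed(9)
  ref <- initFusion(fusionSpec(d_clinical = 2))
  expect_equal(m@params$dense1$W, ref$dense1$W)
  expect_error(trainFusion(regions, clin, rep(0L, 12), epochs = 1L),
               "both classes")
})

test_that("numerical and analytic fusion gradients agree on a 3-sample batch", {
  for (branch in c("conv1d", "conv2d")) {
    sp <- fusionSpec(d_clinical = 4, branch = branch)
    set.seed(6)
    pars <- initFusion(sp)
    regions <- array(runif(3 * 8 * 32), dim = c(3, 8, 32))
    clin <- matrix(rnorm(12), 3, 4)
    y <- c(0L, 1L, 1L)
    dm <- list(m1 = matrix(1, 128, 3), m2 = matrix(1, 64, 3))
    fw <- dermapatch:::fusionForwardFull(regions, clin, pars, sp,
                                         training = TRUE, dropmask = dm)
    ce <- dermapatch:::crossEntropy(fw$logits, y)
    g <- dermapatch:::fusionBackwardFull(ce$dlogits, pars, sp, fw$cache)
    fl <- function(p) dermapatch:::fusionLoss(regions, clin, y, p, sp,
                                              training = TRUE, dropmask = dm)
    set.seed(7)
    paths <- list(c("branch", "W1"), c("branch", "bn1", "gamma"),
                  c("branch", "W2"), c("branch", "bn2", "beta"),
                  c("dense1", "W"), c("dense2", "W"), c("out", "W"),
                  c("out", "b"))
    for (pth in paths) {
      for (k in sample(length(pars[[pth]]), 2)) {
        eps <- 1e-6
        p1 <- pars; p1[[pth]][k] <- p1[[pth]][k] + eps
        p2 <- pars; p2[[pth]][k] <- p2[[pth]][k] - eps
        num <- (fl(p1) - fl(p2)) / (2 * eps)
        expect_true(grad_agrees(num, g[[pth]][k]),
                    label = sprintf("%s gradient of %s[%d]", branch,
                                    paste(pth, collapse = "$"), k))
      }
    }
  }
})

test_that("the fusion net learns a separable clinical signal", {
  set.seed(8)
  n <- 120
  y <- rep(c(0L, 1L), n / 2)
  regions <- array(runif(n * 8 * 32), dim = c(n, 8, 32))   # uninformative
  clin <- cbind(rnorm(n) + 2.5 * y, rnorm(n))
  m <- trainFusion(regions, clin, y, epochs = 10L, seed = 3)
  expect_gt(tail(trainingHistory(m)$val_acc, 1), 0.75)
})

test_that("predictImage composes the full pipeline deterministically", {
  co <- generateCohort(synthConfig(n_images = 24, image_size = c(64, 64),
                                   lesion_intensity_shift = 0.3, seed = 13))
  dat <- collectPatches(co, seq_len(24), 32L, 16L)
  small <- fcrnSpec(width = 8L, width2 = 12L)
  fcrn <- trainFcrn(dat$pixels, dat$labels, small, epochs = 1L, seed = 1)
  enc <- fitClinicalEncoder(cohortClinical(co))
  regions <- cohortRegionTensors(co, fcrn)
  cvec <- transformClinical(cohortClinical(co), enc)
  fus <- trainFusion(regions, cvec, cohortLabels(co), epochs = 2L, seed = 1)

  rec <- cohortClinical(co)[1, , drop = FALSE]
  r1 <- predictImage(co@images[[1]], rec, fcrn, fus, encoder = enc)
  r2 <- predictImage(co@images[[1]], rec, fcrn, fus, encoder = enc)
  expect_identical(r1$probs, r2$probs)
  expect_equal(sum(r1$probs), 1, tolerance = 1e-6)
  expect_s4_class(r1$map, "ProbMap")
  expect_error(predictImage(array(0.5, dim = c(16, 16, 3)), rec, fcrn, fus,
                            encoder = enc), "patching stage")
})
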