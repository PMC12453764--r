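test_that("nearest resampling follows the index-remapping rule", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]] row-wise
  up <- resampleImage(img, c(4, 4))
  # brute-force coordinate map floor(x * H / H')
  ref <- matrix(0, 4, 4)
  for (x in 0:3) for (y in 0:3)
    ref[x + 1, y + 1] <- img[floor(x * 2 / 4) + 1, floor(y * 2 / 4) + 1]
  expect_equal(up[, , 1], ref)
  expect_equal(up[1:2, 1:2, 1], matrix(1, 2, 2))   # source pixel fills a block

  same <- resampleImage(img, c(2, 2))
  expect_equal(same[, , 1], img)

  img4 <- matrix(seq_len(16), 4, 4)
  down <- resampleImage(img4, c(2, 2))
  expect_equal(down[, , 1], img4[c(1, 3), c(1, 3)])
  expect_true(all(down %in% img4))     # no new intensities in nearest mode
})

test_that("resampling rejects non-positive targets", {
  expect_error(resampleImage(matrix(1, 2, 2), c(0, 4)), "positive")
})

test_that("bilinear resampling preserves constants and stays in range", {
  img <- rand_img(6, 6, 1, seed = 2)
  out <- resampleImage(img, c(9, 9), mode = "bilinear")
  expect_true(min(out) >= min(img) - 1e-12 && max(out) <= max(img) + 1e-12)
  cst <- resampleImage(array(0.4, dim = c(3, 3, 1)), c(7, 5), mode = "bilinear")
  expect_equal(as.numeric(cst), rep(0.4, 35))
})

test_that("SANLM denoising matches the double-loop reference", {
  cfg <- preprocessConfig(sanlm_h = 0.5, sanlm_patch_radius = 1,
                          sanlm_search_radius = 2)
  img <- rand_img(16, 16, 1, seed = 3)
  expect_lt(max(abs(sanlmDenoise(img, cfg) - oracle_nlm(img, 1, 2, 0.5))), 1e-10)
  # pointwise distance variant (patch radius 0) and RGB weights-shared variant
  cfg0 <- preprocessConfig(sanlm_h = 0.3, sanlm_patch_radius = 0,
                           sanlm_search_radius = 2)
  img3 <- rand_img(10, 12, 3, seed = 4)
  expect_lt(max(abs(sanlmDenoise(img3, cfg0) - oracle_nlm(img3, 0, 2, 0.3))), 1e-10)
})

test_that("SANLM is exact on constant images and intensity-bounded", {
  cst <- array(0.37, dim = c(8, 8, 3))
  expect_equal(sanlmDenoise(cst), cst)
  expect_equal(exp(-0 / 0.1^2), 1)   # w(p,q) = 1 when intensities match
  for (s in 1:5) {
    img <- rand_img(9, 9, 3, seed = s)
    out <- sanlmDenoise(img)
    expect_true(min(out) >= min(img) - 1e-12 && max(out) <= max(img) + 1e-12)
  }
  expect_error(preprocessConfig(sanlm_h = 0), "> 0")
})

test_that("Otsu threshold equals the exhaustive within-class-variance scan", {
  two <- rep(0, 256); two[1] <- 10; two[256] <- 7
  expect_equal(otsuThreshold(two), oracle_otsu(two))
  expect_equal(otsuThreshold(two), 0L)   # smallest optimum on ties

  bim <- rep(0, 256); bim[51] <- 10; bim[201] <- 10
  t_bim <- otsuThreshold(bim)
  expect_equal(t_bim, oracle_otsu(bim))
  expect_true(t_bim >= 50 && t_bim < 200)  # classes are exactly {50}, {200}

  set.seed(10)
  for (i in 1:25) {
    counts <- rpois(256, lambda = runif(1, 0.2, 4))
    if (sum(counts > 0) < 2) next
    expect_equal(otsuThreshold(counts), oracle_otsu(counts))
  }
  expect_error(otsuThreshold(c(100, rep(0, 255))), "degenerate")
})

test_that("the skin mask separates a two-level image and zeroes background", {
  img <- array(0.1, dim = c(8, 8, 3))
  img[, 5:8, ] <- 0.9
  sm <- skinMask(img)
  expect_equal(sm$mask, cbind(matrix(0, 8, 4), matrix(1, 8, 4)))
  expect_true(all(sm$segmented[, 1:4, ] == 0))           # I * M zeroes background
  expect_equal(sm$segmented[, 5:8, ], img[, 5:8, ])
  # masking is idempotent
  expect_equal(sm$segmented * array(rep(sm$mask, 3), dim = dim(img)),
               sm$segmented)
  # forced external threshold below the minimum keeps everything
  toy <- array(runif(48, 0.8, 0.9), dim = c(4, 4, 3))
  expect_true(all(skinMask(toy, threshold = 0.5)$mask == 1))
  expect_error(skinMask(array(0.5, dim = c(4, 4, 3))), "degenerate")
})

test_that("min-max normalisation maps endpoints and is idempotent", {
  out <- minmaxNormalize(array(c(10, 20, 30), dim = c(3, 1, 1)))
  expect_equal(as.numeric(out$pixels), c(0, 0.5, 1))
  expect_equal(out$i_min, 10); expect_equal(out$i_max, 30)

  img <- rand_img(5, 5, 3, seed = 6)
  once <- minmaxNormalize(img)$pixels
  expect_equal(minmaxNormalize(once)$pixels, once)
  already <- array(c(0, runif(10), 1), dim = c(12, 1, 1))
  expect_equal(minmaxNormalize(already)$pixels, already)

  cst <- minmaxNormalize(array(0.7, dim = c(3, 3, 1)))
  expect_true(cst$degenerate)
  expect_true(all(cst$pixels == 0))
})

test_that("augmentations implement the printed geometry", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]]
  r90 <- augmentImage(img, "rotate", angle = 90)
  expect_equal(r90[, , 1], matrix(c(2, 1, 4, 3), 2, 2))  # [[2,4],[1,3]]
  expect_equal(augmentImage(img, "rotate", angle = 0)[, , 1], img)

  x <- rand_img(6, 7, 3, seed = 8)
  expect_equal(augmentImage(augmentImage(x, "hflip"), "hflip"), x)
  expect_equal(augmentImage(augmentImage(x, "vflip"), "vflip"), x)
  cr <- augmentImage(x, "crop", window = c(1, 2, 3, 4))
  expect_equal(dim(cr), c(3L, 4L, 3L))
  expect_equal(cr, x[2:4, 3:6, , drop = FALSE])
  expect_error(augmentImage(x, "crop", window = c(4, 4, 4, 4)), "outside")

  br <- augmentImage(x, "brightness", factor = 3)
  expect_true(max(br) <= 1)
  expect_equal(br, pmin(pmax(x * 3, 0), 1))
  expect_error(augmentImage(x, "brightness", factor = -1), "> 0")
})

test_that("the preprocessing pipeline is deterministic and well-formed", {
  img <- rand_img(20, 20, 3, seed = 9) * 0.5 + 0.3
  img[3:12, 4:14, ] <- img[3:12, 4:14, ] + 0.4   # bright 'skin' region
  cfg <- preprocessConfig(target_size = c(16, 16))
  a <- preprocessImage(img, cfg)
  b <- preprocessImage(img, cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_equal(dim(a$pixels), c(16L, 16L, 3L))
  expect_true(min(a$pixels) >= 0 && max(a$pixels) <= 1)
  expect_length(a$steps, 4)
})
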