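grid_of <- function(H, W, p, s, seed = 1) {
  extractPatches(rand_img(H, W, 3, seed = seed), p, s)
}

test_that("map aggregation is the per-pixel max over covering patches", {
  g <- grid_of(32, 32, 32, 32)
  pm <- aggregateMap(g, 0.8)
  expect_true(all(mapValues(pm) == 0.8))

  g2 <- grid_of(48, 32, 32, 16)                # two vertically overlapping
  pm2 <- aggregateMap(g2, c(0.3, 0.7))
  expect_true(all(mapValues(pm2)[17:32, ] == 0.7))   # overlap takes the max
  expect_true(all(mapValues(pm2)[1:16, ] == 0.3))

  set.seed(2)
  g3 <- grid_of(64, 64, 32, 16, seed = 3)
  preds <- runif(nPatches(g3))
  pm3 <- aggregateMap(g3, preds)
  ref <- oracle_map(patchOrigins(g3), 32, preds, 64, 64)
  expect_equal(mapValues(pm3), ref$values)
  expect_equal(mapCoverage(pm3), ref$coverage)
})

test_that("uncovered pixels carry zero probability and zero coverage", {
  g <- grid_of(40, 40, 32, 32, seed = 4)
  pm <- aggregateMap(g, 0.9)
  expect_true(all(mapValues(pm)[33:40, ] == 0))
  expect_true(all(mapCoverage(pm)[, 33:40] == 0L))
  expect_error(aggregateMap(g, c(0.5, 0.5)), "expected 1")
})

test_that("raising one patch probability never lowers the map", {
  set.seed(5)
  g <- grid_of(64, 48, 32, 16, seed = 5)
  preds <- runif(nPatches(g))
  base <- mapValues(aggregateMap(g, preds))
  for (k in sample(nPatches(g), 3)) {
    up <- preds; up[k] <- min(1, up[k] + 0.3)
    expect_true(all(mapValues(aggregateMap(g, up)) >= base - 1e-12))
  }
})

test_that("thresholding keeps exactly the pixels at or above T and nests", {
  g <- grid_of(64, 64, 32, 32, seed = 6)
  pm <- aggregateMap(g, c(0.2, 0.6, 0.9, 0.4))
  th <- thresholdRegions(pm, 0.5)
  expect_setequal(unique(th$values), c(0.6, 0.9))
  expect_equal(sum(th$mask), 2 * 32 * 32)
  expect_equal(sum(thresholdRegions(pm, 0)$mask), 64 * 64)  # all covered pixels
  expect_equal(sum(thresholdRegions(pm, 1)$mask), 0)
  for (t1 in c(0, 0.3, 0.7)) {
    m1 <- thresholdRegions(pm, t1)$mask
    m2 <- thresholdRegions(pm, min(t1 + 0.2, 1))$mask
    expect_true(all(m1[m2]))                     # T1 <= T2 => R(T2) subset R(T1)
  }
  expect_error(thresholdRegions(pm, 1.2), "threshold")
})

test_that("top regions rank disjoint windows by mean with stable ties", {
  vals <- matrix(0.1, 64, 64)
  vals[33:64, 1:32] <- 0.9
  pm <- methods::new("ProbMap", values = vals,
                     coverage = matrix(1L, 64, 64), stride = 32L)
  top1 <- topRegions(pm, n = 1)
  expect_equal(patchOrigins(top1)[1, ], c(row = 32L, col = 0L))
  expect_equal(regionMeans(top1), 0.9)

  all4 <- topRegions(pm, n = 99)
  expect_length(regionMeans(all4), 4)
  expect_true(!is.unsorted(-regionMeans(all4)))
  # ties broken by (row, col) ascending
  expect_equal(patchOrigins(all4)[2, ], c(row = 0L, col = 0L))

  set.seed(7)
  rvals <- matrix(runif(128 * 128), 128, 128)
  pmr <- methods::new("ProbMap", values = rvals,
                      coverage = matrix(1L, 128, 128), stride = 32L)
  got <- topRegions(pmr, n = 3)
  means <- sapply(seq(0, 96, 32), function(r) sapply(seq(0, 96, 32), function(c)
    mean(rvals[r + 1:32, c + 1:32])))
  expect_equal(regionMeans(got), sort(as.numeric(means), decreasing = TRUE)[1:3])

  expect_equal(length(regionMeans(topRegions(pmr, n = 5, threshold = 0.9))), 0)
  expect_error(topRegions(pm, n = 1, windowSize = 128), "smaller")
})

test_that("region tensors are column-mean profiles with zero padding", {
  win <- matrix(0.5, 32, 32)
  rs <- methods::new("RiskRegionSet", origins = matrix(0L, 1, 2),
                     means = 0.5, values = list(win), windowSize = 32L)
  tens <- regionsToTensor(rs, n_slots = 8)
  expect_equal(dim(tensorData(tens)), c(8L, 1L, 32L))
  expect_true(all(tensorData(tens)[1, 1, ] == 0.5))
  expect_true(all(tensorData(tens)[2:8, , ] == 0))   # padded rows
  expect_equal(tens@nRegions, 1L)

  ramp <- matrix(rep((0:31) / 31, each = 32), 32, 32)
  rs2 <- methods::new("RiskRegionSet", origins = matrix(0L, 1, 2),
                      means = mean(ramp), values = list(ramp), windowSize = 32L)
  expect_equal(as.numeric(tensorData(regionsToTensor(rs2))[1, 1, ]), (0:31) / 31)

  set.seed(8)
  rwin <- matrix(runif(1024), 32, 32)
  rs3 <- methods::new("RiskRegionSet", origins = matrix(0L, 1, 2),
                      means = mean(rwin), values = list(rwin), windowSize = 32L)
  direct <- sapply(1:32, function(j) sum(rwin[, j]) / 32)
  expect_lt(max(abs(tensorData(regionsToTensor(rs3))[1, 1, ] - direct)), 1e-12)

  flat <- regionsToTensor(rs3, n_slots = 2, reduce = "flat")
  expect_equal(dim(tensorData(flat))[3], 1024L)
  expect_equal(as.numeric(tensorData(flat)[1, 1, ]), as.numeric(t(rwin)))
})

test_that("overlay rendering blends and round-trips through PNG", {
  dir <- withr::local_tempdir()
  img <- rand_img(32, 32, 3, seed = 9)
  g <- extractPatches(img, 32, 32)
  pm0 <- aggregateMap(g, 0)
  expect_equal(renderOverlay(pm0, img), img)
  pm1 <- aggregateMap(g, 1)
  ov <- renderOverlay(pm1, img, file.path(dir, "ov.png"), alpha = 0.6)
  expect_equal(ov[, , 1], 0.4 * img[, , 1] + 0.6)
  back <- png::readPNG(file.path(dir, "ov.png"))
  expect_equal(dim(back), dim(img))
  expect_error(renderOverlay(pm1, rand_img(16, 16)), "mismatch")
})
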