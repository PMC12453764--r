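test_that("stratified label assignment hits the prevalence exactly", {
  co <- generateCohort(synthConfig(n_images = 10, prevalence = 0.5, seed = 1))
  expect_equal(sum(cohortLabels(co) == 1L), 5L)
  expect_equal(sum(cohortLabels(co) == 0L), 5L)
  co2 <- generateCohort(synthConfig(n_images = 30, prevalence = 0.3, seed = 9))
  expect_equal(sum(cohortLabels(co2)), 9L)
  expect_true(abs(mean(cohortLabels(co2)) - 0.3) <= 1 / 30)
})

test_that("identical config and seed reproduce the cohort bit-identically", {
  cfg <- synthConfig(n_images = 8, seed = 123)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("cohort structure honours its invariants", {
  co <- generateCohort(synthConfig(n_images = 12, seed = 4))
  for (i in seq_len(nSamples(co))) {
    img <- co@images[[i]]
    expect_true(min(img) >= 0 && max(img) <= 1)
    if (cohortLabels(co)[i] == 0L) expect_true(all(co@masks[[i]] == 0))
    else expect_gt(sum(co@masks[[i]]), 0)
  }
  expect_setequal(colnames(cohortClinical(co)),
                  c("image", "age", "symptom_duration", "gender", "skin_type",
                    "history_flag", "label"))
  expect_true(all(cohortClinical(co)$age >= 18 & cohortClinical(co)$age <= 90))
  expect_true(all(cohortClinical(co)$skin_type %in% c("I","II","III","IV","V","VI")))
})

test_that("zero intensity shift with equal noise leaves lesions undetectable", {
  co <- generateCohort(synthConfig(n_images = 60, lesion_intensity_shift = 0,
                                   lesion_noise_sd = 0.05,
                                   background_noise_sd = 0.05, seed = 7))
  inside <- c(); outside <- c()
  for (i in which(cohortLabels(co) == 1L)) {
    m <- co@masks[[i]] == 1
    for (ch in 1:3) {
      pl <- co@images[[i]][, , ch]
      inside <- c(inside, mean(pl[m]))
      outside <- c(outside, mean(pl[!m]))
    }
  }
  d <- inside - outside
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 2 * se + 1e-3)
})

test_that("patch-level discriminability is monotone in the intensity shift", {
  aucs <- sapply(c(0, 0.1, 0.2, 0.3), function(shift) {
    co <- generateCohort(synthConfig(n_images = 40,
                                     lesion_intensity_shift = shift,
                                     lesion_noise_sd = 0.05,
                                     background_noise_sd = 0.05, seed = 11))
    scores <- c(); labs <- c()
    for (i in seq_len(nSamples(co))) {
      grid <- extractPatches(co@images[[i]], 32, 16)
      pl <- labelPatches(grid, co@masks[[i]])
      px <- patchPixels(grid)
      scores <- c(scores, apply(px, 4, mean))
      labs <- c(labs, pl)
    }
    metricValues(computeMetrics(labs, labs, scores))["auc"]
  })
  expect_true(all(diff(aucs) >= -0.02))   # non-decreasing up to seed noise
  expect_gt(aucs[4], 0.95)                # strong shift is near-separable
})

test_that("null clinical effect leaves symptom duration uninformative", {
  co <- generateCohort(synthConfig(n_images = 200, clinical_effect_beta = 0,
                                   seed = 5))
  x <- cohortClinical(co)$symptom_duration
  y <- cohortLabels(co)
  d <- mean(x[y == 1]) - mean(x[y == 0])
  se <- sqrt(var(x[y == 1]) / sum(y == 1) + var(x[y == 0]) / sum(y == 0))
  expect_lt(abs(d), 2 * se)
})

test_that("positive clinical effect separates the latent covariate", {
  co <- generateCohort(synthConfig(n_images = 300, clinical_effect_beta = 3,
                                   seed = 6))
  x <- cohortClinical(co)$symptom_duration
  y <- cohortLabels(co)
  auc <- metricValues(computeMetrics(y, y, x))["auc"]
  # Bayes AUC for N(+-beta/2, 1) latents is pnorm(beta/sqrt(2)) ~ 0.983
  expect_gt(auc, 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(n_images = 0), "positive")
  expect_error(synthConfig(prevalence = 1.5), "prevalence")
  expect_error(synthConfig(image_size = c(32, 32),
                           lesion_axes_range = c(10, 40)), "fit")
  expect_error(synthConfig(background_noise_sd = -1), ">= 0")
})

test_that("write/read round-trips a cohort through PNG and CSV", {
  dir <- withr::local_tempdir()
  co <- generateCohort(synthConfig(n_images = 3, prevalence = 2 / 3, seed = 2))
  man <- writeCohort(co, dir)
  expect_length(man$images, 3)
  expect_length(man$masks, 3)
  expect_true(all(file.exists(unlist(man[c("images", "masks", "clinical")]))))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- readCohort(dir)
  expect_identical(cohortLabels(back), cohortLabels(co))
  expect_identical(back@clinical$gender, co@clinical$gender)
  for (i in 1:3) {
    expect_lt(max(abs(back@images[[i]] - co@images[[i]])), 1 / 255 + 1e-9)
    expect_identical(back@masks[[i]] == 1, co@masks[[i]] == 1)
  }
})

test_that("an empty cohort writes a header-only CSV", {
  dir <- withr::local_tempdir()
  co <- generateCohort(synthConfig(n_images = 2, seed = 3))
  empty <- methods::new("SynthCohort", images = list(), masks = list(),
                        clinical = cohortClinical(co)[0, , drop = FALSE],
                        labels = integer(0), config = list())
  writeCohort(empty, dir)
  tab <- utils::read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(tab), 0L)
  expect_true("symptom_duration" %in% colnames(tab))
})
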