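# dermapatch

Patch-based residual networks and multimodal fusion for binary skin-disease
detection from RGB images and clinical metadata.

## What it does, and for whom

Whole-image CNN classifiers pool away the local evidence (lesion borders,
pigmentation, texture irregularity) that drives dermatological diagnosis,
and most ignore the patient's clinical context entirely. `dermapatch` is an
R implementation of a hybrid framework for researchers studying
interpretable, multimodal lesion classification:

1. **Patch-level FCRN.** Images are preprocessed (resampling, adaptive
   non-local-means denoising, Otsu skin masking, min–max normalisation) and
   tiled into 32×32 patches. A fully convolutional residual network — a
   64-filter 3×3 stem, two width-64 residual blocks
   `ReLU(BN(W₂·ReLU(BN(W₁·x))) + x)` around a 2×2 max-pool, a 128-filter
   3×3 convolution, global average pooling and a 1×1 two-class head —
   assigns each patch a diseased probability
   `P(c|x) = exp(z_c) / Σ_j exp(z_j)`.
2. **Disease probability maps.** Patch probabilities are max-aggregated
   into a per-pixel surface `M(x,y) = max_k P_k(x,y)` that localises risk;
   thresholded regions `R = {M ≥ T}` make the model's attention auditable.
3. **Multimodal fusion.** The top-N high-risk 32×32 windows are reduced to
   an (N, 1, 32) tensor, passed through a 1-D convolutional branch
   (16 then 32 kernels, batch norm, ReLU), pooled to a 32-vector, and
   concatenated with the clinical vector `C_f` (z-scored continuous
   covariates, one-hot categoricals). Dense layers (128, 64, leaky-ReLU,
   dropout 0.1) produce the final classification — image evidence and
   patient context in one decision.

A seeded synthetic-cohort generator (textured elliptical lesions with
pixel-level masks, plus clinical covariates with an exactly controlled
log-odds effect size) makes every stage testable without external data, and
an evaluation harness provides stratified 70/15/15 splits, 5-fold CV,
confusion-matrix metrics, rank-based AUC and a 243-cell hyperparameter grid
search.

The networks are implemented from scratch in R (im2col + BLAS matrix
products with C++ kernels for the memory-bound steps), double precision,
with finite-difference-verified gradients — a reference implementation
built for correctness and auditability on a single CPU.

## Worked example

```r
library(dermapatch)

# a 60-image synthetic cohort: 64x64 images, bright textured lesions,
# clinical effect beta = 2 on symptom duration
cohort <- generateCohort(synthConfig(n_images = 60, image_size = c(64, 64),
                                     lesion_intensity_shift = 0.3,
                                     clinical_effect_beta = 2, seed = 7))
cohort
#> SynthCohort: 60 images (64x64), 30 diseased / 30 healthy
#>   clinical columns: image, age, symptom_duration, gender, skin_type, history_flag, label

# train the patch classifier on mask-labelled patches
split <- stratifiedSplit(cohortLabels(cohort), seed = 7)
patches <- collectPatches(cohort, split$train, 32L, 16L)
fcrn <- trainFcrn(patches$pixels, patches$labels, fcrnSpec(),
                  epochs = 2, seed = 7)

# probability map and high-risk regions for one diseased image
i <- which(cohortLabels(cohort) == 1)[1]
grid <- extractPatches(cohort@images[[i]], p = 32, stride = 16)
pred <- fcrnForward(patchPixels(grid), fcrn)
pmap <- aggregateMap(grid, pred$probs[2, ])
pmap
#> ProbMap: 64x64, values in [0.000, 1.000], 0 uncovered pixels
regions <- topRegions(pmap, n = 8, windowSize = 32)

# fuse with encoded clinical covariates and classify the image
enc <- fitClinicalEncoder(cohortClinical(cohort)[split$train, ])
tensors <- cohortRegionTensors(cohort, fcrn)
cvec <- transformClinical(cohortClinical(cohort), enc)
fusion <- trainFusion(tensors[split$train, , ], cvec[split$train, ],
                      cohortLabels(cohort)[split$train], epochs = 10, seed = 7)
round(predictImage(cohort@images[[i]], cohortClinical(cohort)[i, ], fcrn,
                   fusion, encoder = enc)$probs, 4)
#>  healthy diseased
#>   0.0069   0.9931
```

The map values are per-pixel diseased probabilities: on this diseased image
the lesion footprint lights up near 1 while background patches sit at 0
(the same model maps a healthy image to 0 everywhere), and the fused
classifier combines that spatial evidence with the patient's covariates —
here calling the image diseased at probability 0.993.

A command-line wrapper covering the same stages (simulate, preprocess,
patch, train-fcrn, probmap, encode-clinical, train-fusion, predict,
evaluate, grid-search) is installed at `inst/cli/dermapatch.R`:

```sh
Rscript inst/cli/dermapatch.R simulate --n 60 --seed 7 --out cohort/
Rscript inst/cli/dermapatch.R --help
```

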