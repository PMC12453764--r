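#' Configuration for the synthetic skin-image generator
#'
#' Defines a synthetic cohort: RGB images over a skin-toned background, with
#' one textured elliptical lesion per diseased image, pixel-level lesion
#' masks, and a clinical table whose informative covariate (symptom duration)
#' carries a configurable log-odds association with the label.
#'
#' The lesion is brighter than the surrounding skin by
#' \code{lesion_intensity_shift} (added to all three channels, clipped to
#' \code{[0,1]}) and rougher in texture (\code{lesion_noise_sd} against
#' \code{background_noise_sd}). The informative clinical covariate is
#' generated from a latent standard-normal score z with label-conditional
#' means at +/- \code{clinical_effect_beta}/2, so that the Bayes log-odds of
#' disease given z is \code{clinical_effect_beta * z} (plus the prevalence
#' offset); z is mapped monotonically onto a day scale with marginal mean 30.
#'
#' @param n_images number of images to generate.
#' @param image_size integer (rows, cols); default c(64, 64).
#' @param prevalence diseased fraction in \code{[0,1]}; assigned
#'   deterministically as \code{round(prevalence * n_images)} diseased images.
#' @param lesion_axes_range numeric (min, max) lesion semi-axes in pixels.
#'   Default \code{NULL} uses 25--40\% of the smaller image dimension,
#'   emulating close-up photographs where the lesion dominates the frame.
#' @param lesion_intensity_shift mean RGB offset of lesion over background.
#' @param lesion_noise_sd pixel noise sd inside the lesion (texture).
#' @param background_noise_sd pixel noise sd outside the lesion.
#' @param clinical_effect_beta log-odds coefficient of the latent clinical
#'   score; 0 makes the covariate uninformative.
#' @param seed integer RNG seed; identical (config, seed) reproduces the
#'   cohort bit-identically.
#' @return a validated config list of class \code{synthConfig}.
#' @export
synthConfig <- function(n_images = 100L, image_size = c(64L, 64L),
                        prevalence = 0.5, lesion_axes_range = NULL,
                        lesion_intensity_shift = 0.2, lesion_noise_sd = 0.10,
                        background_noise_sd = 0.05, clinical_effect_beta = 1.0,
                        seed = 1L) {
  if (length(n_images) != 1L || !is.finite(n_images) || n_images < 1)
    stop("n_images must be a positive count")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 1L))
    stop("image_size must be two positive integers")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must lie in [0,1]")
  if (lesion_noise_sd < 0 || background_noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (is.null(lesion_axes_range))
    lesion_axes_range <- round(c(0.25, 0.40) * min(image_size))
  if (length(lesion_axes_range) != 2L || lesion_axes_range[1] > lesion_axes_range[2] ||
      lesion_axes_range[1] < 1)
    stop("lesion_axes_range must be (min, max) semi-axes >= 1")
  if (2 * lesion_axes_range[2] >= min(image_size))
    stop(sprintf("lesion too large for image: semi-axis %g does not fit in %dx%d",
                 lesion_axes_range[2], image_size[1], image_size[2]))
  structure(list(
    n_images = as.integer(n_images), image_size = image_size,
    prevalence = prevalence, lesion_axes_range = as.numeric(lesion_axes_range),
    lesion_intensity_shift = lesion_intensity_shift,
    lesion_noise_sd = lesion_noise_sd, background_noise_sd = background_noise_sd,
    clinical_effect_beta = clinical_effect_beta, seed = as.integer(seed)),
    class = "synthConfig")
}

# Skin-toned background base colour (RGB in [0,1]).
.skin_base <- c(0.80, 0.62, 0.52)

#' Generate a synthetic cohort
#'
#' Draws \code{n_images} samples under a \code{\link{synthConfig}}. Labels are
#' assigned by deterministic stratified allocation (exactly
#' \code{round(prevalence * n)} diseased, order shuffled under the seed).
#' Diseased images receive one axis-aligned ellipse of shifted mean intensity
#' and higher texture noise; its pixel mask is recorded. Clinical covariates:
#' age ~ Normal(50, 15) truncated to [18, 90]; symptom duration mapped from a
#' label-conditional latent normal (see \code{\link{synthConfig}}); gender in
#' \{F, M\}; Fitzpatrick skin type I--VI; binary history flag.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return a \linkS4class{SynthCohort}.
#' @examples
#' cohort <- generateCohort(synthConfig(n_images = 10, seed = 1))
#' table(cohortLabels(cohort))
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "synthConfig")) config <- do.call(synthConfig, config)
  set.seed(config$seed)
  n <- config$n_images
  H <- config$image_size[1]; W <- config$image_size[2]

  n_dis <- as.integer(round(config$prevalence * n))
  labels <- c(rep(1L, n_dis), rep(0L, n - n_dis))
  labels <- labels[sample.int(n)]

  images <- vector("list", n)
  masks <- vector("list", n)
  rr <- matrix(rep(seq_len(H) - 1, W), H, W)
  cc <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  for (i in seq_len(n)) {
    img <- array(rep(.skin_base, each = H * W), dim = c(H, W, 3)) +
      array(stats::rnorm(H * W * 3, 0, config$background_noise_sd), dim = c(H, W, 3))
    mask <- matrix(0, H, W)
    if (labels[i] == 1L) {
      ax <- stats::runif(2, config$lesion_axes_range[1], config$lesion_axes_range[2])
      ctr <- c(stats::runif(1, ax[1], H - 1 - ax[1]),
               stats::runif(1, ax[2], W - 1 - ax[2]))
      inside <- ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
      mask[inside] <- 1
      n_in <- sum(inside)
      extra_sd <- sqrt(max(config$lesion_noise_sd^2 - config$background_noise_sd^2, 0))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- plane[inside] + config$lesion_intensity_shift +
          stats::rnorm(n_in, 0, extra_sd)
        img[, , ch] <- plane
      }
    }
    images[[i]] <- pmin(pmax(img, 0), 1)
    masks[[i]] <- mask
  }

  beta <- config$clinical_effect_beta
  z <- stats::rnorm(n, mean = (labels - 0.5) * beta, sd = 1)
  clinical <- data.frame(
    image = sprintf("img_%04d.png", seq_len(n)),
    age = pmin(pmax(round(stats::rnorm(n, 50, 15), 1), 18), 90),
    symptom_duration = round(stats::qexp(stats::pnorm(z), rate = 1 / 30), 2),
    gender = sample(c("F", "M"), n, replace = TRUE),
    skin_type = sample(c("I", "II", "III", "IV", "V", "VI"), n, replace = TRUE),
    history_flag = stats::rbinom(n, 1, 0.3),
    label = labels,
    stringsAsFactors = FALSE)

  methods::new("SynthCohort", images = images, masks = masks,
               clinical = clinical, labels = labels,
               config = unclass(config))
}

#' Write a cohort to disk
#'
#' Writes 8-bit RGB PNG images under \code{images/}, 8-bit grayscale mask
#' PNGs (values 0/255) under \code{masks/}, one clinical/label CSV keyed by
#' image filename, and a JSON manifest listing all paths. Reading the cohort
#' back reproduces the images within 8-bit quantisation (1/255 per channel).
#'
#' @param cohort a \linkS4class{SynthCohort}.
#' @param directory output directory (created if missing).
#' @return invisibly, the manifest list (paths of images, masks, csv).
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "SynthCohort"))
  dir.create(file.path(directory, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create output directory '%s'", directory))
  n <- nSamples(cohort)
  img_paths <- character(n); mask_paths <- character(n)
  for (i in seq_len(n)) {
    nm <- cohort@clinical$image[i]
    img_paths[i] <- file.path(directory, "images", nm)
    mask_paths[i] <- file.path(directory, "masks", nm)
    ok <- try({
      png::writePNG(cohort@images[[i]], target = img_paths[i])
      png::writePNG(cohort@masks[[i]], target = mask_paths[i])
    }, silent = TRUE)
    if (inherits(ok, "try-error"))
      stop(sprintf("failed writing '%s': %s", img_paths[i], as.character(ok)))
  }
  csv_path <- file.path(directory, "clinical.csv")
  utils::write.csv(cohort@clinical, csv_path, row.names = FALSE)
  manifest <- list(n_images = n, images = img_paths, masks = mask_paths,
                   clinical = csv_path)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param directory directory holding \code{images/}, \code{masks/},
#'   \code{clinical.csv}.
#' @return a \linkS4class{SynthCohort} (config slot holds only the source
#'   directory).
#' @export
readCohort <- function(directory) {
  csv_path <- file.path(directory, "clinical.csv")
  if (!file.exists(csv_path))
    stop(sprintf("no clinical.csv under '%s'", directory))
  clinical <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  n <- nrow(clinical)
  images <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- png::readPNG(file.path(directory, "images", clinical$image[i]))
    m <- png::readPNG(file.path(directory, "masks", clinical$image[i]))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    masks[[i]] <- (m > 0.5) + 0
  }
  methods::new("SynthCohort", images = images, masks = masks,
               clinical = clinical, labels = as.integer(clinical$label),
               config = list(source = directory))
}
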