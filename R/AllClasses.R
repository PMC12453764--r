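#' @import methods
NULL

#' Synthetic skin-image cohort
#'
#' Container for a generated cohort: RGB images in \code{[0,1]}, pixel-level
#' lesion masks, a clinical table and binary image labels (0 = healthy,
#' 1 = diseased). Produced by \code{\link{generateCohort}}.
#'
#' @slot images list of H x W x 3 numeric arrays in \code{[0,1]}.
#' @slot masks list of H x W binary (0/1) matrices; all-zero for healthy images.
#' @slot clinical data.frame with one row per image.
#' @slot labels integer vector of 0/1 image labels.
#' @slot config the \code{\link{synthConfig}} list used for generation.
#' @export
setClass("SynthCohort",
  representation(images = "list", masks = "list", clinical = "data.frame",
                 labels = "integer", config = "list"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@masks) != n || length(object@labels) != n ||
        nrow(object@clinical) != n)
      return("images, masks, clinical rows and labels must have equal length")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must be 0 (healthy) or 1 (diseased)")
    for (i in seq_len(min(n, 3L))) {
      img <- object@images[[i]]
      if (length(dim(img)) != 3L || dim(img)[3] != 3L)
        return("images must be H x W x 3 arrays")
      if (min(img) < 0 || max(img) > 1)
        return("image values must lie in [0,1]")
      m <- object@masks[[i]]
      if (object@labels[i] == 0L && any(m != 0))
        return("healthy images must have all-zero masks")
      if (object@labels[i] == 1L && !any(m != 0))
        return("diseased images must have a non-empty lesion mask")
    }
    TRUE
  })

#' Grid of image patches
#'
#' Ordered p x p x 3 tiles cut from one image at a fixed stride, with their
#' 0-based top-left origins. When \code{stride == patchSize} the tiling is
#' disjoint and the patch count equals \code{floor(H/p) * floor(W/p)}.
#'
#' @slot pixels numeric array \code{[p, p, C, N]} holding the patches.
#' @slot origins integer matrix \code{N x 2} of 0-based (row, col) origins,
#'   row-major ordered.
#' @slot patchSize integer patch side p.
#' @slot stride integer stride s.
#' @slot imageDim integer length-2 source image dimensions (H, W).
#' @export
setClass("PatchGrid",
  representation(pixels = "array", origins = "matrix", patchSize = "integer",
                 stride = "integer", imageDim = "integer"),
  validity = function(object) {
    p <- object@patchSize
    d <- dim(object@pixels)
    if (length(d) != 4L || d[1] != p || d[2] != p)
      return("pixels must be a [p, p, C, N] array")
    if (nrow(object@origins) != d[4])
      return("one origin per patch required")
    if (any(object@origins < 0L))
      return("origins are 0-based and non-negative")
    if (any(object@origins[, 1] + p > object@imageDim[1]) ||
        any(object@origins[, 2] + p > object@imageDim[2]))
      return("patches must lie inside the source image")
    if (anyDuplicated(object@origins))
      return("patch origins must be unique")
    TRUE
  })

#' Per-pixel disease probability map
#'
#' Max-aggregated diseased-class probability surface over an image, together
#' with the per-pixel patch coverage counts. Pixels covered by no patch carry
#' probability 0 and coverage 0.
#'
#' @slot values numeric H x W matrix in \code{[0,1]}.
#' @slot coverage integer H x W matrix of patch counts per pixel.
#' @slot stride integer stride of the grid the map was aggregated from.
#' @export
setClass("ProbMap",
  representation(values = "matrix", coverage = "matrix", stride = "integer"),
  validity = function(object) {
    if (!identical(dim(object@values), dim(object@coverage)))
      return("values and coverage must share dimensions")
    if (min(object@values) < 0 || max(object@values) > 1)
      return("map values must lie in [0,1]")
    if (any(object@values[object@coverage == 0L] != 0))
      return("uncovered pixels must have value 0")
    TRUE
  })

#' High-risk regions of a probability map
#'
#' Fixed-size windows of a \linkS4class{ProbMap} ranked by mean intensity
#' (descending, ties broken by ascending row then column origin).
#'
#' @slot origins integer N x 2 matrix of 0-based window origins.
#' @slot means numeric vector of window mean intensities, non-increasing.
#' @slot values list of windowSize x windowSize sub-map matrices.
#' @slot windowSize integer window side (32 by default).
#' @export
setClass("RiskRegionSet",
  representation(origins = "matrix", means = "numeric", values = "list",
                 windowSize = "integer"),
  validity = function(object) {
    if (length(object@means) != nrow(object@origins) ||
        length(object@values) != length(object@means))
      return("origins, means and values must align")
    if (is.unsorted(-object@means))
      return("means must be non-increasing")
    for (i in seq_along(object@values)) {
      if (abs(mean(object@values[[i]]) - object@means[i]) > 1e-12)
        return("stored means must equal window means")
    }
    TRUE
  })

#' Fusion input tensor of reduced high-risk regions
#'
#' Each 32 x 32 high-risk region is reduced column-wise to a length-32
#' profile; profiles are stacked into an (N, 1, 32) tensor, zero-padded when
#' fewer than N regions were available.
#'
#' @slot data numeric array of shape (N, 1, 32) with values in \code{[0,1]}.
#' @slot nRegions integer count of non-padded rows.
#' @export
setClass("RegionTensor",
  representation(data = "array", nRegions = "integer"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L || d[2] != 1L)
      return("data must have shape (N, 1, L)")
    if (min(object@data) < 0 || max(object@data) > 1)
      return("region tensor values must lie in [0,1]")
    if (object@nRegions > d[1])
      return("nRegions cannot exceed tensor rows")
    TRUE
  })

#' Fitted clinical feature encoder
#'
#' Stores per-feature standardisation and one-hot state fitted on a training
#' table: mean/sd/median for continuous features (population sd convention)
#' and sorted category vocabularies for categorical features. The fitted
#' layout fixes the output vector dimension.
#'
#' @slot continuous named list; each element has \code{mean}, \code{sd},
#'   \code{median}.
#' @slot categorical named list of character vocabularies (sorted, with a
#'   trailing \code{"missing"} level when NAs were seen or allowed).
#' @slot dropped character names of constant continuous columns removed at fit.
#' @slot featureNames character vector: the output column layout.
#' @export
setClass("ClinicalEncoder",
  representation(continuous = "list", categorical = "list",
                 dropped = "character", featureNames = "character"),
  validity = function(object) {
    for (nm in names(object@continuous)) {
      el <- object@continuous[[nm]]
      if (!is.finite(el$sd) || el$sd <= 0)
        return(sprintf("retained continuous feature '%s' must have sd > 0", nm))
    }
    for (nm in names(object@categorical)) {
      v <- object@categorical[[nm]]
      if (length(v) == 0L || anyDuplicated(v))
        return(sprintf("vocabulary of '%s' must be non-empty and duplicate-free", nm))
    }
    TRUE
  })

#' Trained patch-level FCRN
#'
#' Architecture specification, parameters and training history of the fully
#' convolutional residual network. See \code{\link{fcrnSpec}} and
#' \code{\link{trainFcrn}}.
#'
#' @slot spec list from \code{\link{fcrnSpec}}.
#' @slot params list of layer parameter tensors (kernels, biases, batch-norm
#'   state).
#' @slot history data.frame of per-epoch train/validation loss and accuracy.
#' @export
setClass("FcrnModel",
  representation(spec = "list", params = "list", history = "data.frame"))

#' Trained multimodal fusion network
#'
#' @slot spec list from \code{\link{fusionSpec}}.
#' @slot params list of parameter tensors.
#' @slot history data.frame of per-epoch train/validation loss and accuracy.
#' @export
setClass("FusionModel",
  representation(spec = "list", params = "list", history = "data.frame"))

#' Classification metrics report
#'
#' Confusion-matrix counts and derived metrics for a binary classifier, plus
#' ROC points swept over unique score thresholds. Undefined ratios (zero
#' denominators) are reported as NA, never silently as 0.
#'
#' @slot counts named integer vector (TP, FP, TN, FN).
#' @slot metrics named numeric vector (accuracy, sensitivity, specificity,
#'   precision, f1, auc); NA where undefined.
#' @slot roc data.frame with columns threshold, fpr, tpr.
#' @export
setClass("MetricsReport",
  representation(counts = "integer", metrics = "numeric", roc = "data.frame"),
  validity = function(object) {
    if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
      return("counts must name TP, FP, TN, FN")
    if (any(object@counts < 0L)) return("counts must be non-negative")
    ok <- object@metrics[!is.na(object@metrics)]
    if (length(ok) && (min(ok) < 0 || max(ok) > 1))
      return("metrics must lie in [0,1]")
    TRUE
  })
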