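# Accessors and show() methods for the S4 containers.

#' @rdname nSamples
#' @export
setMethod("nSamples", "SynthCohort", function(x) length(x@images))

#' @rdname nSamples
#' @export
setMethod("nPatches", "PatchGrid", function(x) dim(x@pixels)[4])

#' @rdname cohortLabels
#' @export
setMethod("cohortLabels", "SynthCohort", function(x) x@labels)

#' @rdname cohortClinical
#' @export
setMethod("cohortClinical", "SynthCohort", function(x) x@clinical)

#' @rdname patchPixels
#' @export
setMethod("patchPixels", "PatchGrid", function(x) x@pixels)

#' @rdname patchOrigins
#' @export
setMethod("patchOrigins", "PatchGrid", function(x) x@origins)

#' @rdname patchOrigins
#' @export
setMethod("patchOrigins", "RiskRegionSet", function(x) x@origins)

#' @rdname mapValues
#' @export
setMethod("mapValues", "ProbMap", function(x) x@values)

#' @rdname mapCoverage
#' @export
setMethod("mapCoverage", "ProbMap", function(x) x@coverage)

#' @rdname regionMeans
#' @export
setMethod("regionMeans", "RiskRegionSet", function(x) x@means)

#' @rdname tensorData
#' @export
setMethod("tensorData", "RegionTensor", function(x) x@data)

#' @rdname featureNames
#' @export
setMethod("featureNames", "ClinicalEncoder", function(x) x@featureNames)

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "FcrnModel", function(x) x@history)

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "FusionModel", function(x) x@history)

#' @rdname metricValues
#' @export
setMethod("metricValues", "MetricsReport", function(x) x@metrics)

#' @rdname confusionCounts
#' @export
setMethod("confusionCounts", "MetricsReport", function(x) x@counts)

#' @rdname rocPoints
#' @export
setMethod("rocPoints", "MetricsReport", function(x) x@roc)

setMethod("show", "SynthCohort", function(object) {
  d <- dim(object@images[[1]])
  cat(sprintf("SynthCohort: %d images (%dx%d), %d diseased / %d healthy\n",
              length(object@images), d[1], d[2],
              sum(object@labels == 1L), sum(object@labels == 0L)))
  cat(sprintf("  clinical columns: %s\n",
              paste(colnames(object@clinical), collapse = ", ")))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %dx%d, stride %d, from %dx%d image\n",
              dim(object@pixels)[4], object@patchSize, object@patchSize,
              object@stride, object@imageDim[1], object@imageDim[2]))
})

setMethod("show", "ProbMap", function(object) {
  cat(sprintf("ProbMap: %dx%d, values in [%.3f, %.3f], %d uncovered pixels\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values),
              sum(object@coverage == 0L)))
})

setMethod("show", "RiskRegionSet", function(object) {
  cat(sprintf("RiskRegionSet: %d windows of %dx%d, mean intensity %.3f..%.3f\n",
              length(object@means), object@windowSize, object@windowSize,
              if (length(object@means)) max(object@means) else NA,
              if (length(object@means)) min(object@means) else NA))
})

setMethod("show", "RegionTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("RegionTensor: shape (%d, %d, %d), %d non-padded rows\n",
              d[1], d[2], d[3], object@nRegions))
})

setMethod("show", "ClinicalEncoder", function(object) {
  cat(sprintf("ClinicalEncoder: %d continuous, %d categorical -> %d features\n",
              length(object@continuous), length(object@categorical),
              length(object@featureNames)))
  if (length(object@dropped))
    cat(sprintf("  dropped constant columns: %s\n",
                paste(object@dropped, collapse = ", ")))
})

setMethod("show", "FcrnModel", function(object) {
  cat(sprintf("FcrnModel: %d/%d filters, %d residual blocks, %d epochs trained\n",
              object@spec$width, object@spec$width2, 2L, nrow(object@history)))
})

setMethod("show", "FusionModel", function(object) {
  cat(sprintf("FusionModel: %s branch, clinical dim %d, %d epochs trained\n",
              object@spec$branch, object@spec$dClinical, nrow(object@history)))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n  counts:",
      paste(sprintf("%s=%d", names(object@counts), object@counts), collapse = " "),
      "\n  metrics:",
      paste(sprintf("%s=%.4f", names(object@metrics), object@metrics), collapse = " "),
      "\n")
})
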