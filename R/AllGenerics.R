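#' Number of samples or patches in a container
#'
#' @param x a \linkS4class{SynthCohort}, \linkS4class{PatchGrid} or
#'   \linkS4class{RiskRegionSet}.
#' @return integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' Access image labels
#' @param x a \linkS4class{SynthCohort}.
#' @return integer 0/1 vector.
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' Access the clinical table of a cohort
#' @param x a \linkS4class{SynthCohort}.
#' @return data.frame.
#' @export
setGeneric("cohortClinical", function(x) standardGeneric("cohortClinical"))

#' Access patch pixel data
#' @param x a \linkS4class{PatchGrid}.
#' @return numeric array \code{[p, p, C, N]}.
#' @export
setGeneric("patchPixels", function(x) standardGeneric("patchPixels"))

#' Access 0-based patch origins
#' @param x a \linkS4class{PatchGrid} or \linkS4class{RiskRegionSet}.
#' @return integer matrix N x 2.
#' @export
setGeneric("patchOrigins", function(x) standardGeneric("patchOrigins"))

#' Access probability-map values
#' @param x a \linkS4class{ProbMap}.
#' @return numeric matrix.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Access probability-map coverage counts
#' @param x a \linkS4class{ProbMap}.
#' @return integer matrix.
#' @export
setGeneric("mapCoverage", function(x) standardGeneric("mapCoverage"))

#' Access region mean intensities
#' @param x a \linkS4class{RiskRegionSet}.
#' @return numeric vector, non-increasing.
#' @export
setGeneric("regionMeans", function(x) standardGeneric("regionMeans"))

#' Access the tensor payload
#' @param x a \linkS4class{RegionTensor}.
#' @return numeric array (N, 1, 32).
#' @export
setGeneric("tensorData", function(x) standardGeneric("tensorData"))

#' Access fitted feature layout
#' @param x a \linkS4class{ClinicalEncoder}.
#' @return character vector of output column names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Access training history
#' @param x a \linkS4class{FcrnModel} or \linkS4class{FusionModel}.
#' @return data.frame with per-epoch loss/accuracy.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Access metric values
#' @param x a \linkS4class{MetricsReport}.
#' @return named numeric vector.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' Access confusion-matrix counts
#' @param x a \linkS4class{MetricsReport}.
#' @return named integer vector (TP, FP, TN, FN).
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' Access ROC points
#' @param x a \linkS4class{MetricsReport}.
#' @return data.frame with threshold, fpr, tpr.
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
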