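## Accessors and show methods.

#' @rdname RoiTimeSeriesSet-class
#' @param object,x a \linkS4class{RoiTimeSeriesSet}.
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("tsMatrix", "RoiTimeSeriesSet", function(x) x@mat)

#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("trS", function(x) standardGeneric("trS"))

#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("trS", "RoiTimeSeriesSet", function(x) x@trS)

#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("regionIds", "RoiTimeSeriesSet", function(x) x@regionIds)

#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("participantId", "RoiTimeSeriesSet", function(x) x@participantId)

#' @rdname RoiTimeSeriesSet-class
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname RoiTimeSeriesSet-class
#' @export
setMethod("sessionId", "RoiTimeSeriesSet", function(x) x@sessionId)

setMethod("show", "RoiTimeSeriesSet", function(object) {
  cat("RoiTimeSeriesSet:", object@participantId, "/", object@sessionId, "\n")
  cat(sprintf("  %d regions x %d timepoints, TR = %.3g s (fs = %.4g Hz)\n",
              nrow(object@mat), ncol(object@mat), object@trS, 1 / object@trS))
})

#' @rdname FilterBank-class
#' @param x,object a \linkS4class{FilterBank}.
#' @export
setGeneric("bandBounds", function(x) standardGeneric("bandBounds"))

#' @rdname FilterBank-class
#' @export
setMethod("bandBounds", "FilterBank", function(x) x@bands)

#' @rdname FilterBank-class
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' @rdname FilterBank-class
#' @export
setMethod("bandCenters", "FilterBank", function(x) x@centers)

#' @rdname FilterBank-class
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname FilterBank-class
#' @export
setMethod("nBands", "FilterBank", function(x) x@nBands)

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank: %d bands of %.4g Hz tiling [%.3g, %.3g) Hz\n",
              object@nBands, (object@fHi - object@fLo) / object@nBands,
              object@fLo, object@fHi))
})

#' Feature matrix in samples-by-features orientation
#'
#' The assay is stored features-by-sessions; classifiers and the causal
#' forest consume its transpose.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @return numeric matrix, one row per participant-session.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureTable",
          function(x) t(SummarizedExperiment::assay(x, "features")))

#' Session-level labels of a feature table
#'
#' @param x a \linkS4class{FeatureTable}.
#' @return data.frame with participant_id, session_id, sex, diagnosis and
#'   severity_score.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "FeatureTable",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname CausalForestModel-class
#' @param x,object a \linkS4class{CausalForestModel}.
#' @export
setGeneric("splitCounts", function(x) standardGeneric("splitCounts"))

#' @rdname CausalForestModel-class
#' @export
setMethod("splitCounts", "CausalForestModel", function(x) x@splitCounts)

setMethod("show", "CausalForestModel", function(object) {
  cat(sprintf("CausalForestModel: %d honest trees, %d features, n = %d\n",
              length(object@trees), length(object@featureNames), object@n))
  cat(sprintf("  total splits: %d\n", sum(object@splitCounts)))
})

#' @rdname StabilitySelection-class
#' @param x,object a \linkS4class{StabilitySelection}.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname StabilitySelection-class
#' @export
setMethod("selectedFeatures", "StabilitySelection", function(x) x@selected)

setMethod("show", "StabilitySelection", function(object) {
  cat(sprintf(
    "StabilitySelection: %d stable features (top cut %d per run, %d runs)\n",
    length(object@selected), object@topK, length(object@perRunTop)))
  if (length(object@selected))
    cat("  head:", paste(head(object@selected, 5), collapse = ", "), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", nrow(object@perFold), "outer folds\n")
  for (m in names(object@mean))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, object@mean[m], object@sd[m]))
})

#' @rdname McaResult-class
#' @param x,object an \linkS4class{McaResult}.
#' @export
setGeneric("inertiaShares", function(x) standardGeneric("inertiaShares"))

#' @rdname McaResult-class
#' @export
setMethod("inertiaShares", "McaResult", function(x) x@inertiaShares)

#' @rdname McaResult-class
#' @export
setGeneric("rowCoords", function(x) standardGeneric("rowCoords"))

#' @rdname McaResult-class
#' @export
setMethod("rowCoords", "McaResult", function(x) x@rowCoords)

#' @rdname McaResult-class
#' @export
setGeneric("colCoords", function(x) standardGeneric("colCoords"))

#' @rdname McaResult-class
#' @export
setMethod("colCoords", "McaResult", function(x) x@colCoords)

setMethod("show", "McaResult", function(object) {
  cat(sprintf("McaResult: %d x %d table, %d retained dimension(s)\n",
              length(object@rowMasses), length(object@colMasses),
              object@nDims))
  sh <- object@inertiaShares[seq_len(object@nDims)]
  cat("  inertia shares:", paste(sprintf("%.1f%%", 100 * sh), collapse = ", "),
      "\n")
})
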