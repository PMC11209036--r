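## S4 class definitions for the whole pipeline.

#' Configuration of a synthetic parcellated BOLD cohort
#'
#' Describes a four-cell cohort (female/male crossed with patient/control) of
#' region-by-timepoint BOLD-like matrices with planted, severity-scaled
#' group differences in selected regions. Defaults emulate typical
#' resting-state acquisitions: 175--265 frames at a repetition time of
#' 2--2.4 s over a 200-region cortical parcellation.
#'
#' @slot nPerGroup participants per (sex x diagnosis) cell.
#' @slot nRegions number of atlas regions.
#' @slot nTimepointsRange inclusive integer interval of frame counts.
#' @slot trRangeS inclusive interval of repetition times in seconds.
#' @slot affectedRegions 1-based indices of regions carrying planted effects.
#' @slot amplitudeEffect dimensionless fluctuation-scale shift applied to
#'   affected regions of patients (0 = none).
#' @slot bandEffectBand index of the filter-bank band receiving a planted
#'   power change (1..10 for the default bank).
#' @slot bandEffectFactor multiplicative band-power factor (> 0; 1 = none).
#' @slot severityMeanlog,severitySdlog log-normal parameters of patient
#'   severity scores (controls score 0).
#' @slot sessionsPerPatientRange inclusive interval of sessions per patient.
#' @slot seed root seed; all randomness descends from it via per-entity
#'   substreams.
#' @export
setClass("CohortConfig",
  representation(
    nPerGroup = "integer",
    nRegions = "integer",
    nTimepointsRange = "integer",
    trRangeS = "numeric",
    affectedRegions = "integer",
    amplitudeEffect = "numeric",
    bandEffectBand = "integer",
    bandEffectFactor = "numeric",
    severityMeanlog = "numeric",
    severitySdlog = "numeric",
    sessionsPerPatientRange = "integer",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (object@nRegions < 1L) msg <- c(msg, "nRegions must be >= 1")
  if (length(object@nTimepointsRange) != 2L ||
      object@nTimepointsRange[1] > object@nTimepointsRange[2] ||
      object@nTimepointsRange[1] < 3L)
    msg <- c(msg, "nTimepointsRange must be a non-empty interval with lower bound >= 3")
  if (length(object@trRangeS) != 2L || object@trRangeS[1] > object@trRangeS[2] ||
      object@trRangeS[1] <= 0)
    msg <- c(msg, "trRangeS must be a non-empty positive interval")
  if (length(object@affectedRegions) &&
      (any(object@affectedRegions < 1L) ||
       any(object@affectedRegions > object@nRegions)))
    msg <- c(msg, "affectedRegions out of 1..nRegions")
  if (object@bandEffectBand < 1L || object@bandEffectBand > 10L)
    msg <- c(msg, "bandEffectBand outside the filter-bank range 1..10")
  if (object@bandEffectFactor <= 0)
    msg <- c(msg, "bandEffectFactor must be > 0")
  if (length(object@sessionsPerPatientRange) != 2L ||
      object@sessionsPerPatientRange[1] > object@sessionsPerPatientRange[2] ||
      object@sessionsPerPatientRange[1] < 1L)
    msg <- c(msg, "sessionsPerPatientRange must be a non-empty interval >= 1")
  if (length(msg)) msg else TRUE
})

#' One participant-session's parcellated ROI time series
#'
#' A regions-by-timepoints matrix of BOLD-like values with its sampling
#' metadata.
#'
#' @slot participantId,sessionId identifiers.
#' @slot mat numeric matrix, one row per region.
#' @slot trS repetition time in seconds (sampling interval).
#' @slot regionIds 1-based atlas indices, one per matrix row.
#' @export
setClass("RoiTimeSeriesSet",
  representation(
    participantId = "character",
    sessionId = "character",
    mat = "matrix",
    trS = "numeric",
    regionIds = "integer"
  )
)

setValidity("RoiTimeSeriesSet", function(object) {
  msg <- character()
  if (nrow(object@mat) != length(object@regionIds))
    msg <- c(msg, "matrix row count must equal length(regionIds)")
  if (anyNA(object@mat)) msg <- c(msg, "matrix must not contain missing values")
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  if (length(msg)) msg else TRUE
})

#' Contiguous equal-width frequency filter bank
#'
#' Tiles the analyzed band [fLo, fHi) with nBands equal-width half-open
#' intervals; the top band additionally includes fHi.
#'
#' @slot fLo,fHi band edges in Hz.
#' @slot nBands number of bands.
#' @slot bands nBands x 2 matrix of (low, high) edges.
#' @slot centers band center frequencies (low + width/2).
#' @export
setClass("FilterBank",
  representation(fLo = "numeric", fHi = "numeric", nBands = "integer",
                 bands = "matrix", centers = "numeric")
)

setValidity("FilterBank", function(object) {
  msg <- character()
  if (object@fHi <= object@fLo) msg <- c(msg, "fHi must exceed fLo")
  if (object@nBands < 1L) msg <- c(msg, "nBands must be >= 1")
  w <- (object@fHi - object@fLo) / object@nBands
  if (nrow(object@bands) == object@nBands) {
    widths <- object@bands[, 2] - object@bands[, 1]
    if (any(abs(widths - w) > 1e-12))
      msg <- c(msg, "bands must have equal width (fHi - fLo)/nBands")
    if (abs(object@bands[1, 1] - object@fLo) > 1e-12 ||
        abs(object@bands[object@nBands, 2] - object@fHi) > 1e-12)
      msg <- c(msg, "bands must tile [fLo, fHi)")
  } else msg <- c(msg, "bands must have nBands rows")
  if (length(msg)) msg else TRUE
})

#' Cohort-level feature table
#'
#' A \linkS4class{SummarizedExperiment} whose assay holds the canonical
#' descriptor matrix (features in rows, participant-sessions in columns),
#' with feature metadata (region, family, descriptor, band) in
#' \code{rowData} and session labels (participant, sex, diagnosis,
#' severity) in \code{colData}.
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

#' Causal forest tuning parameters
#'
#' @slot nTrees number of honest causal trees.
#' @slot subsampleFraction fraction of samples drawn (without replacement)
#'   per tree.
#' @slot honestyFraction fraction of each tree's subsample used to learn the
#'   split structure; the complement estimates leaf effects.
#' @slot mtry features tried per split; \code{NA} means \code{floor(sqrt(p))}.
#' @slot minLeafTreated,minLeafControl minimum samples of each arm per leaf.
#' @slot maxDepth maximum tree depth; 0 means unlimited.
#' @slot seed RNG seed.
#' @export
setClass("CfParams",
  representation(nTrees = "integer", subsampleFraction = "numeric",
                 honestyFraction = "numeric", mtry = "integer",
                 minLeafTreated = "integer", minLeafControl = "integer",
                 maxDepth = "integer", seed = "integer")
)

setValidity("CfParams", function(object) {
  msg <- character()
  if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
  if (object@subsampleFraction <= 0 || object@subsampleFraction > 1)
    msg <- c(msg, "subsampleFraction must be in (0, 1]")
  if (object@honestyFraction <= 0 || object@honestyFraction >= 1)
    msg <- c(msg, "honestyFraction must be in (0, 1)")
  if (!is.na(object@mtry) && object@mtry < 1L)
    msg <- c(msg, "mtry must be >= 1")
  if (object@minLeafTreated < 1L || object@minLeafControl < 1L)
    msg <- c(msg, "minimum leaf sizes must be >= 1")
  if (object@maxDepth < 0L) msg <- c(msg, "maxDepth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Fitted honest causal forest
#'
#' @slot trees per-tree node tables (feature, threshold, children, honest
#'   leaf effect, validity flag, sample counts).
#' @slot splitCounts per-feature split totals across all trees.
#' @slot featureNames column names of the fitted design matrix.
#' @slot params the \linkS4class{CfParams} used.
#' @slot n number of fitted samples.
#' @export
setClass("CausalForestModel",
  representation(trees = "list", splitCounts = "numeric",
                 featureNames = "character", params = "CfParams",
                 n = "integer")
)

#' Stability-selection configuration
#'
#' The repeated-run rule: fit the forest \code{nRuns} times with independent
#' seeds, mark each run's top \code{topFraction} of features, and keep
#' features marked in at least \code{minAppearances} runs.
#'
#' @slot nRuns number of independently seeded forest fits (default 10).
#' @slot minAppearances minimum number of runs a feature must reach the top
#'   cut to be kept (default 4).
#' @slot topFraction fraction of features marked per run (default 0.04, the
#'   complement of a 96 percent reduction).
#' @export
setClass("StabilityConfig",
  representation(nRuns = "integer", minAppearances = "integer",
                 topFraction = "numeric")
)

setValidity("StabilityConfig", function(object) {
  msg <- character()
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (object@minAppearances < 1L || object@minAppearances > object@nRuns)
    msg <- c(msg, "minAppearances must be in 1..nRuns")
  if (object@topFraction <= 0 || object@topFraction > 1)
    msg <- c(msg, "topFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of repeated-run stability selection
#'
#' @slot selected stable feature names, ordered by mean importance.
#' @slot appearances per-feature count of runs in which it reached the top
#'   cut (all features).
#' @slot meanImportance per-feature importance averaged over runs.
#' @slot perRunTop the top feature set of each run.
#' @slot topK the per-run top-cut size \code{ceiling(topFraction * p)}.
#' @export
setClass("StabilitySelection",
  representation(selected = "character", appearances = "integer",
                 meanImportance = "numeric", perRunTop = "list",
                 topK = "integer")
)

#' Wrapper forward-selection configuration
#'
#' @slot classifier "logistic" or "xgboost".
#' @slot hyperParams classifier hyperparameters (list).
#' @slot metric scoring metric; "accuracy".
#' @slot innerFolds grouped cross-validation folds used to score candidates.
#' @slot maxSubsetSize cap on the selected subset size.
#' @slot tolerance minimum score improvement required to accept a feature.
#' @slot seed RNG seed (fold assignment and classifier).
#' @export
setClass("WfssConfig",
  representation(classifier = "character", hyperParams = "list",
                 metric = "character", innerFolds = "integer",
                 maxSubsetSize = "integer", tolerance = "numeric",
                 seed = "integer")
)

setValidity("WfssConfig", function(object) {
  msg <- character()
  if (!object@classifier %in% c("logistic", "xgboost"))
    msg <- c(msg, "classifier must be 'logistic' or 'xgboost'")
  if (object@innerFolds < 2L) msg <- c(msg, "innerFolds must be >= 2")
  if (object@maxSubsetSize < 1L) msg <- c(msg, "maxSubsetSize must be >= 1")
  if (object@tolerance < 0) msg <- c(msg, "tolerance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ridge-regularized logistic classifier
#'
#' Maximizes the Bernoulli log-likelihood with a small L2 penalty on the
#' non-intercept coefficients; the penalty guarantees a finite optimum even
#' under complete separation.
#'
#' @slot coefficients intercept followed by feature weights.
#' @slot lambda ridge penalty.
#' @slot converged logical.
#' @slot iterations Newton iterations used.
#' @export
setClass("LogisticModel",
  representation(coefficients = "numeric", lambda = "numeric",
                 converged = "logical", iterations = "integer")
)

#' Patient-grouped nested cross-validation scheme
#'
#' @slot outerFolds number of outer (evaluation) folds.
#' @slot innerFolds number of inner (model-selection) folds.
#' @slot stratify stratify fold assignment by class at the participant level.
#' @slot seed RNG seed for fold draws.
#' @export
setClass("CvScheme",
  representation(outerFolds = "integer", innerFolds = "integer",
                 stratify = "logical", seed = "integer")
)

setValidity("CvScheme", function(object) {
  msg <- character()
  if (object@outerFolds < 1L) msg <- c(msg, "outerFolds must be >= 1")
  if (object@innerFolds < 2L) msg <- c(msg, "innerFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Nested cross-validation metrics report
#'
#' @slot perFold one row per outer fold: accuracy, F1, precision, recall.
#' @slot mean,sd metric means and standard deviations over outer folds.
#' @slot confusion per-fold confusion matrices (2 x 2).
#' @slot folds per-fold train/test participant assignments.
#' @export
setClass("MetricsReport",
  representation(perFold = "data.frame", mean = "numeric", sd = "numeric",
                 confusion = "list", folds = "list")
)

#' Correspondence analysis result
#'
#' @slot rowMasses,colMasses marginal masses (each sums to 1).
#' @slot singularValues singular values of the standardized residual matrix.
#' @slot principalInertias squared singular values.
#' @slot inertiaShares principal inertias as shares of the total.
#' @slot rowCoords,colCoords principal coordinates, retained dimensions in
#'   columns.
#' @slot nDims retained dimensions (2, or 1 for rank-deficient tables).
#' @export
setClass("McaResult",
  representation(rowMasses = "numeric", colMasses = "numeric",
                 singularValues = "numeric", principalInertias = "numeric",
                 inertiaShares = "numeric", rowCoords = "matrix",
                 colCoords = "matrix", nDims = "integer")
)
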