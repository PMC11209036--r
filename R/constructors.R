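#' Create a synthetic cohort configuration
#'
#' @param nPerGroup participants per (sex x diagnosis) cell.
#' @param nRegions number of atlas regions (200 for a Schaefer-style
#'   cortical parcellation).
#' @param nTimepointsRange inclusive interval of frame counts per session.
#' @param trRangeS inclusive interval of repetition times (seconds).
#' @param affectedRegions region indices carrying planted patient effects.
#' @param amplitudeEffect fluctuation-scale shift in affected regions of
#'   patients, scaled by severity; 0 disables it.
#' @param bandEffect length-2 numeric: filter-bank band index and the
#'   multiplicative band-power factor planted in affected regions of
#'   patients; factor 1 disables it.
#' @param severityMeanlog,severitySdlog log-normal severity parameters for
#'   patients. The default median \code{exp(severityMeanlog)} is 23.7, the
#'   UPDRS-III motor-score level near Hoehn-Yahr stage 2, so both severity
#'   subgroups are populated when splitting at that threshold.
#' @param sessionsPerPatientRange inclusive interval of sessions contributed
#'   per patient (controls contribute one session).
#' @param seed root RNG seed.
#' @return A validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nPerGroup,
                         nRegions = 200L,
                         nTimepointsRange = c(175L, 265L),
                         trRangeS = c(2.0, 2.4),
                         affectedRegions = integer(),
                         amplitudeEffect = 0,
                         bandEffect = c(3, 1),
                         severityMeanlog = log(23.7),
                         severitySdlog = 0.6,
                         sessionsPerPatientRange = c(1L, 3L),
                         seed = 1L) {
  if (length(bandEffect) != 2L)
    stop("bandEffect must be c(band index, power factor)")
  new("CohortConfig",
      nPerGroup = as.integer(nPerGroup),
      nRegions = as.integer(nRegions),
      nTimepointsRange = as.integer(nTimepointsRange),
      trRangeS = as.numeric(trRangeS),
      affectedRegions = as.integer(affectedRegions),
      amplitudeEffect = as.numeric(amplitudeEffect),
      bandEffectBand = as.integer(bandEffect[1]),
      bandEffectFactor = as.numeric(bandEffect[2]),
      severityMeanlog = as.numeric(severityMeanlog),
      severitySdlog = as.numeric(severitySdlog),
      sessionsPerPatientRange = as.integer(sessionsPerPatientRange),
      seed = as.integer(seed))
}

#' Construct an ROI time-series set
#'
#' @param mat regions x timepoints numeric matrix.
#' @param trS repetition time in seconds.
#' @param participantId,sessionId identifiers.
#' @param regionIds 1-based atlas indices (default 1..nrow).
#' @return A validated \linkS4class{RoiTimeSeriesSet}.
#' @export
roiTimeSeriesSet <- function(mat, trS, participantId = "sub-01",
                             sessionId = "ses-01",
                             regionIds = seq_len(nrow(mat))) {
  new("RoiTimeSeriesSet", participantId = as.character(participantId),
      sessionId = as.character(sessionId), mat = as.matrix(mat),
      trS = as.numeric(trS), regionIds = as.integer(regionIds))
}

#' Create causal forest parameters
#'
#' Defaults: 500 trees, half-sample subsampling, an even honesty split,
#' \code{sqrt(p)} features per split, and at least 5 samples of each
#' treatment arm per leaf.
#'
#' @param nTrees,subsampleFraction,honestyFraction,mtry,minLeafTreated,minLeafControl,maxDepth,seed
#'   see \linkS4class{CfParams}.
#' @return A validated \linkS4class{CfParams}.
#' @export
cfParams <- function(nTrees = 500L, subsampleFraction = 0.5,
                     honestyFraction = 0.5, mtry = NA_integer_,
                     minLeafTreated = 5L, minLeafControl = 5L,
                     maxDepth = 0L, seed = 1L) {
  new("CfParams", nTrees = as.integer(nTrees),
      subsampleFraction = as.numeric(subsampleFraction),
      honestyFraction = as.numeric(honestyFraction),
      mtry = as.integer(mtry), minLeafTreated = as.integer(minLeafTreated),
      minLeafControl = as.integer(minLeafControl),
      maxDepth = as.integer(maxDepth), seed = as.integer(seed))
}

#' Create a stability-selection configuration
#'
#' Either \code{topFraction} or its reduction-percentage form may be given:
#' \code{reductionPercent = 96} means the top 4 percent of features are
#' marked per run.
#'
#' @param nRuns number of independently seeded forest runs.
#' @param minAppearances runs a feature must reach the top cut.
#' @param topFraction fraction of features marked per run.
#' @param reductionPercent alternative to \code{topFraction}; one of the
#'   usual sweep values 99.9, 99.5, 99, 98, 96.
#' @return A validated \linkS4class{StabilityConfig}.
#' @export
stabilityConfig <- function(nRuns = 10L, minAppearances = 4L,
                            topFraction = 0.04, reductionPercent = NULL) {
  if (!is.null(reductionPercent))
    topFraction <- (100 - reductionPercent) / 100
  new("StabilityConfig", nRuns = as.integer(nRuns),
      minAppearances = as.integer(minAppearances),
      topFraction = as.numeric(topFraction))
}

#' Create a wrapper forward-selection configuration
#'
#' @param classifier "logistic" or "xgboost".
#' @param hyperParams classifier hyperparameters.
#' @param metric scoring metric (only "accuracy" is implemented).
#' @param innerFolds grouped CV folds for candidate scoring.
#' @param maxSubsetSize subset size cap.
#' @param tolerance minimum improvement to accept a feature (0 = strict
#'   improvement).
#' @param seed RNG seed.
#' @return A validated \linkS4class{WfssConfig}.
#' @export
wfssConfig <- function(classifier = "logistic", hyperParams = list(),
                       metric = "accuracy", innerFolds = 5L,
                       maxSubsetSize = 50L, tolerance = 0, seed = 1L) {
  new("WfssConfig", classifier = classifier, hyperParams = hyperParams,
      metric = metric, innerFolds = as.integer(innerFolds),
      maxSubsetSize = as.integer(maxSubsetSize),
      tolerance = as.numeric(tolerance), seed = as.integer(seed))
}

#' Create a patient-grouped nested cross-validation scheme
#'
#' @param outerFolds outer (evaluation) folds.
#' @param innerFolds inner (model-selection) folds.
#' @param stratify stratify participants by class when building folds.
#' @param seed RNG seed.
#' @return A validated \linkS4class{CvScheme}.
#' @export
cvScheme <- function(outerFolds = 5L, innerFolds = 5L, stratify = TRUE,
                     seed = 1L) {
  new("CvScheme", outerFolds = as.integer(outerFolds),
      innerFolds = as.integer(innerFolds), stratify = isTRUE(stratify),
      seed = as.integer(seed))
}
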