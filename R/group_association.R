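## Group-wise region scores feeding the association analysis.
##
## The causal forest is fit within each sex with treatment = diagnosis and
## outcome = severity (the detection convention). Its stable features are
## then attributed to the patient or control group of that sex by the sign
## of the feature's association with diagnosis (higher in patients ->
## patient group), giving one region-score table per sex-by-diagnosis
## group. The severity variant restricts to patients and uses treatment =
## (severity above threshold).

# split a sex's stable features into two groups by association sign and
# aggregate each into region scores
.signSplitRegionScores <- function(X, grpHigh, grpLow, isHigh, sel,
                                   labelHigh, labelLow, out) {
  ranking <- stabilityRanking(sel)
  feats <- selectedFeatures(sel)
  if (!length(feats)) return(out)
  assoc <- colMeans(X[isHigh, feats, drop = FALSE]) -
    colMeans(X[!isHigh, feats, drop = FALSE])
  hi <- feats[assoc > 0]
  lo <- feats[assoc <= 0]
  if (length(hi))
    out[[labelHigh]] <- regionAverageRanking(ranking, hi)
  if (length(lo))
    out[[labelLow]] <- regionAverageRanking(ranking, lo)
  out
}

#' Region scores per sex-by-diagnosis group
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param params \linkS4class{CfParams} for the per-sex forests.
#' @param stability \linkS4class{StabilityConfig}.
#' @return named list of region-score data.frames (groups "F-PD",
#'   "F-control", "M-PD", "M-control"; groups without stable features are
#'   absent).
#' @export
groupRegionScores <- function(table, params = cfParams(),
                              stability = stabilityConfig()) {
  info <- sampleInfo(table)
  X <- featureValues(table)
  out <- list()
  for (sx in c("F", "M")) {
    idx <- which(info$sex == sx)
    if (length(unique(info$diagnosis[idx])) < 2L) next
    ps <- params
    ps@seed <- deriveSeed(params@seed, idCode(sx))
    sel <- suppressWarnings(stabilitySelect(
      X[idx, , drop = FALSE], Y = info$severity_score[idx],
      T = info$diagnosis[idx] == "PD", ps, stability))
    out <- .signSplitRegionScores(
      X[idx, , drop = FALSE], isHigh = info$diagnosis[idx] == "PD",
      sel = sel, labelHigh = paste0(sx, "-PD"),
      labelLow = paste0(sx, "-control"), out = out)
  }
  out
}

#' Region scores per sex-by-severity group
#'
#' Patients only; within each sex the forest contrasts patients above and
#' below the severity threshold.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param threshold severity threshold (default 23.7, see
#'   \code{\link{assignSeverityGroups}}).
#' @param params,stability forest configuration.
#' @return named list of region-score data.frames (groups "F-above",
#'   "F-below", "M-above", "M-below"; empty groups absent).
#' @export
severityRegionScores <- function(table, threshold = 23.7,
                                 params = cfParams(),
                                 stability = stabilityConfig()) {
  info <- sampleInfo(table)
  X <- featureValues(table)
  out <- list()
  for (sx in c("F", "M")) {
    idx <- which(info$sex == sx & info$diagnosis == "PD")
    if (!length(idx)) next
    above <- info$severity_score[idx] > threshold
    if (length(unique(above)) < 2L) next
    ps <- params
    ps@seed <- deriveSeed(params@seed, idCode(sx), 2L)
    sel <- suppressWarnings(stabilitySelect(
      X[idx, , drop = FALSE], Y = info$severity_score[idx], T = above,
      ps, stability))
    out <- .signSplitRegionScores(
      X[idx, , drop = FALSE], isHigh = above, sel = sel,
      labelHigh = paste0(sx, "-above"), labelLow = paste0(sx, "-below"),
      out = out)
  }
  out
}
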