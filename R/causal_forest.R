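## Honest causal forest with split-frequency importance and the
## repeated-run stability rule.

#' Fit an honest causal forest
#'
#' Grows \code{nTrees} causal trees. Each tree draws a subsample without
#' replacement, splits it into a structure half and an estimation half
#' (honesty), and greedily maximizes the treatment-effect heterogeneity
#' criterion \deqn{\frac{n_L n_R}{(n_L+n_R)^2}(\hat\tau_L - \hat\tau_R)^2}
#' on the structure half, trying \code{mtry} randomly chosen features per
#' split. Leaf effects \eqn{\hat\tau = \bar Y_{T=1} - \bar Y_{T=0}} are
#' estimated on the estimation half; a leaf is valid for prediction only if
#' that half holds at least the configured minimum of each arm. Split
#' counts per feature are accumulated for the importance ranking.
#'
#' With a constant outcome no split has positive criterion, so the forest
#' degenerates to stumps and the importance ranking is uniform.
#'
#' @param X numeric matrix, samples x features (column names become
#'   feature names).
#' @param Y numeric outcome.
#' @param T binary treatment indicator (0/1 or logical).
#' @param params a \linkS4class{CfParams}.
#' @return A \linkS4class{CausalForestModel}.
#' @export
fitCausalForest <- function(X, Y, T, params = cfParams()) {
  validObject(params)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Y <- as.numeric(Y)
  T <- as.integer(as.logical(T) | T == 1)
  n <- nrow(X)
  p <- ncol(X)
  if (length(Y) != n || length(T) != n)
    stop("X, Y and T must have matching lengths")
  if (length(unique(T)) < 2L)
    stop("both treatment arms must be present")
  minPerLeaf <- params@minLeafTreated + params@minLeafControl
  if (n < 4L * max(params@minLeafTreated, params@minLeafControl))
    stop("too few samples for the configured leaf sizes")
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  mtry <- if (is.na(params@mtry)) max(1L, floor(sqrt(p))) else
    min(params@mtry, p)
  m <- max(2L, floor(params@subsampleFraction * n))
  nstr <- max(1L, floor(params@honestyFraction * m))
  if (nstr >= m) nstr <- m - 1L
  trees <- vector("list", params@nTrees)
  counts <- numeric(p)
  withSeed(params@seed, {
    for (t in seq_len(params@nTrees)) {
      sub <- sample.int(n, m)
      strIdx <- sub[seq_len(nstr)]
      estIdx <- sub[(nstr + 1L):m]
      nodes <- cpp_grow_tree(X, Y, T, strIdx, estIdx, mtry,
                             params@minLeafTreated, params@minLeafControl,
                             params@maxDepth)
      attr(nodes, "structure_idx") <- strIdx
      attr(nodes, "estimation_idx") <- estIdx
      trees[[t]] <- nodes
      sf <- nodes[, "feature"]
      sf <- sf[sf > 0]
      if (length(sf)) {
        tb <- tabulate(sf, nbins = p)
        counts <- counts + tb
      }
    }
  })
  names(counts) <- fn
  new("CausalForestModel", trees = trees, splitCounts = counts,
      featureNames = fn, params = params, n = as.integer(n))
}

#' Predict conditional average treatment effects
#'
#' Routes each sample down every tree and averages the honest leaf effects
#' over trees whose leaf is valid (has enough estimation-half samples of
#' both arms).
#'
#' @param model a \linkS4class{CausalForestModel}.
#' @param X numeric matrix (or vector for a single sample) with the fitted
#'   dimensionality.
#' @return numeric vector of \eqn{\hat\tau(x)}.
#' @export
predictCate <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(model@featureNames))
    stop("X must have the fitted dimensionality (",
         length(model@featureNames), " features)")
  pr <- cpp_predict_forest(model@trees, X)
  if (any(pr$nvalid == 0L))
    stop("no tree has a valid leaf for ", sum(pr$nvalid == 0L), " sample(s)")
  pr$tau
}

#' Split-frequency feature importance
#'
#' Importance of a feature is the number of internal splits made on it
#' across the forest, normalized so the scores sum to 1. Ordering is by
#' descending score with ties broken by feature name. A forest with no
#' splits at all (constant outcome) yields a uniform ranking with a
#' warning.
#'
#' @param model a \linkS4class{CausalForestModel}.
#' @return data.frame with columns \code{feature} and \code{importance},
#'   in rank order.
#' @export
splitFrequencyImportance <- function(model) {
  counts <- model@splitCounts
  tot <- sum(counts)
  if (tot == 0) {
    warning("forest made no splits; importance is uniform")
    imp <- rep(1 / length(counts), length(counts))
  } else imp <- counts / tot
  ord <- order(-imp, names(counts))
  data.frame(feature = names(counts)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Repeated-run stability selection
#'
#' Fits the forest \code{nRuns} times with independently derived seeds,
#' marks each run's top \code{ceiling(topFraction * p)} features by
#' split-frequency importance, and keeps features marked in at least
#' \code{minAppearances} runs, ordered by mean importance over runs (ties
#' by name) and capped at the per-run top-cut size. A feature a run never
#' split on is not "highly ranked" in that run, so the per-run marked set
#' is additionally restricted to features with a positive split count.
#'
#' @param X,Y,T as in \code{\link{fitCausalForest}}.
#' @param params a \linkS4class{CfParams}; its seed is the base seed from
#'   which the per-run seeds are derived.
#' @param stability a \linkS4class{StabilityConfig}.
#' @return A \linkS4class{StabilitySelection}; empty (with a warning) if no
#'   feature is stable.
#' @export
stabilitySelect <- function(X, Y, T, params = cfParams(),
                            stability = stabilityConfig()) {
  validObject(stability)
  X <- as.matrix(X)
  p <- ncol(X)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  colnames(X) <- fn
  rankings <- vector("list", stability@nRuns)
  eligible <- vector("list", stability@nRuns)
  for (run in seq_len(stability@nRuns)) {
    rp <- params
    rp@seed <- deriveSeed(params@seed, 1000L + run)
    model <- fitCausalForest(X, Y, T, rp)
    rk <- suppressWarnings(splitFrequencyImportance(model))
    rankings[[run]] <- rk
    # only features the run actually split on can be "highly ranked"
    eligible[[run]] <- names(model@splitCounts)[model@splitCounts > 0]
  }
  aggregateStabilityRuns(rankings, stability, eligible = eligible)
}

#' Aggregate per-run rankings with the stability rule
#'
#' The rule applied by \code{\link{stabilitySelect}}, exposed so
#' precomputed rankings can be aggregated: mark each run's top
#' \code{ceiling(topFraction * p)} features, keep those marked in at least
#' \code{minAppearances} runs, order by mean importance (ties by name),
#' cap at the top-cut size.
#'
#' @param rankings list of per-run data.frames (columns \code{feature},
#'   \code{importance}) in rank order, all over the same feature set.
#' @param stability a \linkS4class{StabilityConfig} with
#'   \code{nRuns = length(rankings)}.
#' @param eligible optional list (same length) of feature subsets allowed
#'   into each run's top cut; defaults to all features.
#' @return A \linkS4class{StabilitySelection}.
#' @export
aggregateStabilityRuns <- function(rankings, stability = stabilityConfig(),
                                   eligible = NULL) {
  validObject(stability)
  if (length(rankings) != stability@nRuns)
    stop("need exactly nRuns = ", stability@nRuns, " rankings")
  fn <- sort(rankings[[1]]$feature)
  p <- length(fn)
  topK <- as.integer(ceiling(stability@topFraction * p))
  appearances <- setNames(integer(p), fn)
  impSum <- setNames(numeric(p), fn)
  perRunTop <- vector("list", stability@nRuns)
  for (run in seq_along(rankings)) {
    rk <- rankings[[run]]
    if (!setequal(rk$feature, fn))
      stop("run ", run, " ranks a different feature set")
    keep <- if (is.null(eligible)) rep(TRUE, nrow(rk)) else
      rk$feature %in% eligible[[run]]
    top <- head(rk$feature[keep], topK)
    perRunTop[[run]] <- top
    appearances[top] <- appearances[top] + 1L
    impSum[rk$feature] <- impSum[rk$feature] + rk$importance
  }
  meanImp <- impSum / stability@nRuns
  stable <- names(appearances)[appearances >= stability@minAppearances]
  stable <- stable[order(-meanImp[stable], stable)]
  if (length(stable) > topK) stable <- stable[seq_len(topK)]
  if (!length(stable))
    warning("no feature was stable across runs; consider lowering ",
            "minAppearances")
  new("StabilitySelection", selected = stable, appearances = appearances,
      meanImportance = meanImp, perRunTop = perRunTop, topK = topK)
}

#' Region-level aggregation of top-ranked features
#'
#' For each brain region with at least one selected feature, computes the
#' mean importance and the count of its selected features; regions with no
#' selected feature are omitted. This is the data behind region bubble
#' plots (region index vs. average ranking, bubble size = feature count).
#'
#' @param ranking data.frame from \code{\link{splitFrequencyImportance}}
#'   (or the mean-importance analogue of a stability selection).
#' @param selected character vector of selected feature names.
#' @param regionOf optional named integer vector mapping feature names to
#'   region indices; by default regions are parsed from canonical names.
#' @return data.frame with columns \code{region}, \code{mean_importance},
#'   \code{n_features}, sorted by decreasing mean importance.
#' @export
regionAverageRanking <- function(ranking, selected, regionOf = NULL) {
  if (!length(selected)) stop("no selected features to aggregate")
  idx <- match(selected, ranking$feature)
  if (anyNA(idx))
    stop("selected feature(s) missing from the ranking: ",
         paste(head(selected[is.na(idx)], 3), collapse = ", "))
  reg <- if (is.null(regionOf)) featureRegion(selected) else {
    r <- regionOf[selected]
    if (anyNA(r))
      stop("feature(s) not mapped to a region: ",
           paste(head(selected[is.na(r)], 3), collapse = ", "))
    as.integer(r)
  }
  imp <- ranking$importance[idx]
  agg <- vapply(split(imp, reg), mean, numeric(1))
  cnt <- vapply(split(imp, reg), length, integer(1))
  out <- data.frame(region = as.integer(names(agg)),
                    mean_importance = unname(agg),
                    n_features = unname(cnt))
  out[order(-out$mean_importance, out$region), , drop = FALSE]
}

#' Mean-importance ranking of a stability selection
#'
#' Convenience accessor returning all features ordered by their importance
#' averaged over the stability runs, in the same shape as
#' \code{\link{splitFrequencyImportance}}.
#'
#' @param selection a \linkS4class{StabilitySelection}.
#' @return data.frame with columns \code{feature} and \code{importance}.
#' @export
stabilityRanking <- function(selection) {
  imp <- selection@meanImportance
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
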