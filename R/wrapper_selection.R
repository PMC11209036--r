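## Wrapper forward feature-subset selection.

# grouped-CV accuracy of a feature subset under a classifier spec
.groupedCvScore <- function(X, y, folds, spec, seed) {
  k <- max(folds)
  correct <- 0L
  total <- 0L
  for (f in seq_len(k)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    if (length(unique(y[trainIdx])) < 2L) next
    fit <- .trainClf(spec, X[trainIdx, , drop = FALSE], y[trainIdx],
                     seed = deriveSeed(seed, f))
    pred <- .predictClf(fit, X[testIdx, , drop = FALSE])
    correct <- correct + sum(pred == y[testIdx])
    total <- total + length(testIdx)
  }
  if (total == 0L) stop("no scoreable fold; degenerate labels")
  correct / total
}

#' Greedy wrapper forward subset selection
#'
#' Starts from the empty set and, at each step, adds the candidate feature
#' whose addition maximizes the patient-grouped cross-validated accuracy of
#' the configured classifier; stops when no candidate improves the score by
#' more than the tolerance or the subset-size cap is reached. The fold
#' assignment is drawn once (grouped by participant, stratified by class)
#' and reused for every candidate evaluation, and the starting score is the
#' majority-class accuracy, so the accepted-step score trace is
#' non-decreasing. Ties go to the earlier feature in pool order.
#'
#' @param X numeric matrix restricted to the candidate pool (samples x
#'   features, named columns).
#' @param y binary labels.
#' @param groups participant ids, one per sample.
#' @param config a \linkS4class{WfssConfig}.
#' @return list with \code{selected} (features in acceptance order),
#'   \code{trace} (data.frame of feature and score after each acceptance),
#'   and \code{baseline} (the majority-class starting score).
#' @export
wfss <- function(X, y, groups, config = wfssConfig()) {
  validObject(config)
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("empty candidate pool")
  y <- as.integer(as.logical(y) | y == 1)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  spec <- list(name = config@classifier, hyperParams = config@hyperParams)
  folds <- makeGroupedFolds(groups, y, config@innerFolds, config@seed)
  pool <- colnames(X)
  selected <- character()
  best <- max(mean(y), 1 - mean(y))  # majority-class baseline
  baseline <- best
  trace <- data.frame(feature = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  while (length(selected) < config@maxSubsetSize && length(pool)) {
    scores <- vapply(pool, function(f) {
      .groupedCvScore(X[, c(selected, f), drop = FALSE], y, folds, spec,
                      deriveSeed(config@seed, idCode(f)))
    }, numeric(1))
    iBest <- which.max(scores)  # first maximum: earlier pool order wins ties
    if (scores[iBest] <= best + config@tolerance) break
    best <- scores[iBest]
    selected <- c(selected, pool[iBest])
    trace <- rbind(trace, data.frame(feature = pool[iBest], score = best,
                                     stringsAsFactors = FALSE))
    pool <- pool[-iBest]
  }
  list(selected = selected, trace = trace, baseline = baseline)
}
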