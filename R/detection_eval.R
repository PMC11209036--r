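## Patient-grouped cross-validation and the detection metrics.
##
## All studies of one participant stay in the same fold, so a participant
## is never used for both training and testing; sessions are scored as
## independent test items.

#' Patient-grouped, class-stratified fold assignment
#'
#' Participants (not sessions) are assigned to folds: within each class,
#' participants are shuffled and dealt round-robin, so folds are
#' class-balanced at the participant level and every session of one
#' participant lands in the same fold.
#'
#' @param participantIds character vector, one entry per session.
#' @param labels binary labels, one per session (constant within
#'   participant).
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @param stratify stratify by class; if \code{FALSE}, participants are
#'   dealt without regard to class.
#' @return integer fold id per session.
#' @export
makeGroupedFolds <- function(participantIds, labels, k, seed = 1L,
                             stratify = TRUE) {
  pid <- as.character(participantIds)
  up <- unique(pid)
  if (length(up) < k)
    stop("fewer participants (", length(up), ") than folds (", k, ")")
  plab <- labels[match(up, pid)]
  foldOf <- setNames(integer(length(up)), up)
  withSeed(seed, {
    if (stratify) {
      for (cl in unique(plab)) {
        members <- sample(up[plab == cl])
        foldOf[members] <- (seq_along(members) - 1L) %% k + 1L
      }
    } else {
      members <- sample(up)
      foldOf[members] <- (seq_along(members) - 1L) %% k + 1L
    }
  })
  unname(foldOf[pid])
}

# hard leakage guard: no participant on both sides of a split
.assertDisjoint <- function(pid, trainIdx, testIdx) {
  inter <- intersect(unique(pid[trainIdx]), unique(pid[testIdx]))
  if (length(inter))
    stop("participant leakage across train/test: ",
         paste(head(inter, 3), collapse = ", "))
  invisible(TRUE)
}

#' Binary classification metrics
#'
#' @param truth,pred binary vectors (0/1).
#' @return named vector: accuracy, f1, precision, recall, plus the
#'   confusion counts as an attribute \code{"confusion"} (2 x 2 matrix).
#' @export
classificationMetrics <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  out <- c(accuracy = (tp + tn) / length(truth), f1 = f1,
           precision = prec, recall = rec)
  attr(out, "confusion") <- matrix(c(tp, fn, fp, tn), 2, 2,
    dimnames = list(truth = c("1", "0"), pred = c("1", "0")))
  out
}

#' Detection pipeline specification
#'
#' Bundles the three stages refit inside every outer training fold of
#' \code{\link{nestedCv}}: causal-forest stability selection (optional),
#' wrapper forward subset selection (optional), and the final classifier.
#' The causal-forest stage uses the detection convention: treatment =
#' diagnosis (patient 1, control 0) and outcome = severity score (0 for
#' controls), so heterogeneity splits track features that modulate the
#' diagnosis-severity contrast.
#'
#' @param classifier list(name = "logistic"|"xgboost", hyperParams = list()).
#' @param cf optional \linkS4class{CfParams} enabling causal-forest
#'   reduction.
#' @param stability \linkS4class{StabilityConfig} used when \code{cf} is
#'   given.
#' @param wfss optional \linkS4class{WfssConfig} enabling wrapper
#'   refinement.
#' @return an object of class \code{"detectionPipeline"}.
#' @export
detectionPipeline <- function(classifier = list(name = "logistic"),
                              cf = NULL, stability = stabilityConfig(),
                              wfss = NULL) {
  structure(list(classifier = classifier, cf = cf, stability = stability,
                 wfss = wfss), class = "detectionPipeline")
}

# fit one outer-training fold: select features, train the classifier
.fitPipeline <- function(pipeline, X, y, severity, groups, innerK, seed) {
  features <- colnames(X)
  if (!is.null(pipeline$cf)) {
    cfp <- pipeline$cf
    cfp@seed <- deriveSeed(seed, 11L)
    sel <- suppressWarnings(
      stabilitySelect(X, Y = severity, T = y, cfp, pipeline$stability))
    if (length(sel@selected)) features <- sel@selected
  }
  if (!is.null(pipeline$wfss) && length(features) > 1L) {
    wcfg <- pipeline$wfss
    wcfg@seed <- deriveSeed(seed, 13L)
    wcfg@innerFolds <- as.integer(innerK)
    wres <- wfss(X[, features, drop = FALSE], y, groups, wcfg)
    if (length(wres$selected)) features <- wres$selected
  }
  fit <- .trainClf(c(pipeline$classifier,
                     list(hyperParams = pipeline$classifier$hyperParams)),
                   X[, features, drop = FALSE], y,
                   seed = deriveSeed(seed, 17L))
  list(fit = fit, features = features)
}

#' Patient-grouped nested cross-validation
#'
#' Outer folds estimate generalization; inside every outer training fold
#' the pipeline's feature selection and model fitting are re-run from
#' scratch (the inner grouped folds of the wrapper stage are the model
#' selection loop), so no information from an outer test fold influences
#' the model evaluated on it. Participant-disjointness of every split is
#' hard-asserted.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param scheme a \linkS4class{CvScheme}.
#' @param pipeline a \code{\link{detectionPipeline}}.
#' @return A \linkS4class{MetricsReport}.
#' @export
nestedCv <- function(table, scheme = cvScheme(),
                     pipeline = detectionPipeline()) {
  validObject(scheme)
  info <- sampleInfo(table)
  X <- featureValues(table)
  y <- as.integer(info$diagnosis == "PD")
  pid <- info$participant_id
  sev <- info$severity_score
  folds <- makeGroupedFolds(pid, y, scheme@outerFolds, scheme@seed,
                            scheme@stratify)
  # every fold must contain both classes among its test sessions
  for (f in seq_len(scheme@outerFolds))
    if (length(unique(y[folds == f])) < 2L)
      stop("outer fold ", f, " lacks a class; use fewer folds or more ",
           "participants")
  perFold <- NULL
  confs <- list()
  assignments <- list()
  for (f in seq_len(scheme@outerFolds)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    .assertDisjoint(pid, trainIdx, testIdx)
    fitSeed <- deriveSeed(scheme@seed, 100L + f)
    fit <- .fitPipeline(pipeline, X[trainIdx, , drop = FALSE], y[trainIdx],
                        sev[trainIdx], pid[trainIdx], scheme@innerFolds,
                        fitSeed)
    pred <- .predictClf(fit$fit,
                        X[testIdx, fit$features, drop = FALSE])
    m <- classificationMetrics(y[testIdx], pred)
    confs[[f]] <- attr(m, "confusion")
    perFold <- rbind(perFold, as.data.frame(as.list(m)))
    assignments[[f]] <- list(train = unique(pid[trainIdx]),
                             test = unique(pid[testIdx]),
                             n_features = length(fit$features))
  }
  mn <- colMeans(perFold)
  sdev <- apply(perFold, 2, sd)
  new("MetricsReport", perFold = perFold, mean = mn, sd = sdev,
      confusion = confs, folds = assignments)
}
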