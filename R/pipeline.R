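## End-to-end pipeline: simulate -> extract -> rank -> select -> evaluate
## -> associate, with a JSON run manifest tying every artifact to the
## configuration and seed that produced it.

#' Default pipeline configuration
#'
#' A small demonstration cohort (25 participants per sex-by-diagnosis
#' cell, 6 regions) with planted effects in two regions, sized to run
#' end-to-end in well under a minute.
#'
#' @param seed root seed.
#' @return nested configuration list understood by
#'   \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = seed,
    cohort = list(nPerGroup = 25, nRegions = 6,
                  affectedRegions = c(2, 5),
                  amplitudeEffect = 0.5, bandEffect = c(3, 2.5),
                  sessionsPerPatientRange = c(1, 2)),
    cf = list(nTrees = 400, subsampleFraction = 0.8, maxDepth = 2),
    stability = list(nRuns = 10, minAppearances = 4, topFraction = 0.04),
    wfss = list(classifier = "logistic", maxSubsetSize = 8),
    cv = list(outerFolds = 4, innerFolds = 3),
    classifier = list(name = "logistic")
  )
}

.configFromList <- function(cfg) {
  seed <- as.integer(cfg$seed %||% 1L)
  co <- cfg$cohort %||% list()
  coArgs <- co[intersect(names(co),
                         names(formals(cohortConfig)))]
  coArgs$seed <- deriveSeed(seed, 1L)
  st <- cfg$stability %||% list()
  stArgs <- st[intersect(names(st), names(formals(stabilityConfig)))]
  cf <- cfg$cf %||% list()
  cfArgs <- cf[intersect(names(cf), names(formals(cfParams)))]
  cfArgs$seed <- deriveSeed(seed, 2L)
  wf <- cfg$wfss %||% list()
  wfArgs <- wf[intersect(names(wf), names(formals(wfssConfig)))]
  wfArgs$seed <- deriveSeed(seed, 3L)
  cv <- cfg$cv %||% list()
  cvArgs <- cv[intersect(names(cv), names(formals(cvScheme)))]
  cvArgs$seed <- deriveSeed(seed, 4L)
  list(seed = seed,
       cohort = do.call(cohortConfig, coArgs),
       cfParams = do.call(cfParams, cfArgs),
       stability = do.call(stabilityConfig, stArgs),
       wfss = do.call(wfssConfig, wfArgs),
       cv = do.call(cvScheme, cvArgs),
       classifier = cfg$classifier %||% list(name = "logistic"))
}

#' Run the full pipeline and write its artifacts
#'
#' Executes simulate, extract, rank (stability selection on the full
#' cohort), select (wrapper refinement), evaluate (patient-grouped nested
#' cross-validation) and associate (correspondence analysis of the
#' group-by-region table), writing six artifacts plus a run manifest into
#' \code{outDir}: \code{participants.csv}, \code{feature_table.csv},
#' \code{ranking.csv}, \code{selection.csv}, \code{metrics.json} and
#' \code{mca_coordinates.csv}.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or the path of a JSON file
#'   holding one.
#' @param outDir output directory, created if needed.
#' @return list with the in-memory stage results (cohort, table,
#'   selection, wfss, metrics, mca) and \code{artifacts}, the written file
#'   paths.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfgObjs <- .configFromList(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(outDir, f)

  cohort <- generateCohort(cfgObjs$cohort)
  write.csv(cohort$participants, art("participants.csv"), row.names = FALSE)

  table <- extractFeatureTable(cohort)
  writeFeatureTable(table, art("feature_table.csv"))

  info <- sampleInfo(table)
  X <- featureValues(table)
  sel <- suppressWarnings(stabilitySelect(
    X, Y = info$severity_score, T = info$diagnosis == "PD",
    cfgObjs$cfParams, cfgObjs$stability))
  ranking <- stabilityRanking(sel)
  ranking$runs_appeared <- sel@appearances[ranking$feature]
  write.csv(ranking, art("ranking.csv"), row.names = FALSE)

  wres <- NULL
  selectedPool <- selectedFeatures(sel)
  if (length(selectedPool) > 1L) {
    wres <- wfss(X[, selectedPool, drop = FALSE],
                 info$diagnosis == "PD", info$participant_id, cfgObjs$wfss)
  }
  selDf <- data.frame(
    feature = selectedPool,
    mean_importance = sel@meanImportance[selectedPool],
    runs_appeared = sel@appearances[selectedPool],
    wfss_selected = selectedPool %in% (wres$selected %||% character()))
  write.csv(selDf, art("selection.csv"), row.names = FALSE)

  pipeline <- detectionPipeline(classifier = cfgObjs$classifier,
                                cf = cfgObjs$cfParams,
                                stability = cfgObjs$stability,
                                wfss = cfgObjs$wfss)
  metrics <- nestedCv(table, cfgObjs$cv, pipeline)
  jsonlite::write_json(
    list(mean = as.list(metrics@mean), sd = as.list(metrics@sd),
         per_fold = metrics@perFold,
         n_features_per_fold = vapply(metrics@folds, `[[`, numeric(1),
                                      "n_features")),
    art("metrics.json"), auto_unbox = TRUE, digits = NA)

  scores <- groupRegionScores(table, cfgObjs$cfParams, cfgObjs$stability)
  mca <- tryCatch({
    m <- fitMca(buildAssociationTable(scores))
    write.csv(associationPlotData(m), art("mca_coordinates.csv"),
              row.names = FALSE)
    m
  }, error = function(e) {
    warning("association analysis skipped: ", conditionMessage(e))
    NULL
  })

  files <- list.files(outDir, full.names = TRUE)
  manifest <- list(
    config = config, seed = cfgObjs$seed,
    package_version = as.character(utils::packageVersion("fmriCF")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = lapply(setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, art("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, table = table, selection = sel,
                 wfss = wres, metrics = metrics, mca = mca,
                 artifacts = c(list.files(outDir, full.names = TRUE))))
}
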