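## Plain-text I/O: ROI time-series TSV with a JSON sidecar, feature-table
## CSV with a JSON schema, and small CSV/JSON artifact writers.

#' Write an ROI time-series set
#'
#' One TSV row per region (first column the region id, remaining columns
#' the timepoints) plus a JSON sidecar, replacing the \code{.tsv} suffix
#' with \code{.json}, holding the repetition time and identifiers. Values
#' are written with full double precision so a write-read round trip is an
#' identity.
#'
#' @param tss a \linkS4class{RoiTimeSeriesSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRoiTimeSeries <- function(tss, path) {
  validObject(tss)
  mat <- tss@mat
  header <- c("region", paste0("t", seq_len(ncol(mat))))
  lines <- c(paste(header, collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(tss@regionIds[i],
                       formatC(mat[i, ], format = "g", digits = 17)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(tr_s = tss@trS, participant_id = tss@participantId,
         session_id = tss@sessionId),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI time-series set
#'
#' Expects the TSV layout of \code{\link{writeRoiTimeSeries}} and its JSON
#' sidecar. Ragged rows, non-numeric cells and a missing sidecar each
#' raise a distinct error naming the file (and line, where applicable).
#'
#' @param path TSV path.
#' @return A \linkS4class{RoiTimeSeriesSet}.
#' @export
readRoiTimeSeries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for ", path, " (expected ", sidecar, ")")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$tr_s)) stop("sidecar ", sidecar, " lacks tr_s")
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file ", path, " has no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  for (i in seq_along(cells))
    if (length(cells[[i]]) != width)
      stop("ragged row in ", path, " at line ", i, ": expected ", width,
           " fields, found ", length(cells[[i]]))
  body <- cells[-1]
  regions <- integer(length(body))
  mat <- matrix(NA_real_, length(body), width - 1L)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]]))
    if (anyNA(v))
      stop("non-numeric cell in ", path, " at line ", i + 1L)
    regions[i] <- as.integer(v[1])
    mat[i, ] <- v[-1]
  }
  roiTimeSeriesSet(mat, meta$tr_s,
                   participantId = meta$participant_id %||% "unknown",
                   sessionId = meta$session_id %||% "unknown",
                   regionIds = regions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table as CSV plus a JSON schema
#'
#' The CSV holds one row per participant-session: the label columns
#' (participant_id, session_id, sex, diagnosis, severity_score) followed
#' by the canonical feature columns. The schema file records the filter
#' bank and package version.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param path output CSV path; the schema goes to \code{<path>.schema.json}.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  df <- cbind(sampleInfo(table),
              as.data.frame(featureValues(table), check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(bank = S4Vectors::metadata(table)$bank,
         n_features = nrow(table),
         package_version = as.character(utils::packageVersion("fmriCF"))),
    paste0(path, ".schema.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#'
#' @param path CSV path.
#' @return A \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labelCols <- c("participant_id", "session_id", "sex", "diagnosis",
                 "severity_score")
  if (!all(labelCols %in% names(df)))
    stop("feature-table CSV ", path, " lacks label column(s): ",
         paste(setdiff(labelCols, names(df)), collapse = ", "))
  feat <- as.matrix(df[, setdiff(names(df), labelCols), drop = FALSE])
  assay <- t(feat)
  colnames(assay) <- paste(df$participant_id, df$session_id, sep = ".")
  cd <- S4Vectors::DataFrame(df[, labelCols], row.names = colnames(assay))
  rd <- S4Vectors::DataFrame(region = featureRegion(rownames(assay)),
                             family = featureFamily(rownames(assay)),
                             row.names = rownames(assay))
  meta <- list()
  schema <- paste0(path, ".schema.json")
  if (file.exists(schema))
    meta <- jsonlite::read_json(schema, simplifyVector = TRUE)["bank"]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), colData = cd, rowData = rd,
    metadata = meta)
  new("FeatureTable", se)
}
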