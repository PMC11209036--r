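## Correspondence analysis of group-by-region association tables.
##
## The rows are participant groups (sex x diagnosis, or sex x severity
## subgroup), the columns are brain-region categories, and the cells count
## each region's stability-selected features within the group. The
## analysis is the classical CA decomposition: standardized residuals of
## the correspondence matrix, SVD, principal coordinates, and inertia
## shares; the two leading dimensions are retained for the association
## map.

#' Build the group-by-region association table
#'
#' @param regionScoresList named list (one element per group) of region
#'   score tables from \code{\link{regionAverageRanking}}.
#' @param binary if \code{TRUE}, cells record membership (0/1) instead of
#'   selected-feature counts.
#' @return numeric matrix, groups in rows, region categories
#'   (\code{"r<index>"}) in columns; all-zero columns are dropped.
#' @export
buildAssociationTable <- function(regionScoresList, binary = FALSE) {
  if (is.null(names(regionScoresList)) ||
      any(!nzchar(names(regionScoresList))))
    stop("regionScoresList must be a named list (one name per group)")
  nonEmpty <- vapply(regionScoresList, function(d) nrow(d) > 0, logical(1))
  if (sum(nonEmpty) < 2L)
    stop("at least two non-empty groups are required")
  regions <- sort(unique(unlist(lapply(regionScoresList,
                                       function(d) d$region))))
  tab <- matrix(0, length(regionScoresList), length(regions),
                dimnames = list(names(regionScoresList),
                                paste0("r", regions)))
  for (g in names(regionScoresList)) {
    d <- regionScoresList[[g]]
    if (!nrow(d)) next
    tab[g, match(d$region, regions)] <-
      if (binary) 1 else d$n_features
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) stop("fewer than two region categories with mass")
  tab
}

#' Correspondence analysis of a nonnegative table
#'
#' Decomposes the correspondence matrix \eqn{P = N / n} via the SVD of the
#' standardized residuals
#' \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}}: principal inertias are the
#' squared singular values, and row/column principal coordinates are
#' \eqn{D_r^{-1/2} U \Sigma} and \eqn{D_c^{-1/2} V \Sigma}. Dimensions are
#' ordered by decreasing inertia and the two leading ones are retained;
#' the sign of each axis is fixed by making its largest-magnitude
#' coordinate positive. A rank-1 table yields a one-dimensional result
#' with a warning.
#'
#' @param tab nonnegative matrix without all-zero rows or columns.
#' @return An \linkS4class{McaResult}.
#' @export
fitMca <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("table cells must be finite and nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table must have no all-zero row or column")
  n <- sum(tab)
  P <- tab / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  keep <- which(sv$d > 1e-12)
  if (length(keep) < 1L) stop("table has no association structure (rank 0)")
  nd <- min(2L, length(keep))
  if (nd < 2L)
    warning("table has rank 1; returning a one-dimensional result")
  d <- sv$d[keep]
  inertias <- d^2
  shares <- inertias / sum(inertias)
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  F <- diag(1 / sqrt(r)) %*% U %*% diag(d, length(d))
  G <- diag(1 / sqrt(cc)) %*% V %*% diag(d, length(d))
  for (j in seq_len(ncol(F))) {           # deterministic axis signs
    all_j <- c(F[, j], G[, j])
    if (all_j[which.max(abs(all_j))] < 0) {
      F[, j] <- -F[, j]
      G[, j] <- -G[, j]
    }
  }
  dimnames(F) <- list(rownames(tab), paste0("dim", seq_along(d)))
  dimnames(G) <- list(colnames(tab), paste0("dim", seq_along(d)))
  new("McaResult", rowMasses = r, colMasses = cc, singularValues = d,
      principalInertias = inertias, inertiaShares = shares,
      rowCoords = F[, seq_len(nd), drop = FALSE],
      colCoords = G[, seq_len(nd), drop = FALSE], nDims = nd)
}

#' Assign sex-by-severity groups to patients
#'
#' Splits patients at a motor-score threshold (default 23.7 on the
#' UPDRS-III, the level at which Hoehn-Yahr stage 2 is approximately
#' reached). The comparison is strict: a score exactly at the threshold is
#' "below". Controls are excluded.
#'
#' @param participants participant table (see
#'   \code{\link{generateParticipants}}).
#' @param threshold severity threshold.
#' @return character vector named by participant id, values of the form
#'   \code{"F-above"}, \code{"M-below"}, ...
#' @export
assignSeverityGroups <- function(participants, threshold = 23.7) {
  pts <- participants[participants$diagnosis == "PD", , drop = FALSE]
  if (!nrow(pts)) stop("no patients in the participant table")
  if (anyNA(pts$severity_score))
    stop("missing severity score for patient(s): ",
         paste(head(pts$participant_id[is.na(pts$severity_score)], 3),
               collapse = ", "))
  setNames(sprintf("%s-%s", pts$sex,
                   ifelse(pts$severity_score > threshold, "above", "below")),
           pts$participant_id)
}

#' Coordinates table for the association map
#'
#' @param mca an \linkS4class{McaResult}.
#' @return data.frame with one row per group and region category: id, kind
#'   ("group" or "region"), the two principal coordinates, and the per-axis
#'   inertia shares (repeated columns \code{axis1_share},
#'   \code{axis2_share}).
#' @export
associationPlotData <- function(mca) {
  nd <- mca@nDims
  getDim <- function(M, j) if (j <= nd) M[, j] else rep(0, nrow(M))
  d <- data.frame(
    id = c(rownames(mca@rowCoords), rownames(mca@colCoords)),
    kind = rep(c("group", "region"),
               c(nrow(mca@rowCoords), nrow(mca@colCoords))),
    dim1 = c(getDim(mca@rowCoords, 1L), getDim(mca@colCoords, 1L)),
    dim2 = c(getDim(mca@rowCoords, 2L), getDim(mca@colCoords, 2L)),
    stringsAsFactors = FALSE)
  d$axis1_share <- mca@inertiaShares[1]
  d$axis2_share <- if (nd >= 2L) mca@inertiaShares[2] else 0
  d
}

#' Scatter plot of the association map
#'
#' Base-graphics rendering of \code{\link{associationPlotData}}: regions as
#' points, groups highlighted as filled squares, axes annotated with their
#' inertia shares.
#'
#' @param mca an \linkS4class{McaResult}.
#' @param ... passed to \code{plot}.
#' @return the plot data, invisibly.
#' @export
plotAssociation <- function(mca, ...) {
  d <- associationPlotData(mca)
  isGroup <- d$kind == "group"
  plot(d$dim1, d$dim2, type = "n",
       xlab = sprintf("Dimension 1 (%.1f%%)", 100 * d$axis1_share[1]),
       ylab = sprintf("Dimension 2 (%.1f%%)", 100 * d$axis2_share[1]), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 2)
  graphics::points(d$dim1[!isGroup], d$dim2[!isGroup], pch = 1,
                   col = "grey40")
  graphics::points(d$dim1[isGroup], d$dim2[isGroup], pch = 15,
                   col = "firebrick", cex = 1.3)
  graphics::text(d$dim1, d$dim2, d$id, pos = 3, cex = 0.7)
  invisible(d)
}
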