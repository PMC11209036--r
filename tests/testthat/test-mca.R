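test_that("the identity table has unit singular values and inertia 3", {
  tab <- diag(4)
  dimnames(tab) <- list(paste0("g", 1:4), paste0("r", 1:4))
  m <- fitMca(tab)
  expect_equal(sum(m@principalInertias), 3)
  expect_equal(m@singularValues, rep(1, 3))
  # each group's coordinates coincide with its own category's
  expect_equal(unname(rowCoords(m)), unname(colCoords(m)), tolerance = 1e-10)
  expect_equal(sum(inertiaShares(m)), 1)
  expect_equal(sum(m@rowMasses), 1)
  expect_equal(sum(m@colMasses), 1)
})

test_that("coordinates match a brute-force eigendecomposition", {
  set.seed(21)
  for (i in 1:5) {
    tab <- matrix(rpois(30, 4) + 1, 6, 5,
                  dimnames = list(paste0("g", 1:6), paste0("r", 1:5)))
    m <- fitMca(tab)
    ref <- slowCA(tab)
    expect_equal(m@singularValues, ref$sv, tolerance = 1e-8)
    for (d in 1:2) {
      # sign-free comparison per axis
      expect_equal(abs(unname(m@rowCoords[, d])), abs(ref$rowCoords[, d]),
                   tolerance = 1e-8)
      expect_equal(abs(unname(m@colCoords[, d])), abs(ref$colCoords[, d]),
                   tolerance = 1e-8)
      # consistent relative signs within the axis
      s <- sign(m@rowCoords[, d]) * sign(ref$rowCoords[, d])
      nz <- abs(ref$rowCoords[, d]) > 1e-10
      expect_equal(length(unique(s[nz])), 1L)
    }
  }
})

test_that("transition formulas and axis conventions hold", {
  set.seed(22)
  tab <- matrix(rpois(24, 6) + 1, 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("r", 1:6)))
  m <- fitMca(tab)
  # rows are barycenters of column coordinates scaled by 1/sigma
  P <- tab / sum(tab)
  r <- rowSums(P)
  profile <- sweep(P, 1, r, "/")
  for (d in 1:2) {
    expect_equal(unname(m@rowCoords[, d]),
                 unname(drop(profile %*% m@colCoords[, d])) /
                   m@singularValues[d], tolerance = 1e-10)
  }
  expect_gte(m@inertiaShares[1], m@inertiaShares[2])
  # deterministic sign: the largest-magnitude loading on each axis is +
  for (d in 1:2) {
    all_d <- c(m@rowCoords[, d], m@colCoords[, d])
    expect_gt(all_d[which.max(abs(all_d))], 0)
  }
})

test_that("degenerate tables are refused or reduced", {
  expect_error(fitMca(matrix(c(1, 0, 0, 0), 2, 2)), "all-zero")
  expect_error(fitMca(matrix(-1, 2, 2)), "nonnegative")
  rank1 <- matrix(c(3, 1, 1, 3), 2, 2,
                  dimnames = list(c("a", "b"), c("x", "y")))
  expect_warning(m <- fitMca(rank1), "rank 1")
  expect_equal(m@nDims, 1L)
  # an independence (outer-product) table has no association at all
  indep <- outer(c(1, 2), c(1, 3))
  dimnames(indep) <- list(c("a", "b"), c("x", "y"))
  expect_error(fitMca(indep), "rank 0")
})

test_that("association tables count selected features per region", {
  rs <- list(
    gA = data.frame(region = c(7L, 9L), mean_importance = c(0.3, 0.1),
                    n_features = c(3L, 1L)),
    gB = data.frame(region = c(2L, 9L), mean_importance = c(0.2, 0.4),
                    n_features = c(2L, 5L)))
  tab <- buildAssociationTable(rs)
  expect_equal(rownames(tab), c("gA", "gB"))
  expect_equal(colnames(tab), c("r2", "r7", "r9"))
  expect_equal(unname(tab["gA", ]), c(0, 3, 1))
  expect_equal(unname(tab["gB", ]), c(2, 0, 5))
  expect_equal(sum(tab), sum(vapply(rs, function(d) sum(d$n_features), 1)))
  tabB <- buildAssociationTable(rs, binary = TRUE)
  expect_true(all(tabB %in% 0:1))
  expect_error(buildAssociationTable(rs["gA"]), "two non-empty")
  expect_error(buildAssociationTable(unname(rs)), "named")
})

test_that("two groups with disjoint regions oppose on dimension 1", {
  rs <- list(
    gA = data.frame(region = 1:2, mean_importance = c(0.3, 0.2),
                    n_features = c(4L, 2L)),
    gB = data.frame(region = 3:4, mean_importance = c(0.25, 0.15),
                    n_features = c(3L, 3L)))
  tab <- buildAssociationTable(rs)
  m <- suppressWarnings(fitMca(tab))
  pd <- associationPlotData(m)
  g <- pd[pd$kind == "group", ]
  expect_equal(nrow(pd), 2 + 4)
  expect_lt(g$dim1[1] * g$dim1[2], 0)
  # each group's nearest region lies in its own block
  regs <- pd[pd$kind == "region", ]
  for (i in 1:2) {
    dist <- sqrt((regs$dim1 - g$dim1[i])^2 + (regs$dim2 - g$dim2[i])^2)
    nearest <- regs$id[which.min(dist)]
    own <- paste0("r", rs[[i]]$region)
    expect_true(nearest %in% own)
  }
})

test_that("severity groups split strictly at the threshold", {
  parts <- data.frame(
    participant_id = c("a", "b", "c", "d", "e"),
    sex = c("F", "M", "F", "M", "F"),
    diagnosis = c("PD", "PD", "PD", "PD", "control"),
    severity_score = c(30, 10, 23.7, 24, 0))
  g <- assignSeverityGroups(parts)
  expect_equal(unname(g["a"]), "F-above")
  expect_equal(unname(g["b"]), "M-below")
  expect_equal(unname(g["c"]), "F-below")  # boundary goes below
  expect_equal(unname(g["d"]), "M-above")
  expect_false("e" %in% names(g))          # controls excluded
  parts$severity_score[1] <- NA
  expect_error(assignSeverityGroups(parts), "missing severity")
})

test_that("group and severity region scores are produced on planted data", {
  dat <- plantedFeatureTable()
  scores <- groupRegionScores(dat$table, rankingCfParams(3),
                              stabilityConfig())
  expect_gte(length(scores), 2)
  for (d in scores) {
    expect_true(all(d$n_features >= 1))
    expect_true(all(d$region %in% 1:6))
  }
  tab <- buildAssociationTable(scores)
  m <- suppressWarnings(fitMca(tab))
  expect_lte(m@nDims, 2L)
  sev <- severityRegionScores(dat$table, threshold = 23.7,
                              rankingCfParams(4), stabilityConfig())
  expect_true(all(grepl("-(above|below)$", names(sev))))
})
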