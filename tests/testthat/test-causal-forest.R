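# fabricate a minimal fitted forest from hand-built node tables
fakeForest <- function(trees, featureNames) {
  counts <- setNames(numeric(length(featureNames)), featureNames)
  for (nodes in trees) {
    sf <- nodes[, "feature"]
    sf <- sf[sf > 0]
    for (f in sf) counts[f] <- counts[f] + 1
  }
  new("CausalForestModel", trees = trees, splitCounts = counts,
      featureNames = featureNames, params = cfParams(), n = 10L)
}

leafNode <- function(tau, valid = 1) {
  m <- matrix(c(-1, 0, 0, 0, tau, valid, 0, 0, 0), 1, 9)
  colnames(m) <- c("feature", "threshold", "left", "right", "tau", "valid",
                   "n_str", "n_est1", "n_est0")
  m
}

test_that("a constant treatment effect is recovered", {
  set.seed(1)
  n <- 500
  X <- matrix(rnorm(n * 10), n, 10)
  T <- rbinom(n, 1, 0.5)
  Y <- T * 2 + rnorm(n, 0, 0.1)
  m <- fitCausalForest(X, Y, T, cfParams(nTrees = 100, seed = 3))
  tau <- predictCate(m, X)
  expect_gte(mean(tau), 1.8)
  expect_lte(mean(tau), 2.2)
})

test_that("heterogeneous effects correlate with the truth", {
  set.seed(2)
  n <- 2000
  X <- matrix(rnorm(n * 20), n, 20)
  T <- rbinom(n, 1, 0.5)
  truth <- 3 * (X[, 1] > 0)
  Y <- T * truth + rnorm(n)
  m <- fitCausalForest(X, Y, T, cfParams(nTrees = 200, seed = 5))
  expect_gte(cor(predictCate(m, X), truth), 0.7)
})

test_that("honesty: structure and estimation halves never overlap", {
  set.seed(3)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  T <- rep(0:1, n / 2)
  Y <- rnorm(n)
  m <- fitCausalForest(X, Y, T, cfParams(nTrees = 50, seed = 1))
  for (nodes in m@trees) {
    s <- attr(nodes, "structure_idx")
    e <- attr(nodes, "estimation_idx")
    expect_length(intersect(s, e), 0)
  }
})

test_that("prediction averages valid per-tree leaf effects", {
  fn <- c("a", "b")
  stumps <- fakeForest(list(leafNode(1), leafNode(1)), fn)
  expect_equal(predictCate(stumps, c(0, 0)), 1)
  two <- fakeForest(list(leafNode(0), leafNode(4)), fn)
  expect_equal(predictCate(two, c(5, -5)), 2)
  # invalid leaves are excluded; all-invalid is an error
  mixed <- fakeForest(list(leafNode(0, valid = 0), leafNode(4)), fn)
  expect_equal(predictCate(mixed, c(0, 0)), 4)
  none <- fakeForest(list(leafNode(9, valid = 0)), fn)
  expect_error(predictCate(none, c(0, 0)), "valid leaf")
})

test_that("prediction agrees with a per-tree traversal oracle", {
  set.seed(4)
  n <- 400
  X <- matrix(rnorm(n * 8), n, 8)
  T <- rbinom(n, 1, 0.5)
  Y <- T * X[, 2] + rnorm(n, 0, 0.5)
  m <- fitCausalForest(X, Y, T, cfParams(nTrees = 60, seed = 2))
  pts <- matrix(rnorm(50 * 8), 50, 8)
  expect_equal(predictCate(m, pts),
               apply(pts, 1, function(x) slowCate(m, x)),
               tolerance = 1e-12)
})

test_that("split-frequency importance is a normalized count ranking", {
  fn <- c("f1", "f2", "f3")
  splitOn3 <- matrix(c(3, 0, 2, 3, NA, 0, 9, 0, 0,
                       -1, 0, 0, 0, 1, 1, 4, 2, 2,
                       -1, 0, 0, 0, 2, 1, 5, 2, 3), 3, 9, byrow = TRUE)
  colnames(splitOn3) <- c("feature", "threshold", "left", "right", "tau",
                          "valid", "n_str", "n_est1", "n_est0")
  m <- fakeForest(list(splitOn3), fn)
  imp <- splitFrequencyImportance(m)
  expect_equal(imp$importance[imp$feature == "f3"], 1)
  expect_equal(sum(imp$importance), 1)
  # no splits at all: uniform with a warning
  m0 <- fakeForest(list(leafNode(1)), fn)
  expect_warning(imp0 <- splitFrequencyImportance(m0), "no splits")
  expect_equal(imp0$importance, rep(1 / 3, 3))
})

test_that("importance scores always sum to one", {
  set.seed(5)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6)
  T <- rbinom(n, 1, 0.5)
  Y <- T * X[, 1] + rnorm(n, 0, 0.3)
  m <- fitCausalForest(X, Y, T, cfParams(nTrees = 40, seed = 9))
  expect_equal(sum(splitFrequencyImportance(m)$importance), 1)
})

test_that("degenerate inputs are handled as specified", {
  set.seed(6)
  X <- matrix(rnorm(200 * 4), 200, 4)
  expect_error(fitCausalForest(X, rnorm(200), rep(1, 200)), "both treatment")
  # constant outcome: no split has positive criterion -> stumps
  m <- fitCausalForest(X, rep(2, 200), rep(0:1, 100),
                       cfParams(nTrees = 20, seed = 1))
  expect_equal(sum(m@splitCounts), 0)
  expect_warning(imp <- splitFrequencyImportance(m), "uniform")
  expect_equal(unique(imp$importance), 1 / 4)
})

test_that("the forest is deterministic given its seed", {
  set.seed(7)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  T <- rbinom(n, 1, 0.5)
  Y <- T * X[, 3] + rnorm(n, 0, 0.2)
  m1 <- fitCausalForest(X, Y, T, cfParams(nTrees = 30, seed = 11))
  m2 <- fitCausalForest(X, Y, T, cfParams(nTrees = 30, seed = 11))
  expect_identical(m1@trees, m2@trees)
  expect_identical(splitFrequencyImportance(m1), splitFrequencyImportance(m2))
})

test_that("null heterogeneity keeps importance roughly uniform", {
  set.seed(8)
  n <- 600
  p <- 50
  X <- matrix(rnorm(n * p), n, p)
  T <- rbinom(n, 1, 0.5)
  Y <- T * 1 + rnorm(n)           # constant effect, no modifiers
  m <- fitCausalForest(X, Y, T, cfParams(nTrees = 200, seed = 4))
  imp <- splitFrequencyImportance(m)$importance
  expect_lte(max(imp) / max(min(imp), 1e-12), 5)
})

test_that("stability selection follows the ten-run rule end to end", {
  set.seed(9)
  n <- 400
  p <- 25
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  T <- rbinom(n, 1, 0.5)
  Y <- T * 2 * X[, 7] + rnorm(n, 0, 0.5)
  sel <- stabilitySelect(X, Y, T, cfParams(nTrees = 100, seed = 21),
                         stabilityConfig(topFraction = 0.08))
  expect_lte(length(sel@selected), sel@topK)
  expect_equal(sel@topK, ceiling(0.08 * p))
  expect_true("f7" %in% sel@selected)
  expect_true(all(sel@appearances[sel@selected] >= 4))
  # determinism
  sel2 <- stabilitySelect(X, Y, T, cfParams(nTrees = 100, seed = 21),
                          stabilityConfig(topFraction = 0.08))
  expect_identical(sel@selected, sel2@selected)
})

test_that("region aggregation is an exact group-by mean", {
  ranking <- data.frame(
    feature = c("r7.a", "r7.b", "r9.a", "r2.x"),
    importance = c(0.4, 0.2, 0.3, 0.1))
  # names here are not canonical; supply the map explicitly
  regionOf <- c(r7.a = 7L, r7.b = 7L, r9.a = 9L, r2.x = 2L)
  rs <- regionAverageRanking(ranking, c("r7.a", "r7.b", "r9.a"), regionOf)
  expect_equal(rs$region, c(7L, 9L))          # region 2 absent: not selected
  expect_equal(rs$mean_importance, c(0.3, 0.3))
  expect_equal(rs$n_features, c(2L, 1L))
  # brute-force cross-check on a larger random instance
  set.seed(10)
  fn <- paste0("r", sample(1:6, 40, TRUE), ".", sprintf("d%02d", 1:40))
  rk <- data.frame(feature = fn, importance = runif(40))
  seld <- sample(fn, 15)
  rs2 <- regionAverageRanking(rk, seld)
  byHand <- tapply(rk$importance[match(seld, rk$feature)],
                   featureRegion(seld), mean)
  byHand <- byHand[order(-byHand, as.integer(names(byHand)))]
  expect_equal(setNames(rs2$mean_importance, as.character(rs2$region)),
               setNames(as.numeric(byHand), names(byHand)))
  expect_error(regionAverageRanking(rk, c(seld, "zz.novel")), "missing")
})
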