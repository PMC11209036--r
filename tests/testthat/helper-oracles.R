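# Independent brute-force references used by the oracle-equivalence tests.
# Everything here is direct summation / naive linear algebra, deliberately
# sharing no code with the package internals.

# population moments by direct sums
slowMoments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  if (v <= 0) return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0))
  c(mean = m, variance = v,
    skewness = (sum((x - m)^3) / n) / v^1.5,
    kurtosis = (sum((x - m)^4) / n) / v^2 - 3)
}

slowAvgAutocorr <- function(x, maxLag = 20) {
  n <- length(x)
  L <- min(maxLag, n - 2)
  if (L < 1) return(0)
  m <- sum(x) / n
  denom <- sum((x - m)^2)
  if (denom <= 0) return(0)
  mean(sapply(seq_len(L), function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + (x[t] - m) * (x[t + k] - m)
    s / denom
  }))
}

slowIntensity <- function(x) {
  c(slowMoments(x), autocorr = slowAvgAutocorr(x),
    waveheight = max(x) - min(x))
}

# O(N^2) DFT by direct summation
slowDFT <- function(x) {
  n <- length(x)
  sapply(seq_len(n) - 1, function(k) {
    s <- 0 + 0i
    for (t in seq_len(n) - 1)
      s <- s + x[t + 1] * exp(-2i * pi * k * t / n)
    s
  })
}

slowDetrend <- function(x) {
  t0 <- seq_along(x)
  unname(stats::residuals(stats::lm(x ~ t0)))
}

# direct inverse DFT restricted to a set of 0-based frequencies and their
# conjugates
slowBandSignal <- function(X, keep0) {
  n <- length(X)
  keep <- union(keep0, (n - keep0) %% n)
  sapply(seq_len(n) - 1, function(t) {
    s <- 0 + 0i
    for (k in keep) s <- s + X[k + 1] * exp(2i * pi * k * t / n)
    Re(s) / n
  })
}

slowBandMembers <- function(fHz, lo, hi, isTop) {
  eps <- 1e-12
  which(fHz >= lo - eps & (fHz < hi - eps | (isTop & fHz <= hi + eps)))
}

# the 4*nb+2 frequency descriptors by direct summation
slowFrequency <- function(ts, fs, bank) {
  x <- slowDetrend(ts)
  n <- length(x)
  X <- slowDFT(x)
  kOne <- 0:(n %/% 2)
  fHz <- kOne / n * fs
  pow <- Mod(X[kOne + 1])^2
  bands <- bandBounds(bank)
  nb <- nrow(bands)
  out <- numeric(0)
  for (b in seq_len(nb)) {
    sel <- slowBandMembers(fHz, bands[b, 1], bands[b, 2], b == nb)
    if (!length(sel)) { out <- c(out, 0, 0, 0, 0); next }
    energy <- sum(pow[sel])
    dom <- fHz[sel[which.max(pow[sel])]]
    xb <- slowBandSignal(X, kOne[sel])
    out <- c(out, energy, dom, sum((xb - mean(xb))^2) / n,
             slowAvgAutocorr(xb))
  }
  selAll <- slowBandMembers(fHz, bank@fLo, bank@fHi, TRUE)
  tot <- sum(pow[selAll])
  dom <- selAll[which.max(pow[selAll])]
  c(out, fHz[dom], if (tot > 0) pow[dom] / tot else 0)
}

# phase-grid maximum overlap by explicit correlation calls
slowConnectivity <- function(ts, fs, bank, nPhase = 64) {
  x <- slowDetrend(ts)
  n <- length(x)
  X <- slowDFT(x)
  kOne <- 0:(n %/% 2)
  fHz <- kOne / n * fs
  tt <- (seq_len(n) - 1) / fs
  bands <- bandBounds(bank)
  nb <- nrow(bands)
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- slowBandMembers(fHz, bands[b, 1], bands[b, 2], b == nb)
    if (!length(sel)) next
    xb <- slowBandSignal(X, kOne[sel])
    if (stats::sd(xb) == 0) next
    best <- -Inf
    for (ph in 2 * pi * (seq_len(nPhase) - 1) / nPhase)
      best <- max(best, stats::cor(xb, sin(2 * pi * bandCenters(bank)[b] * tt + ph)))
    out[b] <- best
  }
  out
}

# per-tree traversal of a fitted forest, in plain R
slowCate <- function(model, x) {
  vals <- sapply(model@trees, function(nodes) {
    id <- 1
    while (nodes[id, "feature"] > 0) {
      f <- nodes[id, "feature"]
      id <- if (x[f] <= nodes[id, "threshold"]) nodes[id, "left"]
            else nodes[id, "right"]
    }
    if (nodes[id, "valid"] > 0) nodes[id, "tau"] else NA_real_
  })
  mean(vals, na.rm = TRUE)
}

# correspondence analysis by explicit eigendecomposition of S^T S
slowCA <- function(tab) {
  n <- sum(tab)
  P <- tab / n
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  keep <- which(ev$values > 1e-12)
  d <- sqrt(ev$values[keep])
  V <- ev$vectors[, keep, drop = FALSE]
  U <- S %*% V %*% diag(1 / d, length(d))
  list(sv = d,
       rowCoords = diag(1 / sqrt(r)) %*% U %*% diag(d, length(d)),
       colCoords = diag(1 / sqrt(cc)) %*% V %*% diag(d, length(d)),
       inertias = d^2)
}

# tiny reference gradient booster: depth-1 regression trees on the
# log-odds gradient, constant learning rate
refBoost <- function(X, y, rounds = 10, eta = 0.3) {
  n <- nrow(X)
  f <- rep(0, n)
  trees <- list()
  for (r in seq_len(rounds)) {
    p <- 1 / (1 + exp(-f))
    g <- y - p                      # negative gradient of logloss
    h <- p * (1 - p)
    best <- NULL
    for (j in seq_len(ncol(X))) {
      vs <- sort(unique(X[, j]))
      if (length(vs) < 2) next
      cuts <- (vs[-1] + vs[-length(vs)]) / 2
      for (cv in cuts) {
        L <- X[, j] <= cv
        if (!any(L) || all(L)) next
        wL <- sum(g[L]) / (sum(h[L]) + 1e-6)
        wR <- sum(g[!L]) / (sum(h[!L]) + 1e-6)
        gain <- sum(g[L]) * wL + sum(g[!L]) * wR
        if (is.null(best) || gain > best$gain)
          best <- list(gain = gain, j = j, cut = cv, wL = wL, wR = wR)
      }
    }
    if (is.null(best)) break
    L <- X[, best$j] <= best$cut
    f <- f + eta * ifelse(L, best$wL, best$wR)
    trees[[r]] <- best
  }
  structure(list(trees = trees, eta = eta), class = "refBoost")
}

predictRefBoost <- function(model, X) {
  f <- rep(0, nrow(X))
  for (tr in model$trees)
    f <- f + model$eta * ifelse(X[, tr$j] <= tr$cut, tr$wL, tr$wR)
  1 / (1 + exp(-f))
}
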