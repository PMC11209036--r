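## Feature extraction: 58 descriptors per region.
##
## Per region: 6 intensity descriptors of the time series, 42 frequency
## descriptors from a 10-band filter bank over 0.01--0.15 Hz (4 per band
## plus 2 global), and 10 connectivity descriptors (maximum phase-searched
## correlation between each band-limited signal and a sinusoid at the band
## center). Over a 200-region parcellation this yields 11,600 features.

#' Build a contiguous equal-width filter bank
#'
#' The default tiles the resting-state band of interest, 0.01 to 0.15 Hz,
#' with ten bands of 0.014 Hz each; frequencies above ~0.15 Hz are dominated
#' by respiratory and cardiac noise and are excluded.
#'
#' @param fLo,fHi analyzed band edges in Hz.
#' @param nBands number of equal-width bands.
#' @return A \linkS4class{FilterBank}; band i covers
#'   \code{[fLo + (i-1) w, fLo + i w)} with \code{w = (fHi - fLo)/nBands};
#'   the top band additionally includes \code{fHi}.
#' @examples
#' bank <- buildFilterBank()
#' bandBounds(bank)[1, ]   # 0.010 0.024
#' bandCenters(bank)[1]    # 0.017
#' @export
buildFilterBank <- function(fLo = 0.01, fHi = 0.15, nBands = 10L) {
  if (fHi <= fLo) stop("fHi must exceed fLo (non-positive band width)")
  nBands <- as.integer(nBands)
  w <- (fHi - fLo) / nBands
  lo <- fLo + (seq_len(nBands) - 1) * w
  bands <- cbind(low = lo, high = lo + w)
  new("FilterBank", fLo = fLo, fHi = fHi, nBands = nBands, bands = bands,
      centers = lo + w / 2)
}

# population moments; constant series yield 0 skewness/kurtosis
.popMoments <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)
  if (v <= 0) return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0))
  c(mean = m, variance = v, skewness = mean(d^3) / v^1.5,
    kurtosis = mean(d^4) / v^2 - 3)
}

# mean normalized autocorrelation over lags 1..min(maxLag, n-2)
.avgAutocorr <- function(x, maxLag = 20L) {
  n <- length(x)
  L <- min(maxLag, n - 2L)
  if (L < 1L) return(0)
  m <- mean(x)
  d <- x - m
  denom <- sum(d^2)
  if (denom <= 0) return(0)
  r <- vapply(seq_len(L), function(k)
    sum(d[seq_len(n - k)] * d[(k + 1):n]) / denom, numeric(1))
  mean(r)
}

#' Intensity descriptors of a time series
#'
#' Six descriptors of the voxel-intensity time course: mean, population
#' variance, skewness, excess kurtosis, average normalized autocorrelation
#' over lags 1..min(20, N-2), and maximum wave height (the vertical
#' distance between crest and trough, i.e. max - min). A constant series
#' yields 0 for variance, skewness, kurtosis, autocorrelation and wave
#' height.
#'
#' @param ts numeric vector, length >= 3.
#' @return named numeric vector of length 6.
#' @export
intensityFeatures <- function(ts) {
  if (length(ts) < 3L) stop("time series must have at least 3 points")
  mom <- .popMoments(ts)
  c(mom,
    autocorr = .avgAutocorr(ts),
    waveheight = max(ts) - min(ts))
}

# one-sided DFT bins: frequencies and power |X(f)|^2
.spectrum <- function(x) {
  n <- length(x)
  X <- fft(x)
  k <- 0:(n %/% 2)
  list(X = X, n = n, kOne = k + 1L, freq = k / n)  # freq in cycles/sample
}

# linear detrend (closed form)
.detrend <- function(x) {
  n <- length(x)
  t0 <- seq_len(n) - (n + 1) / 2
  x - mean(x) - sum(t0 * x) / sum(t0^2) * t0
}

# membership of one-sided bin frequencies in band [lo, hi); the top band
# of the bank also includes fHi (tolerance absorbs float noise)
.inBand <- function(f, lo, hi, includeHi = FALSE) {
  eps <- 1e-12
  f >= lo - eps & (f < hi - eps | (includeHi & f <= hi + eps))
}

# reconstruct the band-limited signal from a set of one-sided bins
.bandSignal <- function(X, n, oneSidedBins) {
  keep <- rep(FALSE, n)
  k <- oneSidedBins - 1L          # 0-based frequencies
  keep[k + 1L] <- TRUE
  conj <- (n - k) %% n            # conjugate bins
  keep[conj + 1L] <- TRUE
  Xb <- X
  Xb[!keep] <- 0
  Re(fft(Xb, inverse = TRUE)) / n
}

#' Filter-bank frequency descriptors of a time series
#'
#' The series is linearly detrended and transformed with the DFT. Per band:
#' (1) energy, the sum of \eqn{|X(f)|^2} over one-sided bins in the band;
#' (2) dominant frequency, the frequency of the maximal-power bin (ties go
#' to the lower frequency); (3) variance of the band-limited signal
#' reconstructed by zeroing out-of-band bins; (4) average autocorrelation
#' of that band-limited signal. Two global descriptors over the whole
#' analyzed range complete the set: the dominant frequency and the share of
#' analyzed-range power carried by the dominant bin. A band containing no
#' DFT bin contributes four zeros with a warning.
#'
#' @param ts numeric vector.
#' @param fs sampling frequency in Hz (1/TR); its Nyquist must cover the
#'   bank.
#' @param bank a \linkS4class{FilterBank}.
#' @return named numeric vector of length \code{4 * nBands + 2}.
#' @export
frequencyFeatures <- function(ts, fs, bank) {
  if (fs / 2 <= bank@fHi)
    stop("Nyquist frequency must exceed the filter bank's upper edge")
  x <- .detrend(ts)
  sp <- .spectrum(x)
  fHz <- sp$freq * fs
  pow <- Mod(sp$X[sp$kOne])^2
  nb <- bank@nBands
  out <- numeric(4 * nb + 2)
  nm <- character(4 * nb + 2)
  for (b in seq_len(nb)) {
    sel <- .inBand(fHz, bank@bands[b, 1], bank@bands[b, 2],
                   includeHi = (b == nb))
    base <- (b - 1) * 4
    nm[base + 1:4] <- paste0(c("energy", "domfreq", "variance", "autocorr"),
                             ".b", b)
    if (!any(sel)) {
      warning("band ", b, " contains no DFT bin (N = ", length(ts),
              ", fs = ", signif(fs, 4), " Hz); its features are 0")
      next
    }
    bins <- which(sel)
    out[base + 1] <- sum(pow[bins])
    out[base + 2] <- fHz[bins[which.max(pow[bins])]]
    xb <- .bandSignal(sp$X, sp$n, bins)
    out[base + 3] <- mean((xb - mean(xb))^2)
    out[base + 4] <- .avgAutocorr(xb)
  }
  selAll <- .inBand(fHz, bank@fLo, bank@fHi, includeHi = TRUE)
  gbase <- 4 * nb
  nm[gbase + 1:2] <- c("domfreq.global", "energypct.global")
  if (any(selAll)) {
    bins <- which(selAll)
    tot <- sum(pow[bins])
    dom <- bins[which.max(pow[bins])]
    out[gbase + 1] <- fHz[dom]
    out[gbase + 2] <- if (tot > 0) pow[dom] / tot else 0
  }
  names(out) <- nm
  out
}

#' Connectivity descriptors: maximum sinusoid overlap per band
#'
#' For each band, the band-limited signal (ideal rectangular DFT mask) is
#' correlated against a unit sinusoid at the band's center frequency; the
#' correlation is maximized over a grid of 64 phase offsets covering one
#' period, and that maximum overlap is the descriptor. A band signal with
#' zero variance yields 0.
#'
#' @inheritParams frequencyFeatures
#' @param nPhase phase-grid resolution over one period.
#' @return named numeric vector of length \code{nBands}.
#' @export
connectivityFeatures <- function(ts, fs, bank, nPhase = 64L) {
  if (fs / 2 <= bank@fHi)
    stop("Nyquist frequency must exceed the filter bank's upper edge")
  x <- .detrend(ts)
  sp <- .spectrum(x)
  fHz <- sp$freq * fs
  n <- sp$n
  tt <- (seq_len(n) - 1) / fs
  phases <- 2 * pi * (seq_len(nPhase) - 1) / nPhase
  nb <- bank@nBands
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- .inBand(fHz, bank@bands[b, 1], bank@bands[b, 2],
                   includeHi = (b == nb))
    if (!any(sel)) next
    xb <- .bandSignal(sp$X, n, which(sel))
    if (sd(xb) == 0) next
    fc <- bank@centers[b]
    # sin(wt + ph) = cos(ph) sin(wt) + sin(ph) cos(wt): evaluate the
    # correlation over the whole phase grid from a handful of crossprods
    sw <- sin(2 * pi * fc * tt)
    cw <- cos(2 * pi * fc * tt)
    xc <- xb - mean(xb)
    sc <- sw - mean(sw)
    cc <- cw - mean(cw)
    covS <- sum(xc * sc)
    covC <- sum(xc * cc)
    vS <- sum(sc^2)
    vC <- sum(cc^2)
    vSC <- sum(sc * cc)
    vX <- sum(xc^2)
    num <- cos(phases) * covS + sin(phases) * covC
    den <- sqrt(pmax(cos(phases)^2 * vS + sin(phases)^2 * vC +
                       2 * sin(phases) * cos(phases) * vSC, 0) * vX)
    r <- ifelse(den > 0, num / den, -Inf)
    best <- max(r)
    out[b] <- if (is.finite(best)) best else 0
  }
  names(out) <- paste0("maxoverlap.b", seq_len(nb))
  out
}

# canonical descriptor names for one region
.regionFeatureNames <- function(region, nb) {
  c(paste0("r", region, ".intensity.",
           c("mean", "variance", "skewness", "kurtosis", "autocorr",
             "waveheight")),
    paste0("r", region, ".freq.",
           as.vector(t(outer(paste0("b", seq_len(nb)),
                             c("energy", "domfreq", "variance", "autocorr"),
                             function(b, d) paste0(d, ".", b))))),
    paste0("r", region, ".freq.", c("domfreq.global", "energypct.global")),
    paste0("r", region, ".conn.maxoverlap.b", seq_len(nb)))
}

#' Canonical feature schema
#'
#' Feature names are a pure function of the region set and the band count:
#' \code{r<region>.<family>.<descriptor>[.b<band>]}.
#'
#' @param regionIds integer region indices.
#' @param bank a \linkS4class{FilterBank}.
#' @return character vector of \code{length(regionIds) * (16 + 4*nBands +
#'   2)} names (58 per region for the default bank).
#' @export
featureSchema <- function(regionIds, bank = buildFilterBank()) {
  unlist(lapply(regionIds, .regionFeatureNames, nb = bank@nBands),
         use.names = FALSE)
}

#' Region index of canonical feature names
#'
#' @param featureNames canonical names from \code{\link{featureSchema}}.
#' @return integer vector of region indices; errors on unparseable names.
#' @export
featureRegion <- function(featureNames) {
  m <- regmatches(featureNames, regexec("^r([0-9]+)\\.", featureNames))
  bad <- lengths(m) != 2L
  if (any(bad))
    stop("feature name(s) without a region prefix: ",
         paste(head(featureNames[bad], 3), collapse = ", "))
  as.integer(vapply(m, `[`, character(1), 2L))
}

#' Feature family of canonical feature names
#'
#' @inheritParams featureRegion
#' @return character vector: "intensity", "freq" or "conn".
#' @export
featureFamily <- function(featureNames) {
  sub("^r[0-9]+\\.([a-z]+)\\..*$", "\\1", featureNames)
}

#' Extract the full descriptor vector of one participant-session
#'
#' Each region's series is z-scored before the frequency and connectivity
#' analyses (scanner scale is arbitrary); the intensity mean and variance
#' are computed on the raw series so they retain the region's intensity
#' scale, while the four remaining intensity descriptors are computed on
#' the standardized series and are therefore scale-free.
#'
#' @param tss a \linkS4class{RoiTimeSeriesSet}.
#' @param bank a \linkS4class{FilterBank}.
#' @return named numeric vector of length \code{n_regions * 58} (default
#'   bank), ordered region by region, family order intensity, frequency,
#'   connectivity.
#' @export
extractFeatures <- function(tss, bank = buildFilterBank()) {
  validObject(tss)
  mat <- tss@mat
  if (ncol(mat) < 3L) stop("region series with fewer than 3 timepoints")
  fs <- 1 / tss@trS
  vals <- lapply(seq_len(nrow(mat)), function(i) {
    raw <- mat[i, ]
    s <- sd(raw)
    z <- if (s > 0) (raw - mean(raw)) / s else raw * 0
    intZ <- intensityFeatures(z)
    intRaw <- .popMoments(raw)[c("mean", "variance")]
    c(intRaw, intZ[c("skewness", "kurtosis", "autocorr", "waveheight")],
      frequencyFeatures(z, fs, bank),
      connectivityFeatures(z, fs, bank))
  })
  out <- unlist(vals, use.names = FALSE)
  names(out) <- featureSchema(tss@regionIds, bank)
  out
}

#' Build the cohort-level feature table
#'
#' @param cohort list with \code{participants} and \code{timeseries} as
#'   returned by \code{\link{generateCohort}}.
#' @param bank a \linkS4class{FilterBank}.
#' @return A \linkS4class{FeatureTable} (features x participant-sessions)
#'   with region/family/descriptor metadata in \code{rowData} and session
#'   labels in \code{colData}.
#' @export
extractFeatureTable <- function(cohort, bank = buildFilterBank()) {
  stopifnot(is.list(cohort), !is.null(cohort$participants),
            length(cohort$timeseries) > 0)
  vecs <- lapply(cohort$timeseries, extractFeatures, bank = bank)
  nms <- names(vecs[[1]])
  for (v in vecs)
    if (!identical(names(v), nms))
      stop("sessions produced inconsistent feature schemas")
  assay <- do.call(cbind, vecs)
  rownames(assay) <- nms
  pid <- vapply(cohort$timeseries, participantId, character(1))
  sid <- vapply(cohort$timeseries, sessionId, character(1))
  colnames(assay) <- paste(pid, sid, sep = ".")
  idx <- match(pid, cohort$participants$participant_id)
  if (anyNA(idx)) stop("time series reference unknown participants")
  cd <- S4Vectors::DataFrame(
    participant_id = pid, session_id = sid,
    sex = cohort$participants$sex[idx],
    diagnosis = cohort$participants$diagnosis[idx],
    severity_score = cohort$participants$severity_score[idx],
    row.names = colnames(assay))
  rd <- S4Vectors::DataFrame(
    region = featureRegion(nms), family = featureFamily(nms),
    row.names = nms)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), colData = cd, rowData = rd,
    metadata = list(bank = list(fLo = bank@fLo, fHi = bank@fHi,
                                nBands = bank@nBands)))
  new("FeatureTable", se)
}
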