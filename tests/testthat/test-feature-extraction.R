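bank <- buildFilterBank()

test_that("intensity descriptors handle degenerate and simple series", {
  f <- intensityFeatures(c(5, 5, 5, 5))
  expect_equal(unname(f), c(5, 0, 0, 0, 0, 0))
  f2 <- intensityFeatures(c(0, 1, 0, 1, 0, 1))
  expect_equal(unname(f2["mean"]), 0.5)
  expect_equal(unname(f2["waveheight"]), 1)
  expect_error(intensityFeatures(c(1, 2)), "at least 3")
})

test_that("intensity descriptors match the direct-sum reference", {
  set.seed(101)
  x <- rnorm(100)
  expect_equal(unname(intensityFeatures(x)), unname(slowIntensity(x)),
               tolerance = 1e-10)
})

test_that("a pure tone lands in the right band and bin", {
  fs <- 0.5
  n <- 256
  tt <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 0.05 * tt)
  f <- frequencyFeatures(x, fs, bank)
  # nearest DFT bin to 0.05 Hz
  binFreqs <- (0:(n %/% 2)) / n * fs
  expect_equal(unname(f["domfreq.global"]),
               binFreqs[which.min(abs(binFreqs - 0.05))])
  energies <- f[paste0("energy.b", 1:10)]
  expect_equal(which.max(energies), 3L, ignore_attr = TRUE)  # 0.05 in band 3
})

test_that("band energies partition the analyzed-range energy", {
  set.seed(7)
  for (n in c(180, 231)) {
    x <- rnorm(n)
    fs <- 1 / 2.1
    f <- frequencyFeatures(x, fs, bank)
    total <- sum(f[paste0("energy.b", 1:10)])
    # recompute total analyzed energy directly
    xd <- x - mean(x) - (seq_len(n) - (n + 1) / 2) *
      sum((seq_len(n) - (n + 1) / 2) * x) / sum((seq_len(n) - (n + 1) / 2)^2)
    X <- fft(xd)
    fr <- (0:(n %/% 2)) / n * fs
    sel <- fr >= 0.01 - 1e-12 & fr <= 0.15 + 1e-12
    expect_equal(total, sum(Mod(X[which(sel)])^2), tolerance = 1e-8)
  }
})

test_that("frequency descriptors match the O(N^2) DFT reference", {
  set.seed(55)
  x <- rnorm(96)
  fs <- 0.45
  expect_equal(unname(frequencyFeatures(x, fs, bank)),
               slowFrequency(x, fs, bank), tolerance = 1e-8)
})

test_that("an empty band yields zeros and a warning", {
  x <- rnorm(8)
  w <- capture_warnings(f <- frequencyFeatures(x, 1, bank))
  expect_true(any(grepl("no DFT bin", w)))
  expect_true(any(f[paste0("energy.b", 1:10)] == 0))
})

test_that("Nyquist must cover the bank", {
  expect_error(frequencyFeatures(rnorm(64), 0.2, bank), "Nyquist")
  expect_error(connectivityFeatures(rnorm(64), 0.2, bank), "Nyquist")
})

test_that("connectivity overlap is high at the band center, phase-free", {
  fs <- 0.5
  n <- 500  # 17 whole cycles of the band-1 center => no spectral leakage
  tt <- (0:(n - 1)) / fs
  fc1 <- bandCenters(bank)[1]
  x <- sin(2 * pi * fc1 * tt)
  v <- connectivityFeatures(x, fs, bank)
  expect_gte(v[1], 0.99)
  vShift <- connectivityFeatures(sin(2 * pi * fc1 * tt + pi / 3), fs, bank)
  expect_equal(unname(v[1]), unname(vShift[1]), tolerance = 1e-3)
  # a distant band sees only detrend leakage; its overlap is whatever the
  # explicit reference computes, and far below the in-band overlap
  expect_equal(unname(v[8]), slowConnectivity(x, fs, bank)[8],
               tolerance = 1e-8)
  expect_lt(abs(v[8]), v[1] - 0.5)
})

test_that("connectivity descriptors match the explicit phase-loop reference", {
  set.seed(77)
  x <- rnorm(120)
  fs <- 0.48
  expect_equal(unname(connectivityFeatures(x, fs, bank)),
               slowConnectivity(x, fs, bank), tolerance = 1e-8)
})

test_that("constant band signals give zero overlap", {
  expect_equal(unname(connectivityFeatures(rep(2, 50), 0.5, bank)),
               rep(0, 10))
})

test_that("the schema is a pure function of regions and bands", {
  nm1 <- featureSchema(1:3, bank)
  expect_equal(length(nm1), 3 * 58)
  expect_equal(anyDuplicated(nm1), 0)
  expect_identical(nm1, featureSchema(1:3, buildFilterBank(0.01, 0.15, 10)))
  expect_equal(featureRegion(c("r7.intensity.mean", "r12.conn.maxoverlap.b3")),
               c(7L, 12L))
  expect_equal(featureFamily(c("r7.intensity.mean", "r1.freq.energy.b2")),
               c("intensity", "freq"))
  expect_error(featureRegion("bogus"), "region prefix")
})

test_that("one region yields 58 descriptors in canonical order", {
  set.seed(3)
  tss <- roiTimeSeriesSet(matrix(rnorm(200), 1, 200), trS = 2.2)
  v <- extractFeatures(tss)
  expect_equal(length(v), 58)
  fam <- featureFamily(names(v))
  expect_equal(sum(fam == "intensity"), 6)
  expect_equal(sum(fam == "freq"), 42)
  expect_equal(sum(fam == "conn"), 10)
})

test_that("sessions with different frame counts share one schema", {
  set.seed(4)
  a <- extractFeatures(roiTimeSeriesSet(matrix(rnorm(2 * 180), 2), 2.0))
  b <- extractFeatures(roiTimeSeriesSet(matrix(rnorm(2 * 260), 2), 2.4))
  expect_identical(names(a), names(b))
  expect_error(extractFeatures(roiTimeSeriesSet(matrix(1:4, 2), 2.0)),
               "fewer than 3")
})

test_that("rescaling a region changes only raw mean and variance", {
  set.seed(9)
  m <- matrix(rnorm(2 * 200, mean = 800, sd = 15), 2)
  tss1 <- roiTimeSeriesSet(m, 2.1)
  m2 <- m
  m2[1, ] <- m[1, ] * 3
  tss2 <- roiTimeSeriesSet(m2, 2.1)
  v1 <- extractFeatures(tss1)
  v2 <- extractFeatures(tss2)
  scaled <- c("r1.intensity.mean", "r1.intensity.variance")
  expect_equal(v2["r1.intensity.mean"], 3 * v1["r1.intensity.mean"])
  expect_equal(v2["r1.intensity.variance"], 9 * v1["r1.intensity.variance"])
  keep <- setdiff(names(v1), scaled)
  expect_equal(v1[keep], v2[keep], tolerance = 1e-10)
})

test_that("the cohort feature table carries labels and metadata", {
  cfg <- cohortConfig(nPerGroup = 2, nRegions = 3,
                      sessionsPerPatientRange = c(2, 2), seed = 21)
  co <- generateCohort(cfg)
  ft <- extractFeatureTable(co)
  expect_s4_class(ft, "FeatureTable")
  expect_equal(nrow(ft), 3 * 58)
  expect_equal(ncol(ft), length(co$timeseries))
  info <- sampleInfo(ft)
  expect_true(all(c("participant_id", "sex", "diagnosis",
                    "severity_score") %in% names(info)))
  expect_false(anyNA(featureValues(ft)))
  rd <- as.data.frame(SummarizedExperiment::rowData(ft))
  expect_equal(sort(unique(rd$region)), 1:3)
})
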