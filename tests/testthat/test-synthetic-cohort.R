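bank <- buildFilterBank()

# band-3 energy of one region's raw series, standardized as the extractor
# does
regionBandEnergy <- function(tss, region, band = 3) {
  x <- tsMatrix(tss)[region, ]
  z <- (x - mean(x)) / sd(x)
  unname(frequencyFeatures(z, 1 / trS(tss), bank)[paste0("energy.b", band)])
}

test_that("identical config yields a bit-identical cohort", {
  cfg <- cohortConfig(nPerGroup = 2, nRegions = 3, seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$participants, b$participants)
  for (i in seq_along(a$timeseries))
    expect_identical(tsMatrix(a$timeseries[[i]]), tsMatrix(b$timeseries[[i]]))
})

test_that("cohort structure follows the configuration", {
  cfg <- cohortConfig(nPerGroup = 3, nRegions = 4,
                      sessionsPerPatientRange = c(2, 3), seed = 5)
  co <- generateCohort(cfg)
  p <- co$participants
  expect_equal(nrow(p), 12)
  expect_equal(sum(p$diagnosis == "PD"), 6)
  expect_true(all(p$severity_score[p$diagnosis == "control"] == 0))
  expect_true(all(p$severity_score[p$diagnosis == "PD"] > 0))
  expect_true(all(p$n_sessions[p$diagnosis == "PD"] %in% 2:3))
  expect_true(all(p$n_sessions[p$diagnosis == "control"] == 1))
  expect_equal(length(co$timeseries), sum(p$n_sessions))
  # frame counts and TR within configured intervals
  for (tss in co$timeseries) {
    expect_gte(ncol(tsMatrix(tss)), 175)
    expect_lte(ncol(tsMatrix(tss)), 265)
    expect_gte(trS(tss), 2.0)
    expect_lte(trS(tss), 2.4)
    expect_false(anyNA(tsMatrix(tss)))
  }
})

test_that("per-session substreams are stable and bounded", {
  cfg <- cohortConfig(nPerGroup = 2, nRegions = 3, seed = 9)
  p <- generateParticipants(cfg)
  rec <- p[p$diagnosis == "PD", ][1, ]
  a <- generateRoiTimeSeries(rec, cfg, 1)
  b <- generateRoiTimeSeries(rec, cfg, 1)
  expect_identical(tsMatrix(a), tsMatrix(b))
  expect_error(generateRoiTimeSeries(rec, cfg, rec$n_sessions + 1L),
               "out of range")
  # enlarging the cohort leaves existing participants' data unchanged
  cfgBig <- cohortConfig(nPerGroup = 4, nRegions = 3, seed = 9)
  a2 <- generateRoiTimeSeries(rec, cfgBig, 1)
  expect_identical(tsMatrix(a), tsMatrix(a2))
})

test_that("controls carry no planted perturbation", {
  base <- cohortConfig(nPerGroup = 2, nRegions = 3, seed = 3)
  planted <- cohortConfig(nPerGroup = 2, nRegions = 3,
                          affectedRegions = c(1, 2), amplitudeEffect = 2,
                          bandEffect = c(3, 5), seed = 3)
  p <- generateParticipants(base)
  ctrl <- p[p$diagnosis == "control", ][1, ]
  expect_identical(tsMatrix(generateRoiTimeSeries(ctrl, base, 1)),
                   tsMatrix(generateRoiTimeSeries(ctrl, planted, 1)))
  # a patient's affected region does change
  pat <- p[p$diagnosis == "PD", ][1, ]
  m0 <- tsMatrix(generateRoiTimeSeries(pat, base, 1))
  m1 <- tsMatrix(generateRoiTimeSeries(pat, planted, 1))
  expect_false(identical(m0[1, ], m1[1, ]))
  expect_identical(m0[3, ], m1[3, ])  # unaffected region untouched
})

test_that("null effects leave patient and control features exchangeable", {
  cfg <- cohortConfig(nPerGroup = 25, nRegions = 2,
                      affectedRegions = c(1, 2), amplitudeEffect = 0,
                      bandEffect = c(3, 1),
                      sessionsPerPatientRange = c(1, 1), seed = 11)
  co <- generateCohort(cfg)
  pd <- co$participants$diagnosis[match(
    vapply(co$timeseries, participantId, character(1)),
    co$participants$participant_id)] == "PD"
  e <- vapply(co$timeseries, regionBandEnergy, numeric(1), region = 1)
  expect_gt(t.test(e[pd], e[!pd])$p.value, 0.01)
})

test_that("a planted band effect is detectable by a direct Welch t-test", {
  cfg <- cohortConfig(nPerGroup = 20, nRegions = 17,
                      affectedRegions = 17L, amplitudeEffect = 0,
                      bandEffect = c(3, 2.5),
                      sessionsPerPatientRange = c(1, 1), seed = 13)
  co <- generateCohort(cfg)
  pd <- co$participants$diagnosis[match(
    vapply(co$timeseries, participantId, character(1)),
    co$participants$participant_id)] == "PD"
  e17 <- vapply(co$timeseries, regionBandEnergy, numeric(1), region = 17)
  expect_lt(t.test(e17[pd], e17[!pd])$p.value, 0.001)
  # an unaffected region shows nothing at that level
  e1 <- vapply(co$timeseries, regionBandEnergy, numeric(1), region = 1)
  expect_gt(t.test(e1[pd], e1[!pd])$p.value, 0.001)
})

test_that("planted band power grows with severity on shared noise", {
  cfg <- cohortConfig(nPerGroup = 2, nRegions = 2, affectedRegions = 1L,
                      amplitudeEffect = 0, bandEffect = c(3, 3),
                      sessionsPerPatientRange = c(1, 1), seed = 17)
  p <- generateParticipants(cfg)
  rec <- p[p$diagnosis == "PD", ][1, ]
  recLo <- rec; recLo$severity_score <- 15
  recHi <- rec; recHi$severity_score <- 30  # same id => same substream noise
  eLo <- regionBandEnergy(generateRoiTimeSeries(recLo, cfg, 1), 1)
  eHi <- regionBandEnergy(generateRoiTimeSeries(recHi, cfg, 1), 1)
  expect_gt(eHi, eLo)
})

test_that("band-power factor increases the planted two-sample statistic", {
  stat <- function(factor) {
    cfg <- cohortConfig(nPerGroup = 15, nRegions = 2, affectedRegions = 1L,
                        amplitudeEffect = 0, bandEffect = c(3, factor),
                        sessionsPerPatientRange = c(1, 1), seed = 19)
    co <- generateCohort(cfg)
    pd <- co$participants$diagnosis[match(
      vapply(co$timeseries, participantId, character(1)),
      co$participants$participant_id)] == "PD"
    e <- vapply(co$timeseries, regionBandEnergy, numeric(1), region = 1)
    unname(t.test(e[pd], e[!pd])$statistic)
  }
  s <- vapply(c(1.5, 2.5, 4), stat, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(nPerGroup = 2, nRegions = 3,
                            affectedRegions = 9L), "affectedRegions")
  expect_error(cohortConfig(nPerGroup = 2, bandEffect = c(12, 2)),
               "bandEffectBand")
  expect_error(cohortConfig(nPerGroup = 2, bandEffect = c(3, 0)),
               "bandEffectFactor")
  expect_error(cohortConfig(nPerGroup = 2, nTimepointsRange = c(100, 50)),
               "nTimepointsRange")
})
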