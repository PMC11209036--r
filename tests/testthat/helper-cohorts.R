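# Shared synthetic cohorts, built once per test run and cached.

.cohortCache <- new.env(parent = emptyenv())

# study conditions for planted-effect analyses: a four-cell cohort of 300
# participants (75 per cell, comparable to the scale at which this method
# family is used), two affected regions carrying a severity-scaled
# amplitude shift and a band-3 power increase that leave the arms
# overlapping
plantedCohortConfig <- function(seed, nPerGroup = 75L, nRegions = 6L,
                                affectedRegions = c(2L, 5L)) {
  cohortConfig(nPerGroup = nPerGroup, nRegions = nRegions,
               affectedRegions = affectedRegions,
               amplitudeEffect = 0.5, bandEffect = c(3, 2.5),
               sessionsPerPatientRange = c(1L, 1L), seed = seed)
}

# forest settings used for region-level ranking at this cohort scale:
# shallow trees concentrate split counts on root-level heterogeneity
rankingCfParams <- function(seed) {
  cfParams(nTrees = 800L, subsampleFraction = 0.8, maxDepth = 2L,
           seed = as.integer(seed))
}

cachedFeatureTable <- function(key, config) {
  if (is.null(.cohortCache[[key]])) {
    cohort <- generateCohort(config)
    .cohortCache[[key]] <- list(cohort = cohort,
                                table = extractFeatureTable(cohort))
  }
  .cohortCache[[key]]
}

# effect-free cohort for null-calibration checks: 25 participants per cell,
# one session each (100 balanced sessions)
nullFeatureTable <- function() {
  cachedFeatureTable("null100", cohortConfig(
    nPerGroup = 25L, nRegions = 5L, affectedRegions = integer(),
    amplitudeEffect = 0, bandEffect = c(3, 1),
    sessionsPerPatientRange = c(1L, 1L), seed = 424L))
}

plantedFeatureTable <- function() {
  cachedFeatureTable("planted", plantedCohortConfig(seed = 31L))
}
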