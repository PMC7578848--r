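# Shared fixtures, computed lazily and cached for the whole test run so the
# expensive synthetic cohorts are generated exactly once.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small, fast cohort configuration used by unit tests. Short segments and
# baselines; study-scale parameters stay at their defaults.
smallConfig <- function(nParticipants = 2, seed = 7, segmentRange = c(6, 9),
                        baselineDuration = 6, ...) {
  cohortConfig(nParticipants = nParticipants, segmentRange = segmentRange,
               baselineDuration = baselineDuration, seed = seed, ...)
}

# One small generated recording (with truth), reused across unit tests.
smallRecording <- function() {
  .cached("smallRecording",
          generateRecording(smallConfig(), 1, "visual"))
}

# The same recording high-passed and segmented.
smallSegRun <- function() {
  .cached("smallSegRun",
          segmentAcquisition(highpass(smallRecording()$recording, 0.5)))
}

cachedAdjacency <- function() {
  .cached("adjacency", buildAdjacency())
}

# ---- acceptance-scale fixtures ----------------------------------------

zeroPowerEffect <- function() defaultPowerEffect() * 0

zeroCouplingEffect <- function() defaultCouplingEffect() * 0

thetaOnlyCouplingEffect <- function() {
  m <- defaultCouplingEffect()
  m["alpha", ] <- 0
  m
}

# Feature matrices of the default cohort (power family), for the 216-row
# assembly criterion.
defaultCohortPowerFeatures <- function() {
  .cached("defaultPower",
          computeCohortFeatures(cohortConfig(), families = "power"))
}

# The three single-effect recovery cohorts of the parameter-recovery
# criterion: each plants exactly one effect family at the study defaults.
# Participants (18) and repetitions (50) are the pinned design numbers;
# segment and baseline durations are shortened (12-14 s segments, 20 s
# baselines) to fit the recovery budget -- shorter segments only make
# detection harder, never easier.
recoveryFeatures <- function(kind) {
  key <- paste0("recovery_", kind)
  .cached(key, {
    cfg <- switch(kind,
      power = cohortConfig(segmentRange = c(12, 14), baselineDuration = 20,
                           loadCouplingEffect = zeroCouplingEffect(),
                           cfcEffect = list(), seed = 11),
      coupling = cohortConfig(segmentRange = c(12, 14),
                              baselineDuration = 20,
                              modalityPowerEffect = zeroPowerEffect(),
                              loadCouplingEffect = thetaOnlyCouplingEffect(),
                              cfcEffect = list(), seed = 12),
      cfc = cohortConfig(segmentRange = c(12, 14), baselineDuration = 20,
                         modalityPowerEffect = zeroPowerEffect(),
                         loadCouplingEffect = zeroCouplingEffect(),
                         seed = 13),
      stop("unknown recovery cohort: ", kind))
    fam <- switch(kind, power = "power", coupling = "connectivity",
                  cfc = "cfc")
    computeCohortFeatures(cfg, families = fam,
                          connectivityBands = "theta",
                          cfcPairs = "theta-beta")
  })
}

# Decode one recovery feature set against its permutation null (50 reps).
recoveryDecoding <- function(kind, scheme, featureSet) {
  key <- paste0("decode_", kind, "_", scheme)
  .cached(key, {
    list(actual = repeatedAccuracy(featureSet, scheme, reps = 50,
                                   seed = 421),
         chance = permutationChance(featureSet, scheme, reps = 50,
                                    seed = 422))
  })
}
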